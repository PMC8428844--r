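# Shared fixtures: the reference parameterization is a symmetric supply
# s = (1,1,1) with mu*K = 0.1 (K = 1, mu = 0.1) and death rate 0.25 or 1.

sym_env <- function(delta = 0.25, mu = 0.1, K = 1, p = 3) {
  environment_spec(supply = rep(1, p), monod_K = K, decay = mu,
                   death_rate = delta)
}

# decay-free environment for closed-form equilibria
mu0_env <- function(delta = 0.25, p = 3, K = 1) {
  environment_spec(supply = rep(1, p), monod_K = K, decay = 0,
                   death_rate = delta)
}

# batch-phase environment (Monod constants only; no supply/death/decay)
batch_env <- function(K = 1, p = 3) {
  environment_spec(supply = rep(0, p), monod_K = K, decay = 0,
                   death_rate = 0)
}

off_center_start <- function(spec) {
  project_to_constraint(c(0.8, 0.15, 0.05), spec)
}

# independent connectivity oracle for single-linkage cluster counts:
# number of connected components of the graph joining strains closer
# than the cutoff
components_count <- function(alpha, cutoff) {
  S <- nrow(alpha)
  d <- as.matrix(stats::dist(alpha))
  parent <- seq_len(S)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(S - 1)) for (j in (i + 1):S) {
    if (d[i, j] < cutoff) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  length(unique(vapply(seq_len(S), find, integer(1))))
}
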