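#' Evolution engine parameters
#'
#' Settings of the mutation-selection simulation. Defaults assume a
#' separation of ecological and evolutionary timescales: one mutation per
#' epoch, each epoch long enough for the ecology to relax.
#'
#' @param mutation_sigma Standard deviation of the isotropic Gaussian
#'   mutational step in trait space (must lie in `(0, 0.2]`).
#' @param mutations_per_epoch Number of mutants introduced per epoch.
#' @param epoch_duration Chemostat time integrated per epoch.
#' @param epoch_batches Number of dilution cycles per epoch (serial
#'   dilution ecology).
#' @param mutant_fraction Fraction of the parent's density transferred to
#'   a new mutant strain (must lie in `(0, 0.1]`).
#' @param max_epochs Hard cap on the number of epochs.
#' @param rng_seed Integer seed; identical seeds and parameters give
#'   bitwise-identical runs.
#' @param stop_window Number of consecutive epochs over which the trait
#'   distribution must be stationary to stop.
#' @param stop_mean_tol Maximum drift of the density-weighted mean
#'   phenotype over the window.
#' @param stop_var_abs,stop_var_rel The total trait variance may range
#'   over at most `max(stop_var_abs, stop_var_rel * max(variance))`
#'   within the window (guards against stopping while a trait cloud is
#'   still spreading towards or through an evolutionary branching).
#' @return Object of class `"evolution_params"`.
#' @export
evolution_params <- function(mutation_sigma = 0.03,
                             mutations_per_epoch = 5L,
                             epoch_duration = 100,
                             epoch_batches = 5L,
                             mutant_fraction = 0.01,
                             max_epochs = 3000L,
                             rng_seed = 1L,
                             stop_window = 400L,
                             stop_mean_tol = 0.02,
                             stop_var_abs = 0.002,
                             stop_var_rel = 0.1) {
  if (mutation_sigma <= 0 || mutation_sigma > 0.2)
    stop("`mutation_sigma` must lie in (0, 0.2]", call. = FALSE)
  if (mutant_fraction <= 0 || mutant_fraction > 0.1)
    stop("`mutant_fraction` must lie in (0, 0.1]", call. = FALSE)
  if (mutations_per_epoch < 1 || max_epochs < 1)
    stop("`mutations_per_epoch` and `max_epochs` must be >= 1",
         call. = FALSE)
  if (epoch_duration <= 0 || epoch_batches < 1)
    stop("invalid epoch length settings", call. = FALSE)
  structure(list(mutation_sigma = mutation_sigma,
                 mutations_per_epoch = as.integer(mutations_per_epoch),
                 epoch_duration = epoch_duration,
                 epoch_batches = as.integer(epoch_batches),
                 mutant_fraction = mutant_fraction,
                 max_epochs = as.integer(max_epochs),
                 rng_seed = as.integer(rng_seed),
                 stop_window = as.integer(stop_window),
                 stop_mean_tol = stop_mean_tol,
                 stop_var_abs = stop_var_abs,
                 stop_var_rel = stop_var_rel),
            class = "evolution_params")
}

#' Mutate a phenotype on the tradeoff surface
#'
#' Adds an isotropic Gaussian perturbation (sd `sigma`) to the parent's
#' allocation vector, clips negative components to zero, and re-projects
#' onto the constraint surface. Exact zeros are permitted, so specialist
#' vertices are reachable by a finite mutational path.
#'
#' @param parent Parent allocation vector (on the surface).
#' @param sigma Mutational step scale.
#' @param spec A [tradeoff_spec()].
#' @param max_retries Resampling bound for the degenerate all-zero draw.
#' @return Mutant allocation vector on the surface.
#' @export
mutate_phenotype <- function(parent, sigma, spec, max_retries = 100L) {
  for (i in seq_len(max_retries)) {
    raw <- pmax(parent + stats::rnorm(length(parent), 0, sigma), 0)
    if (any(raw > 0)) return(project_to_constraint(raw, spec))
  }
  stop("mutation degenerated to the all-zero vector repeatedly",
       call. = FALSE)
}

# number of single-linkage clusters at a distance cutoff
.n_clusters <- function(alpha, cutoff) {
  S <- nrow(alpha)
  if (S <= 1) return(S)
  max(stats::cutree(stats::hclust(stats::dist(alpha), method = "single"),
                    h = cutoff))
}

# Evolutionary finality of the current cluster configuration. Along
# directions with effective concave curvature (gamma_j / q_j < 1)
# selection is disruptive, so a cluster whose budget is still split
# between two or more concave directions (interior shares, 0.1-0.9) has
# an evolutionary branching ahead of it -- e.g. the transient
# two-resource generalist on the way to full specialization, or the
# initial cloud sitting at the singular strategy. A single interior
# concave share imposes no condition: a split along one direction
# cannot separate two viable daughters (the abandoning daughter would
# re-enter an occupied niche), and mixed-curvature endpoints do hold
# one such compromise share.
.clusters_final <- function(state, spec, env, cutoff) {
  geff <- spec$gamma / env$uptake_exponent
  concave <- which(geff < 1 - 1e-12)
  if (length(concave) < 2) return(TRUE)
  S <- nrow(state$alpha)
  memb <- if (S == 1) rep(1L, 1) else
    stats::cutree(stats::hclust(stats::dist(state$alpha),
                                method = "single"), h = cutoff)
  for (k in unique(memb)) {
    sel <- memb == k
    w <- state$density[sel]
    ctr <- as.numeric(crossprod(state$alpha[sel, , drop = FALSE], w)) /
      sum(w)
    shares <- ctr ^ spec$gamma / spec$budget
    if (sum(shares[concave] > 0.1 & shares[concave] < 0.9) >= 2)
      return(FALSE)
  }
  TRUE
}

#' Run a mutation-selection evolutionary simulation
#'
#' Alternates ecological relaxation (chemostat integration over
#' `epoch_duration`, or `epoch_batches` serial-dilution cycles) with
#' mutation events: each epoch, `mutations_per_epoch` parents are drawn
#' with probability proportional to density and each spawns a mutant
#' strain ([mutate_phenotype()]) carrying `mutant_fraction` of the
#' parent's density. Strains below the extinction threshold are culled
#' at epoch boundaries. The run stops when the density-weighted mean
#' phenotype, the single-linkage cluster count and the total trait
#' variance have all been stationary for `stop_window` consecutive
#' epochs, or at `max_epochs`.
#'
#' @param initial Ancestral allocation vector (projected onto the
#'   surface).
#' @param spec A [tradeoff_spec()].
#' @param env An [environment_spec()] (chemostat parameters; for the
#'   dilution ecology it supplies the Monod constants and uptake
#'   exponents).
#' @param evo An [evolution_params()].
#' @param ctrl An [integration_control()].
#' @param protocol A [dilution_protocol()] to run the serial-dilution
#'   ecology; `NULL` (default) runs the chemostat.
#' @param cluster_cutoff Single-linkage cutoff used for the per-epoch
#'   cluster count (default 0.2).
#' @param snapshot_every Keep a full community snapshot every this many
#'   epochs (default 1).
#' @return Object of class `"evolution_trajectory"`: a list with
#'   `snapshots` (list of [community_state()]), `epochs` (snapshot
#'   epochs), `mean_path` (epochs x p density-weighted mean phenotype),
#'   `trait_variance`, `cluster_count`, `events` (data frame of mutation
#'   and extinction events), `final` (final state), `converged` and
#'   `epochs_run`.
#' @export
run_evolution <- function(initial, spec, env, evo = evolution_params(),
                          ctrl = integration_control(), protocol = NULL,
                          cluster_cutoff = 0.2, snapshot_every = 1L) {
  set.seed(evo$rng_seed)
  mode <- if (is.null(protocol)) "chemostat" else "dilution"
  alpha <- matrix(project_to_constraint(initial, spec), nrow = 1)
  if (mode == "chemostat") {
    n0 <- if (env$death_rate > 0) sum(env$supply) / env$death_rate else 1
    state <- community_state(alpha, density = n0, conc = env$monod_K)
    nmin <- .default_nmin_chemostat(env, ctrl)
  } else {
    state <- community_state(alpha, density = protocol$rho0,
                             conc = protocol$c_init)
    nmin <- 1e-9 * protocol$rho0
  }
  next_id <- 2L
  p <- spec$p
  E <- evo$max_epochs
  mean_path <- matrix(NA_real_, E, p)
  trait_var <- numeric(E)
  k_count <- integer(E)
  times <- numeric(E)
  snapshots <- list()
  snap_epochs <- integer(0)
  ev_epoch <- integer(0); ev_type <- character(0)
  ev_id <- integer(0); ev_parent <- integer(0)
  converged <- FALSE
  epochs_run <- 0L

  for (epoch in seq_len(E)) {
    # --- ecological relaxation ---
    if (mode == "chemostat") {
      state <- chemostat_integrate(state, env, ctrl, evo$epoch_duration)
    } else {
      for (b in seq_len(evo$epoch_batches)) {
        res <- run_batch(state, protocol, env, ctrl)
        state <- dilute(res$state, protocol)
      }
    }
    culled <- .cull(state, nmin)
    state <- culled$state
    if (sum(state$density) < 1e-15) {
      warning("community collapsed: the death rate exceeds the maximum ",
              "sustainable per-capita birth rate under this budget",
              call. = FALSE)
      epochs_run <- epoch - 1L
      break
    }
    if (length(culled$extinct)) {
      ev_epoch <- c(ev_epoch, rep(epoch, length(culled$extinct)))
      ev_type <- c(ev_type, rep("extinction", length(culled$extinct)))
      ev_id <- c(ev_id, culled$extinct)
      ev_parent <- c(ev_parent, rep(NA_integer_, length(culled$extinct)))
    }

    # --- record ---
    tot <- sum(state$density)
    wm <- as.numeric(crossprod(state$alpha, state$density)) / tot
    mean_path[epoch, ] <- wm
    dev <- sweep(state$alpha, 2, wm)
    trait_var[epoch] <- sum(state$density * rowSums(dev^2)) / tot
    k_count[epoch] <- .n_clusters(state$alpha, cluster_cutoff)
    times[epoch] <- state$time
    if (epoch %% snapshot_every == 0L) {
      snapshots[[length(snapshots) + 1L]] <- state
      snap_epochs <- c(snap_epochs, epoch)
    }
    epochs_run <- epoch

    # --- stop rule ---
    w <- evo$stop_window
    if (epoch > w) {
      win <- (epoch - w):epoch
      drift <- sqrt(rowSums(sweep(mean_path[win, , drop = FALSE], 2,
                                  wm)^2))
      vmax <- max(trait_var[win]); vmin <- min(trait_var[win])
      if (all(k_count[win] == k_count[epoch]) &&
          max(drift) <= evo$stop_mean_tol &&
          (vmax - vmin) <= max(evo$stop_var_abs, evo$stop_var_rel * vmax) &&
          .clusters_final(state, spec, env, cluster_cutoff)) {
        converged <- TRUE
        break
      }
    }

    # --- mutations ---
    for (m in seq_len(evo$mutations_per_epoch)) {
      pi <- sample.int(nrow(state$alpha), 1L, prob = state$density)
      child <- mutate_phenotype(state$alpha[pi, ], evo$mutation_sigma, spec)
      dn <- evo$mutant_fraction * state$density[pi]
      state$density[pi] <- state$density[pi] - dn
      state$alpha <- rbind(state$alpha, child)
      state$density <- c(state$density, dn)
      state$ids <- c(state$ids, next_id)
      ev_epoch <- c(ev_epoch, epoch); ev_type <- c(ev_type, "mutation")
      ev_id <- c(ev_id, next_id); ev_parent <- c(ev_parent, state$ids[pi])
      next_id <- next_id + 1L
    }
  }

  events <- data.frame(epoch = ev_epoch, type = ev_type,
                       strain_id = ev_id, parent_id = ev_parent)
  structure(list(snapshots = snapshots, epochs = snap_epochs,
                 mean_path = mean_path[seq_len(epochs_run), , drop = FALSE],
                 trait_variance = trait_var[seq_len(epochs_run)],
                 cluster_count = k_count[seq_len(epochs_run)],
                 times = times[seq_len(epochs_run)],
                 events = events, final = state, converged = converged,
                 epochs_run = epochs_run, mode = mode,
                 spec = spec, env = env, protocol = protocol,
                 params = evo),
            class = "evolution_trajectory")
}

#' @export
print.evolution_trajectory <- function(x, ...) {
  cat("Evolutionary trajectory (", x$mode, " ecology)\n", sep = "")
  cat("  epochs run:", x$epochs_run,
      if (x$converged) "(stop rule met)" else "(max epochs)", "\n")
  cat("  final strains:", nrow(x$final$alpha),
      " clusters:", x$cluster_count[x$epochs_run], "\n")
  invisible(x)
}

#' Track convergence of a monomorphic population to the singular strategy
#'
#' Runs [run_evolution()] and reports, per epoch, the Euclidean distance
#' of the density-weighted mean phenotype from the singular strategy,
#' together with the cluster count (so that convergence can be checked to
#' precede any branching).
#'
#' @inheritParams run_evolution
#' @return List with `distance` (a data frame: epoch, time, distance,
#'   n_clusters), `alpha_star` and `trajectory` (the underlying
#'   [run_evolution()] result).
#' @export
monomorphic_convergence_test <- function(initial, spec, env,
                                         evo = evolution_params(),
                                         ctrl = integration_control(),
                                         protocol = NULL, ...) {
  traj <- run_evolution(initial, spec, env, evo, ctrl, protocol, ...)
  astar <- singular_point(env$supply, spec, env$uptake_exponent)
  d <- sqrt(rowSums(sweep(traj$mean_path, 2, astar)^2))
  list(distance = data.frame(epoch = seq_len(traj$epochs_run),
                             time = traj$times, distance = d,
                             n_clusters = traj$cluster_count),
       alpha_star = astar, trajectory = traj)
}
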