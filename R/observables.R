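# Post-processing observables: phenotype clustering, specialist
# classification, simplex projection, and the pure-ecology assembly
# experiment.

#' Budget-share (simplex) coordinates of a phenotype
#'
#' Maps an allocation strategy to its budget shares
#' \eqn{(\alpha_j^{\gamma_j} / E)_j}, which sum to 1 for any strategy on
#' the tradeoff surface. For three resources these are the coordinates
#' used to draw communities on the simplex plane.
#'
#' @param alpha An allocation vector or an `S x p` matrix of strategies
#'   (one row per strain).
#' @param spec A [tradeoff_spec()].
#' @return Vector or matrix of simplex coordinates.
#' @examples
#' simplex_coordinates(rep(1 / 9, 3), tradeoff_spec(0.5, p = 3))
#' @export
simplex_coordinates <- function(alpha, spec) {
  if (is.matrix(alpha)) {
    .effective_alpha(alpha, spec$gamma) / spec$budget
  } else {
    alpha ^ spec$gamma / spec$budget
  }
}

#' Specialist/generalist classification of a strategy
#'
#' A strategy is a specialist when it concentrates at least `threshold`
#' of its budget share on a single resource.
#'
#' @param center Allocation vector (e.g. a cluster center).
#' @param spec A [tradeoff_spec()].
#' @param threshold Budget-share threshold in `(0.5, 1]` (default 0.9).
#' @return List with `specialist` (logical) and `resource` (index of the
#'   dominating resource, or `NA`).
#' @examples
#' classify_specialist(c(1, 0, 0), tradeoff_spec(0.9, p = 3))
#' @export
classify_specialist <- function(center, spec, threshold = 0.9) {
  if (threshold <= 0.5 || threshold > 1)
    stop("`threshold` must lie in (0.5, 1]", call. = FALSE)
  shares <- simplex_coordinates(center, spec)
  j <- which.max(shares)
  if (shares[j] >= threshold) {
    list(specialist = TRUE, resource = as.integer(j))
  } else {
    list(specialist = FALSE, resource = NA_integer_)
  }
}

#' Cluster a community's phenotypes
#'
#' Single-linkage agglomerative clustering on Euclidean distance in
#' trait space, cut at `cutoff` (default 0.2: well above the width of a
#' mutation-selection cloud and well below the inter-vertex distance).
#' Each cluster is summarised by its density-weighted mean phenotype,
#' total density, strain count and specialist classification.
#'
#' @param state A [community_state()] (non-empty).
#' @param spec A [tradeoff_spec()].
#' @param cutoff Single-linkage distance cutoff.
#' @param threshold Specialist budget-share threshold, passed to
#'   [classify_specialist()].
#' @return Object of class `"cluster_summary"`: a list with `clusters`
#'   (data frame: cluster, total_density, n_strains, specialist,
#'   resource), `centers` (matrix of cluster centers), `membership`
#'   (per-strain cluster assignment) and `cutoff`. Clusters are ordered
#'   by decreasing total density.
#' @export
cluster_phenotypes <- function(state, spec, cutoff = 0.2, threshold = 0.9) {
  if (nrow(state$alpha) == 0)
    stop("cannot cluster an empty community", call. = FALSE)
  S <- nrow(state$alpha)
  memb <- if (S == 1) 1L else
    stats::cutree(stats::hclust(stats::dist(state$alpha),
                                method = "single"), h = cutoff)
  ks <- sort(unique(memb))
  centers <- matrix(NA_real_, length(ks), ncol(state$alpha))
  dens <- numeric(length(ks)); nstr <- integer(length(ks))
  specs <- logical(length(ks)); resrc <- integer(length(ks))
  for (i in seq_along(ks)) {
    sel <- memb == ks[i]
    w <- state$density[sel]
    centers[i, ] <- as.numeric(
      crossprod(state$alpha[sel, , drop = FALSE], w)) / sum(w)
    dens[i] <- sum(w)
    nstr[i] <- sum(sel)
    cl <- classify_specialist(centers[i, ], spec, threshold)
    specs[i] <- cl$specialist
    resrc[i] <- cl$resource
  }
  ord <- order(dens, decreasing = TRUE)
  remap <- match(memb, ks[ord])
  structure(list(clusters = data.frame(cluster = seq_along(ks),
                                       total_density = dens[ord],
                                       n_strains = nstr[ord],
                                       specialist = specs[ord],
                                       resource = resrc[ord]),
                 centers = centers[ord, , drop = FALSE],
                 membership = remap, cutoff = cutoff),
            class = "cluster_summary")
}

#' @export
print.cluster_summary <- function(x, ...) {
  cat("Phenotype clusters (single linkage, cutoff ", x$cutoff, ")\n",
      sep = "")
  print(cbind(x$clusters, round(x$centers, 4)), row.names = FALSE)
  invisible(x)
}

#' Pure-ecology community assembly from random phenotypes
#'
#' Seeds the system with `n_species` phenotypes drawn uniformly on the
#' budget-share simplex (Dirichlet(1, ..., 1), mapped back through the
#' componentwise power `1/gamma_j`), then runs the population dynamics
#' with mutation switched off: to stationarity under the chemostat, or
#' to a periodic steady state under serial dilution. Strains falling
#' below the extinction threshold are culled along the way.
#'
#' @param n_species Number of random founder species.
#' @param spec A [tradeoff_spec()].
#' @param env An [environment_spec()].
#' @param ctrl An [integration_control()].
#' @param protocol Optional [dilution_protocol()]; `NULL` runs the
#'   chemostat.
#' @param max_time Chemostat time budget (default `2e5`, long enough for
#'   the slow quasi-neutral sorting close to the singular strategy to
#'   complete).
#' @param max_batches Dilution-cycle budget (default 400).
#' @param cutoff,threshold Clustering parameters, see
#'   [cluster_phenotypes()].
#' @param seed Optional integer seed for the founder draw.
#' @return List with `summary` (a [cluster_phenotypes()] result on the
#'   survivors), `n_survivors` (number of surviving strains), `state`
#'   (final community) and `stationary`/`periodic` diagnostics.
#' @export
ecological_assembly <- function(n_species, spec, env,
                                ctrl = integration_control(),
                                protocol = NULL, max_time = 2e5,
                                max_batches = 400L, cutoff = 0.2,
                                threshold = 0.9, seed = NULL) {
  if (n_species < 1) stop("`n_species` must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  p <- spec$p
  x <- matrix(stats::rexp(n_species * p), n_species, p)
  x <- x / rowSums(x)
  alpha <- matrix(0, n_species, p)
  for (j in seq_len(p))
    alpha[, j] <- (spec$budget * x[, j]) ^ (1 / spec$gamma[j])
  if (is.null(protocol)) {
    n0 <- if (env$death_rate > 0) sum(env$supply) / env$death_rate else 1
    state <- community_state(alpha, density = rep(n0 / n_species, n_species),
                             conc = env$monod_K)
    res <- chemostat_stationary(state, env, ctrl, max_time = max_time)
    state <- res$state
    diag_flag <- list(stationary = res$stationary)
  } else {
    state <- community_state(alpha,
                             density = rep(protocol$rho0 / n_species,
                                           n_species),
                             conc = protocol$c_init)
    nmin <- 1e-9 * protocol$rho0
    prev <- NULL
    periodic <- FALSE
    for (b in seq_len(max_batches)) {
      res <- run_batch(state, protocol, env, ctrl)
      state <- .cull(dilute(res$state, protocol), nmin)$state
      cur <- state$density
      if (!is.null(prev) && length(prev) == length(cur) &&
          sqrt(sum((cur - prev)^2)) <= 1e-6 * sqrt(sum(prev^2))) {
        periodic <- TRUE
        break
      }
      prev <- cur
    }
    diag_flag <- list(periodic = periodic)
  }
  summary <- cluster_phenotypes(state, spec, cutoff, threshold)
  c(list(summary = summary, n_survivors = nrow(state$alpha),
         state = state), diag_flag)
}
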