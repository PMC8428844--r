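#' Serial-dilution protocol
#'
#' Parameters of the batch-growth/dilution cycle: each batch starts from a
#' total inoculum density `rho0` in fresh medium `c_init`, grows with no
#' death and no resource decay, and ends when the total resource
#' concentration is depleted to `c_fin`, after which the community is
#' diluted back to `rho0` and the cycle repeats.
#'
#' @param c_init Length-`p` fresh-batch resource concentrations
#'   \eqn{c_j(0)}.
#' @param rho0 Total inoculum density \eqn{\rho_0} (default `1e-3`).
#' @param c_fin Depletion threshold on \eqn{\sum_j c_j} ending a batch
#'   (default `1e-8`); must be well below `sum(c_init)`.
#' @param n_batches Number of batches for [run_serial()] (default 1).
#' @return Object of class `"dilution_protocol"`.
#' @examples
#' dilution_protocol(c_init = c(1, 1, 1))
#' @export
dilution_protocol <- function(c_init, rho0 = 1e-3, c_fin = 1e-8,
                              n_batches = 1L) {
  c_init <- as.numeric(c_init)
  if (any(c_init < 0) || sum(c_init) <= 0)
    stop("`c_init` must be non-negative with a positive total", call. = FALSE)
  if (rho0 <= 0) stop("`rho0` must be positive", call. = FALSE)
  if (c_fin <= 0 || c_fin >= 0.01 * sum(c_init))
    stop("`c_fin` must be positive and well below sum(c_init)",
         call. = FALSE)
  if (n_batches < 1) stop("`n_batches` must be >= 1", call. = FALSE)
  structure(list(c_init = c_init, rho0 = rho0, c_fin = c_fin,
                 n_batches = as.integer(n_batches),
                 p = length(c_init)),
            class = "dilution_protocol")
}

# batch-phase environment: no supply, no decay, no death
.batch_env <- function(env) {
  environment_spec(supply = rep(0, env$p), monod_K = env$monod_K,
                   decay = 0, death_rate = 0,
                   uptake_exponent = env$uptake_exponent)
}

#' Run a single growth batch to resource depletion
#'
#' Integrates the batch equations (growth mirrored by consumption, with
#' death and decay switched off) from fresh medium `protocol$c_init`
#' until the first time \eqn{\sum_j c_j(t) \le c_{fin}}, located by the
#' solver's root finder.
#'
#' @param state A [community_state()]; its concentrations are replaced by
#'   `protocol$c_init` at batch start.
#' @param protocol A [dilution_protocol()].
#' @param env An [environment_spec()] supplying the Monod constants and
#'   uptake exponents. Death and decay are zeroed internally, per the
#'   batch model.
#' @param ctrl An [integration_control()]; `ctrl$max_time` bounds the
#'   batch duration (a batch that cannot deplete its resources raises a
#'   stalled-batch error).
#' @param times Optional vector of output times (checkpoints) at which the
#'   trajectory is also reported; used e.g. to audit the within-batch
#'   conservation law.
#' @return List with elements `state` (at depletion, time advanced by
#'   `t_fin`), `t_fin`, and `path` (deSolve output matrix when `times`
#'   is supplied, else `NULL`).
#' @export
run_batch <- function(state, protocol, env, ctrl = integration_control(),
                      times = NULL) {
  if (nrow(state$alpha) == 0 || sum(state$density) <= 0 ||
      all(.effective_alpha(state$alpha, env$uptake_exponent) == 0))
    stop("empty inoculum: nothing can consume the batch resources",
         call. = FALSE)
  benv <- .batch_env(env)
  ae <- .effective_alpha(state$alpha, benv$uptake_exponent)
  tgrid <- sort(unique(c(0, times, ctrl$max_time)))
  out <- .ode_run(state$density, protocol$c_init, ae, benv,
                  times = tgrid, ctrl, c_fin = protocol$c_fin)
  troot <- attr(out, "troot")
  if (is.null(troot) || length(troot) == 0)
    stop("stalled batch: resources not depleted to c_fin within max_time",
         call. = FALSE)
  fin <- unname(out[nrow(out), -1])
  S <- length(state$density)
  state$density <- pmax(fin[seq_len(S)], 0)
  state$conc <- pmax(fin[S + seq_len(protocol$p)], 0)
  state$time <- state$time + troot[1]
  list(state = state, t_fin = troot[1],
       path = if (is.null(times)) NULL else out)
}

#' Dilute a community into fresh medium
#'
#' Rescales densities to a total of `rho0`, preserving relative
#' abundances (\eqn{n_a(0) = \rho_0 n_a(t_{fin}) / \sum_a n_a(t_{fin})}),
#' and resets concentrations to `c_init`.
#'
#' @inheritParams run_batch
#' @return The diluted [community_state()].
#' @examples
#' st <- community_state(matrix(c(1, 0, 0, 1), 2, byrow = TRUE),
#'                       density = c(6, 4), conc = c(0, 0))
#' dilute(st, dilution_protocol(c_init = c(1, 1)))$density  # 6e-4, 4e-4
#' @export
dilute <- function(state, protocol) {
  tot <- sum(state$density)
  if (tot <= 0)
    stop("cannot dilute a community with zero total density", call. = FALSE)
  state$density <- protocol$rho0 * state$density / tot
  state$conc <- protocol$c_init
  state
}

#' Run a serial-dilution experiment
#'
#' Alternates [run_batch()] and [dilute()] for `protocol$n_batches`
#' cycles. Strains whose post-dilution density falls below
#' `1e-9 * rho0` are removed.
#'
#' @inheritParams run_batch
#' @return List with elements `snapshots` (end-of-batch
#'   [community_state()]s), `t_fin` (per-batch depletion times), `final`
#'   (the post-dilution state after the last batch) and `periodic`
#'   (`TRUE` when the end-of-batch abundance vector changed by less than
#'   `1e-6` relative between the last two batches).
#' @export
run_serial <- function(state, protocol, env, ctrl = integration_control()) {
  nmin <- 1e-9 * protocol$rho0
  snapshots <- vector("list", protocol$n_batches)
  t_fin <- numeric(protocol$n_batches)
  prev <- NULL
  periodic <- FALSE
  for (b in seq_len(protocol$n_batches)) {
    res <- run_batch(state, protocol, env, ctrl)
    snapshots[[b]] <- res$state
    t_fin[b] <- res$t_fin
    cur <- res$state$density
    if (!is.null(prev) && length(prev) == length(cur)) {
      periodic <- sqrt(sum((cur - prev)^2)) <= 1e-6 * sqrt(sum(prev^2))
    }
    prev <- cur
    state <- dilute(res$state, protocol)
    state <- .cull(state, nmin)$state
  }
  list(snapshots = snapshots, t_fin = t_fin, final = state,
       periodic = periodic)
}
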