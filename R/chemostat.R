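#' Integration control settings
#'
#' Numerical settings shared by the chemostat and serial-dilution
#' integrators.
#'
#' @param rel_tol,abs_tol Relative and absolute solver tolerances
#'   (defaults `1e-8` / `1e-10`; must lie in `(0, 1e-3]`).
#' @param max_time Upper bound on integration time for open-ended runs
#'   (equilibration, batch depletion).
#' @param extinction_threshold Density below which a strain is removed at
#'   checkpoint boundaries. `NULL` (default) means the callers pick a
#'   scale-aware value: `1e-6 * sum(s)/delta` in the chemostat,
#'   `1e-9 * rho0` after a dilution.
#' @param checkpoint_interval Time between checkpoints at which extinct
#'   strains are culled and stationarity is assessed.
#' @param stationarity_tol Stationarity criterion: maximum of
#'   `|dn/dt|/n` and `|dc/dt|` must fall below this value.
#' @param max_steps Maximum internal solver steps per output interval.
#' @param method Solver for non-event integrations: `"adams"` (default;
#'   the model's per-capita rates are bounded by the budget scale and the
#'   Monod factors, so the system is non-stiff under the intended
#'   parameter ranges) or `"lsoda"` (automatic stiff switching).
#'   Depletion-event batches always use `lsodar`.
#' @return Object of class `"integration_control"`.
#' @export
integration_control <- function(rel_tol = 1e-8, abs_tol = 1e-10,
                                max_time = 1e5,
                                extinction_threshold = NULL,
                                checkpoint_interval = 100,
                                stationarity_tol = 1e-8,
                                max_steps = 100000L,
                                method = c("adams", "lsoda")) {
  method <- match.arg(method)
  if (rel_tol <= 0 || rel_tol > 1e-3 || abs_tol <= 0 || abs_tol > 1e-3)
    stop("solver tolerances must lie in (0, 1e-3]", call. = FALSE)
  if (!is.null(extinction_threshold) && extinction_threshold <= 0)
    stop("`extinction_threshold` must be positive", call. = FALSE)
  if (checkpoint_interval <= 0 || max_time <= 0)
    stop("`checkpoint_interval` and `max_time` must be positive",
         call. = FALSE)
  structure(list(rel_tol = rel_tol, abs_tol = abs_tol, max_time = max_time,
                 extinction_threshold = extinction_threshold,
                 checkpoint_interval = checkpoint_interval,
                 stationarity_tol = stationarity_tol,
                 max_steps = as.integer(max_steps), method = method),
            class = "integration_control")
}

#' Right-hand side of the chemostat dynamics
#'
#' Reference (pure R) evaluation of the coupled resource/population
#' equations
#' \deqn{dc_j/dt = s_j - \left(\sum_a n_a \alpha_{aj}^{q_j}\right) r_j(c_j)
#'       - \mu_j c_j,}
#' \deqn{dn_a/dt = \left(\sum_j \alpha_{aj}^{q_j} r_j(c_j) - \delta\right)
#'       n_a.}
#' The compiled integrator uses an identical C implementation; this
#' function is the readable mirror used for stationarity checks and as an
#' independent oracle in tests.
#'
#' @param state A [community_state()].
#' @param env An [environment_spec()].
#' @return List with elements `dn` (length `S`) and `dc` (length `p`).
#' @export
chemostat_derivatives <- function(state, env) {
  ae <- .effective_alpha(state$alpha, env$uptake_exponent)
  r <- monod_uptake(pmax(state$conc, 0), env$monod_K)
  load <- as.numeric(crossprod(ae, state$density)) # sum_a n_a alpha^q per j
  dc <- env$supply - load * r - env$decay * state$conc
  dn <- (as.numeric(ae %*% r) - env$death_rate) * state$density
  list(dn = dn, dc = dc)
}

# Low-level integration of (n, c) with the compiled RHS.
# Returns the deSolve output matrix. `c_fin >= 0` enables the depletion
# root (lsodar); otherwise plain lsoda is used.
.ode_run <- function(density, conc, alpha_eff, env, times, ctrl,
                     c_fin = NULL) {
  S <- length(density)
  p <- length(conc)
  parms <- c(p, S, env$death_rate, if (is.null(c_fin)) -1 else c_fin,
             env$supply, env$monod_K, env$decay, as.double(alpha_eff))
  .Call("crevo_set_parms", as.double(parms), PACKAGE = "crevo")
  y <- c(density, conc)
  out <- if (is.null(c_fin)) {
    if (identical(ctrl$method, "lsoda")) {
      deSolve::lsoda(y = y, times = times, func = "crevo_derivs",
                     parms = NULL, dllname = "crevo", initfunc = NULL,
                     rtol = ctrl$rel_tol, atol = ctrl$abs_tol,
                     maxsteps = ctrl$max_steps)
    } else {
      deSolve::lsode(y = y, times = times, func = "crevo_derivs",
                     parms = NULL, dllname = "crevo", initfunc = NULL,
                     mf = 10, rtol = ctrl$rel_tol, atol = ctrl$abs_tol,
                     maxsteps = ctrl$max_steps)
    }
  } else {
    deSolve::lsodar(y = y, times = times, func = "crevo_derivs",
                    rootfunc = "crevo_root", nroot = 1,
                    parms = NULL, dllname = "crevo", initfunc = NULL,
                    rtol = ctrl$rel_tol, atol = ctrl$abs_tol,
                    maxsteps = ctrl$max_steps)
  }
  istate <- attr(out, "istate")[1]
  if (!is.null(istate) && istate < 0) {
    last <- out[nrow(out), ]
    cond <- structure(
      class = c("crevo_integration_error", "error", "condition"),
      list(message = paste0("ODE integration failed (istate = ", istate,
                            ") at t = ", signif(last[1], 8)),
           call = sys.call(-1), last_state = last))
    stop(cond)
  }
  out
}

.cull <- function(state, threshold) {
  keep <- state$density >= threshold
  if (!any(keep)) keep[which.max(state$density)] <- TRUE
  if (all(keep)) return(list(state = state, extinct = integer(0)))
  extinct <- state$ids[!keep]
  state$alpha <- state$alpha[keep, , drop = FALSE]
  state$density <- state$density[keep]
  state$ids <- state$ids[keep]
  list(state = state, extinct = extinct)
}

.default_nmin_chemostat <- function(env, ctrl) {
  if (!is.null(ctrl$extinction_threshold)) return(ctrl$extinction_threshold)
  if (env$death_rate > 0) 1e-6 * sum(env$supply) / env$death_rate else 1e-6
}

#' Integrate a chemostat community forward in time
#'
#' Advances the community by `duration` using an adaptive, stiffness-aware
#' solver (deSolve's `lsoda`) on the compiled right-hand side. Strains
#' whose density falls below the extinction threshold are removed at
#' checkpoint boundaries; tiny negative solver undershoots are clipped to
#' zero there as well.
#'
#' @param state A [community_state()].
#' @param env An [environment_spec()].
#' @param ctrl An [integration_control()].
#' @param duration Positive time span to integrate.
#' @return The updated [community_state()].
#' @examples
#' env <- environment_spec(supply = c(1, 1, 1), monod_K = 1, decay = 0.1,
#'                         death_rate = 0.25)
#' st <- community_state(rep(1 / 3, 3), density = 1, conc = c(1, 1, 1))
#' chemostat_integrate(st, env, integration_control(), duration = 50)
#' @export
chemostat_integrate <- function(state, env, ctrl = integration_control(),
                                duration) {
  stopifnot(duration > 0)
  nmin <- .default_nmin_chemostat(env, ctrl)
  remaining <- duration
  while (remaining > 1e-12) {
    step <- min(ctrl$checkpoint_interval, remaining)
    if (nrow(state$alpha) > 0) {
      ae <- .effective_alpha(state$alpha, env$uptake_exponent)
    } else {
      ae <- matrix(0, 0, env$p)
    }
    out <- .ode_run(state$density, state$conc, ae, env,
                    times = c(0, step), ctrl)
    fin <- unname(out[nrow(out), -1])
    S <- length(state$density)
    state$density <- pmax(fin[seq_len(S)], 0)
    state$conc <- pmax(fin[S + seq_len(env$p)], 0)
    state$time <- state$time + step
    state <- .cull(state, nmin)$state
    remaining <- remaining - step
  }
  state
}

#' Relax a chemostat community to ecological stationarity
#'
#' Integrates in checkpoint-sized chunks (culling extinct strains at each
#' checkpoint) until the stationarity criterion
#' `max(|dn/dt|/n, |dc/dt|) < stationarity_tol` is met or `max_time` is
#' exhausted.
#'
#' @inheritParams chemostat_integrate
#' @param max_time Optional override of `ctrl$max_time`.
#' @return List with elements `state`, `stationary` (logical) and
#'   `residual` (the final stationarity measure).
#' @export
chemostat_stationary <- function(state, env, ctrl = integration_control(),
                                 max_time = NULL) {
  if (is.null(max_time)) max_time <- ctrl$max_time
  elapsed <- 0
  repeat {
    d <- chemostat_derivatives(state, env)
    res <- max(c(abs(d$dn) / pmax(state$density, 1e-300), abs(d$dc)))
    if (res < ctrl$stationarity_tol)
      return(list(state = state, stationary = TRUE, residual = res))
    if (elapsed >= max_time)
      return(list(state = state, stationary = FALSE, residual = res))
    step <- min(ctrl$checkpoint_interval, max_time - elapsed)
    state <- chemostat_integrate(state, env, ctrl, step)
    elapsed <- elapsed + step
  }
}

#' Closed-form monomorphic equilibrium without resource decay
#'
#' For a single resident strain with \eqn{\mu_j = 0} the stationary state
#' of the chemostat equations has the closed form
#' \deqn{n^* = \sum_j s_j / \delta, \qquad
#'       r_j^* = s_j / (n^* \alpha_j^{q_j}), \qquad
#'       c_j^* = K_j r_j^* / (1 - r_j^*).}
#' The equilibrium is feasible only when every \eqn{r_j^* < 1}: the
#' resident must be able to absorb the full supply of each resource at
#' some finite concentration.
#'
#' @param alpha Resident allocation vector; must be positive wherever the
#'   supply is positive.
#' @param env An [environment_spec()] with all decay rates equal to 0 and
#'   `death_rate > 0`.
#' @return List with elements `n_star`, `r_star`, `c_star`.
#' @examples
#' env <- environment_spec(supply = c(1, 1, 1), death_rate = 0.25)
#' resident_equilibrium_mu0(rep(1 / 3, 3), env)  # n* = 12, r* = 1/4
#' @export
resident_equilibrium_mu0 <- function(alpha, env) {
  if (any(env$decay != 0))
    stop("closed-form equilibrium requires all decay rates mu = 0",
         call. = FALSE)
  if (env$death_rate <= 0)
    stop("closed-form equilibrium requires death_rate > 0", call. = FALSE)
  ae <- alpha ^ env$uptake_exponent
  if (any(env$supply > 0 & ae == 0))
    stop("resident must allocate to every supplied resource", call. = FALSE)
  n_star <- sum(env$supply) / env$death_rate
  r_star <- ifelse(env$supply > 0, env$supply / (n_star * ae), 0)
  if (any(r_star >= 1)) {
    cond <- structure(
      class = c("crevo_infeasible_equilibrium", "error", "condition"),
      list(message = paste0(
        "infeasible resident equilibrium: required uptake factor >= 1 ",
        "for resource(s) ", paste(which(r_star >= 1), collapse = ", ")),
        call = sys.call(-1), r_star = r_star))
    stop(cond)
  }
  c_star <- env$monod_K * r_star / (1 - r_star)
  list(n_star = n_star, r_star = r_star, c_star = c_star)
}
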