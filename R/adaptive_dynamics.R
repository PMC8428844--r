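# Adaptive-dynamics analytics on the tradeoff surface: singular strategy,
# invasion fitness, selection gradient, convergence/evolutionary stability.

# Orthonormal basis of the tangent space of the constraint surface at
# `alpha` (columns of a p x (p-1) matrix). The constraint normal is
# grad of sum(alpha^gamma): (gamma_j alpha_j^(gamma_j - 1)). The
# orthogonal complement is taken from a (deterministic) Householder QR.
.tangent_basis <- function(alpha, spec) {
  nrm <- spec$gamma * alpha ^ (spec$gamma - 1)
  nrm <- nrm / sqrt(sum(nrm^2))
  Q <- qr.Q(qr(matrix(nrm, ncol = 1)), complete = TRUE)
  Q[, -1, drop = FALSE]
}

# Equilibrium uptake factors r_j(c*) of a monomorphic resident: closed
# form when all decay rates are 0, otherwise by numerically relaxing the
# resident community to stationarity.
.resident_uptake <- function(resident, env, ctrl = integration_control()) {
  if (all(env$decay == 0)) {
    return(resident_equilibrium_mu0(resident, env)$r_star)
  }
  n0 <- if (env$death_rate > 0) sum(env$supply) / env$death_rate else 1
  st <- community_state(resident, density = n0, conc = env$monod_K)
  res <- chemostat_stationary(st, env, ctrl)
  if (!res$stationary)
    warning("resident equilibrium reached max_time with residual ",
            signif(res$residual, 3), call. = FALSE)
  monod_uptake(res$state$conc, env$monod_K)
}

#' Singular strategy of the adaptive dynamics
#'
#' The strategy at which the selection gradient along the tradeoff
#' surface vanishes. Without resource decay it has the closed form
#' \deqn{\alpha_j^* = \left(\frac{E\, q_j s_j / \gamma_j}
#'       {\sum_k q_k s_k / \gamma_k}\right)^{1/\gamma_j},}
#' which for a uniform exponent \eqn{\gamma} and unit budget and uptake
#' exponents reduces to \eqn{\alpha_j^* = (s_j / \sum_k s_k)^{1/\gamma}}.
#' The result satisfies the tradeoff constraint identically.
#'
#' @param supply Length-`p` supply vector, at least one entry positive.
#' @param spec A [tradeoff_spec()].
#' @param uptake_exponent Optional uptake exponents `q` (default 1).
#' @return The singular allocation vector \eqn{\alpha^*}.
#' @examples
#' singular_point(c(1, 1, 1), tradeoff_spec(0.5, p = 3))  # rep(1/9, 3)
#' singular_point(c(2, 1, 1), tradeoff_spec(1, p = 3))    # 0.5 0.25 0.25
#' @export
singular_point <- function(supply, spec, uptake_exponent = NULL) {
  supply <- as.numeric(supply)
  if (any(supply < 0) || all(supply == 0))
    stop("`supply` must be non-negative with at least one positive entry",
         call. = FALSE)
  if (is.null(uptake_exponent)) uptake_exponent <- rep(1, spec$p)
  if (length(uptake_exponent) == 1L)
    uptake_exponent <- rep(uptake_exponent, spec$p)
  w <- uptake_exponent * supply / spec$gamma
  (spec$budget * w / sum(w)) ^ (1 / spec$gamma)
}

#' Invasion fitness of a rare mutant
#'
#' Per-capita growth rate of a rare mutant strategy in the stationary
#' environment set by a monomorphic resident:
#' \deqn{f(\alpha' ; \alpha) = \sum_j (\alpha'_j)^{q_j} r_j(c^*_j) -
#'       \delta.}
#' With zero resource decay the resident equilibrium is taken in closed
#' form ([resident_equilibrium_mu0()]); otherwise the resident is relaxed
#' to stationarity numerically.
#'
#' @param mutant,resident Allocation vectors.
#' @param env An [environment_spec()].
#' @param ctrl An [integration_control()] (used only on the numerical
#'   path).
#' @return Scalar invasion fitness; 0 for `mutant == resident`.
#' @export
invasion_fitness <- function(mutant, resident, env,
                             ctrl = integration_control()) {
  r_star <- .resident_uptake(resident, env, ctrl)
  sum(mutant ^ env$uptake_exponent * r_star) - env$death_rate
}

# fitness of a tangent displacement u (length p-1) around `center`,
# with the mutant re-projected onto the constraint surface
.fitness_on_surface <- function(u, center, B, r_star, env, spec) {
  m <- project_to_constraint(pmax(center + as.numeric(B %*% u), 0), spec)
  sum(m ^ env$uptake_exponent * r_star) - env$death_rate
}

# tangent gradient of invasion fitness in the mutant at mutant = resident,
# returned as a p-vector lying in the tangent space at `resident`
.surface_gradient <- function(resident, env, spec, step = 1e-6,
                              ctrl = integration_control(),
                              r_star = NULL) {
  if (is.null(r_star)) r_star <- .resident_uptake(resident, env, ctrl)
  B <- .tangent_basis(resident, spec)
  k <- ncol(B)
  g <- numeric(k)
  boundary <- any(resident < 10 * step)
  for (i in seq_len(k)) {
    e <- rep(0, k); e[i] <- step
    if (boundary) {
      f0 <- .fitness_on_surface(rep(0, k), resident, B, r_star, env, spec)
      fp <- .fitness_on_surface(e, resident, B, r_star, env, spec)
      g[i] <- (fp - f0) / step
    } else {
      fp <- .fitness_on_surface(e, resident, B, r_star, env, spec)
      fm <- .fitness_on_surface(-e, resident, B, r_star, env, spec)
      g[i] <- (fp - fm) / (2 * step)
    }
  }
  if (boundary)
    warning("resident at the trait-space boundary: one-sided differences",
            call. = FALSE)
  out <- as.numeric(B %*% g)
  attr(out, "basis") <- B
  attr(out, "coords") <- g
  out
}

#' Selection gradient along the tradeoff surface
#'
#' Gradient of the invasion fitness in the mutant, evaluated at
#' `mutant = resident` and projected onto the tangent space of the
#' constraint manifold, computed by central finite differences in an
#' orthonormal tangent basis (mutants re-projected onto the surface).
#' At a boundary resident one-sided differences are used, with a warning.
#'
#' @param resident Resident allocation vector (interior points give
#'   central differences).
#' @param env An [environment_spec()].
#' @param spec A [tradeoff_spec()].
#' @param step Finite-difference step (default `1e-6`).
#' @param ctrl An [integration_control()] for the numerical equilibrium
#'   path.
#' @return Length-`(p-1)` numeric vector of tangent coordinates, with
#'   attributes `basis` (the tangent basis used) and `gradient` (the
#'   corresponding p-vector in trait space).
#' @examples
#' env <- environment_spec(supply = c(1, 1, 1), death_rate = 0.25)
#' sp <- tradeoff_spec(0.9, p = 3)
#' g <- selection_gradient(singular_point(env$supply, sp), env, sp)
#' sqrt(sum(g^2))  # ~0 at the singular strategy
#' @export
selection_gradient <- function(resident, env, spec, step = 1e-6,
                               ctrl = integration_control()) {
  gvec <- .surface_gradient(resident, env, spec, step, ctrl)
  out <- attr(gvec, "coords")
  attributes(gvec) <- NULL
  attr(out, "basis") <- .tangent_basis(resident, spec)
  attr(out, "gradient") <- gvec
  out
}

#' Classify the singular strategy
#'
#' Computes, at the singular strategy \eqn{\alpha^*}: the Hessian of the
#' invasion fitness in the mutant restricted to the constraint tangent
#' space (central second differences of the on-surface fitness), whose
#' eigenvalue signs decide evolutionary stability; and the Jacobian of
#' the selection gradient with respect to the resident position on the
#' surface, whose eigenvalue real parts decide convergence stability.
#'
#' Classification rule (tolerance `tol = 1e-8 * delta`): all Hessian
#' eigenvalues < `-tol` gives `"ess_endpoint"`; any eigenvalue > `tol`
#' gives `"branching_point"`; all within `±tol` gives `"neutral"`;
#' anything else `"mixed"`. Per-direction branching flags report the
#' curvature sign along each resource direction projected onto the
#' tangent space (relevant for heterogeneous exponents, where branching
#' is expected exactly along directions with \eqn{\gamma_j < 1}).
#'
#' @param env An [environment_spec()]; the closed-form equilibrium is
#'   used when all decay rates are 0, otherwise the resident is
#'   equilibrated numerically (approximate).
#' @param spec A [tradeoff_spec()].
#' @param gradient_step Finite-difference step for first derivatives
#'   (default `1e-6`).
#' @param hessian_step Step for second differences and for resident
#'   displacements in the Jacobian (default `1e-3`, chosen so that
#'   round-off in the second differences stays well below the neutrality
#'   tolerance at `gamma = 1`).
#' @param ctrl An [integration_control()].
#' @return Object of class `"singular_point_report"`: a list with
#'   `alpha_star`, `hessian`, `hessian_eigs`, `jacobian`,
#'   `jacobian_eigs`, `classification`, `per_direction` (logical
#'   branching flags per resource direction), `per_direction_curvature`
#'   and `tol`.
#' @examples
#' env <- environment_spec(supply = c(1, 1, 1), death_rate = 0.25)
#' classify_singular_point(env, tradeoff_spec(0.9, p = 3))
#' @export
classify_singular_point <- function(env, spec, gradient_step = 1e-6,
                                    hessian_step = 1e-3,
                                    ctrl = integration_control()) {
  if (any(env$supply <= 0))
    stop("classification requires a strictly positive supply vector",
         call. = FALSE)
  astar <- singular_point(env$supply, spec, env$uptake_exponent)
  r_star <- .resident_uptake(astar, env, ctrl)
  B <- .tangent_basis(astar, spec)
  k <- ncol(B)
  h <- hessian_step
  phi <- function(u) .fitness_on_surface(u, astar, B, r_star, env, spec)
  f0 <- phi(rep(0, k))

  H <- matrix(0, k, k)
  for (i in seq_len(k)) {
    ei <- rep(0, k); ei[i] <- h
    H[i, i] <- (phi(ei) - 2 * f0 + phi(-ei)) / h^2
    if (i < k) for (j in seq((i + 1), k)) {
      ej <- rep(0, k); ej[j] <- h
      H[i, j] <- H[j, i] <-
        (phi(ei + ej) - phi(ei - ej) - phi(-ei + ej) + phi(-ei - ej)) /
        (4 * h^2)
    }
  }
  hessian_eigs <- eigen(H, symmetric = TRUE, only.values = TRUE)$values

  # curvature along each resource direction projected onto the tangent
  Pmat <- B %*% t(B)
  curv <- rep(NA_real_, spec$p)
  for (j in seq_len(spec$p)) {
    v <- Pmat[, j]
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) next
    u <- as.numeric(crossprod(B, v / nv))
    curv[j] <- (phi(h * u) - 2 * f0 + phi(-h * u)) / h^2
  }

  # Jacobian of the selection gradient w.r.t. resident displacement on
  # the surface, in the fixed tangent basis at alpha*
  J <- matrix(0, k, k)
  G_at <- function(u) {
    res <- project_to_constraint(pmax(astar + as.numeric(B %*% u), 0), spec)
    gvec <- .surface_gradient(res, env, spec, gradient_step, ctrl)
    as.numeric(crossprod(B, gvec))
  }
  for (i in seq_len(k)) {
    e <- rep(0, k); e[i] <- h
    J[, i] <- (G_at(e) - G_at(-e)) / (2 * h)
  }
  jacobian_eigs <- eigen(J, only.values = TRUE)$values

  tol <- 1e-8 * max(env$death_rate, .Machine$double.eps)
  classification <- if (all(hessian_eigs < -tol)) {
    "ess_endpoint"
  } else if (any(hessian_eigs > tol)) {
    "branching_point"
  } else if (all(abs(hessian_eigs) <= tol)) {
    "neutral"
  } else {
    "mixed"
  }

  structure(list(alpha_star = astar, hessian = H,
                 hessian_eigs = hessian_eigs, jacobian = J,
                 jacobian_eigs = jacobian_eigs,
                 classification = classification,
                 per_direction = !is.na(curv) & curv > tol,
                 per_direction_curvature = curv, tol = tol,
                 approximate = any(env$decay != 0)),
            class = "singular_point_report")
}

#' @export
print.singular_point_report <- function(x, ...) {
  cat("Singular strategy report", if (x$approximate)
    "(numerical equilibrium, mu > 0: approximate)" else "", "\n")
  cat("  alpha* =", paste(signif(x$alpha_star, 6), collapse = ", "), "\n")
  cat("  classification:", x$classification, "\n")
  cat("  Hessian eigenvalues:",
      paste(signif(x$hessian_eigs, 4), collapse = ", "), "\n")
  cat("  Jacobian eigenvalue real parts:",
      paste(signif(Re(x$jacobian_eigs), 4), collapse = ", "), "\n")
  cat("  branching directions:",
      if (any(x$per_direction)) paste(which(x$per_direction),
                                      collapse = ", ") else "none", "\n")
  invisible(x)
}
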