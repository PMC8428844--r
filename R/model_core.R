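#' Tradeoff specification
#'
#' Defines the constraint manifold of permissible allocation strategies,
#' \deqn{\sum_j \alpha_j^{\gamma_j} = E,}
#' where the exponents \eqn{\gamma_j > 0} set the curvature of the tradeoff
#' (concave for \eqn{\gamma < 1}, linear for \eqn{\gamma = 1}, convex for
#' \eqn{\gamma > 1}) and \eqn{E > 0} is the total metabolic budget.
#'
#' @param gamma Tradeoff exponent(s): a positive scalar (broadcast to all
#'   resource directions) or a length-`p` vector of per-direction exponents.
#' @param p Number of resources. Defaults to `length(gamma)`; must be given
#'   when `gamma` is scalar.
#' @param budget Total budget `E` (default 1).
#'
#' @return An object of class `"tradeoff_spec"`: a list with elements
#'   `gamma` (length-`p` numeric), `budget` and `p`.
#' @examples
#' tradeoff_spec(0.9, p = 3)
#' tradeoff_spec(c(0.9, 1.1, 1.1))
#' @export
tradeoff_spec <- function(gamma, p = length(gamma), budget = 1) {
  gamma <- as.numeric(gamma)
  if (length(gamma) == 1L) gamma <- rep(gamma, p)
  if (length(gamma) != p)
    stop("`gamma` must be scalar or of length p = ", p, call. = FALSE)
  if (any(!is.finite(gamma)) || any(gamma <= 0))
    stop("all tradeoff exponents `gamma` must be positive", call. = FALSE)
  if (!is.finite(budget) || budget <= 0)
    stop("`budget` must be a positive number", call. = FALSE)
  structure(list(gamma = gamma, budget = as.numeric(budget), p = as.integer(p)),
            class = "tradeoff_spec")
}

#' @export
print.tradeoff_spec <- function(x, ...) {
  cat("Tradeoff surface: sum(alpha^gamma) =", x$budget, "\n")
  cat("  p =", x$p, " gamma =", paste(signif(x$gamma, 6), collapse = ", "), "\n")
  invisible(x)
}

.uniform_gamma <- function(spec) {
  g <- spec$gamma
  all(abs(g - g[1]) <= 1e-14 * max(1, abs(g[1])))
}

#' Environment specification
#'
#' Collects the abiotic parameters of the consumer-resource model: supply
#' rates `s`, Monod half-saturation constants `K`, resource decay rates
#' `mu`, the common per-capita death rate `delta`, and optional uptake
#' exponents `q` (uptake proportional to \eqn{\alpha_j^{q_j}}; `q = 1`
#' recovers uptake linear in the allocation).
#'
#' @param supply Length-`p` non-negative supply rates \eqn{s_j}.
#' @param monod_K Length-`p` positive Monod constants \eqn{K_j} (scalar
#'   broadcast).
#' @param decay Length-`p` non-negative decay rates \eqn{\mu_j} (scalar
#'   broadcast). Use 0 for serial-dilution batches.
#' @param death_rate Non-negative per-capita death rate \eqn{\delta}.
#' @param uptake_exponent Length-`p` positive uptake exponents \eqn{q_j}
#'   (scalar broadcast, default 1).
#'
#' @return Object of class `"environment_spec"`.
#' @examples
#' environment_spec(supply = c(1, 1, 1), monod_K = 1, decay = 0.1,
#'                  death_rate = 0.25)
#' @export
environment_spec <- function(supply, monod_K = 1, decay = 0, death_rate = 0,
                             uptake_exponent = 1) {
  supply <- as.numeric(supply)
  p <- length(supply)
  bc <- function(x, name) {
    x <- as.numeric(x)
    if (length(x) == 1L) x <- rep(x, p)
    if (length(x) != p)
      stop("`", name, "` must be scalar or of length p = ", p, call. = FALSE)
    x
  }
  monod_K <- bc(monod_K, "monod_K")
  decay <- bc(decay, "decay")
  uptake_exponent <- bc(uptake_exponent, "uptake_exponent")
  if (any(supply < 0)) stop("supply rates must be non-negative", call. = FALSE)
  if (any(monod_K <= 0)) stop("Monod constants must be positive", call. = FALSE)
  if (any(decay < 0)) stop("decay rates must be non-negative", call. = FALSE)
  if (any(uptake_exponent <= 0))
    stop("uptake exponents must be positive", call. = FALSE)
  if (!is.finite(death_rate) || death_rate < 0)
    stop("`death_rate` must be non-negative", call. = FALSE)
  structure(list(supply = supply, monod_K = monod_K, decay = decay,
                 death_rate = as.numeric(death_rate),
                 uptake_exponent = uptake_exponent, p = as.integer(p)),
            class = "environment_spec")
}

#' @export
print.environment_spec <- function(x, ...) {
  cat("Environment: p =", x$p, "resources\n")
  cat("  s =", paste(signif(x$supply, 6), collapse = ", "), "\n")
  cat("  K =", paste(signif(x$monod_K, 6), collapse = ", "),
      " mu =", paste(signif(x$decay, 6), collapse = ", "), "\n")
  cat("  delta =", x$death_rate,
      " q =", paste(signif(x$uptake_exponent, 6), collapse = ", "), "\n")
  invisible(x)
}

#' Monod uptake function
#'
#' Saturating per-capita resource availability \eqn{r(c) = c / (K + c)},
#' strictly increasing in `c` and bounded above by 1.
#'
#' @param c Non-negative resource concentration(s).
#' @param K Positive half-saturation constant(s), recycled against `c`.
#' @return Numeric vector of uptake factors in `[0, 1)`.
#' @examples
#' monod_uptake(0, 1)   # 0
#' monod_uptake(1, 1)   # 0.5 at half-saturation
#' monod_uptake(9, 1)   # 0.9
#' @export
monod_uptake <- function(c, K) {
  if (any(c < 0)) stop("concentrations must be non-negative", call. = FALSE)
  if (any(K <= 0)) stop("Monod constants must be positive", call. = FALSE)
  c / (K + c)
}

#' Tradeoff value of an allocation vector
#'
#' Evaluates \eqn{\sum_j \alpha_j^{\gamma_j}}; a strategy lies on the
#' tradeoff surface when this equals the budget `E`. `0^gamma` is 0.
#'
#' @param alpha Length-`p` non-negative allocation vector.
#' @param spec A [tradeoff_spec()].
#' @return Non-negative scalar.
#' @examples
#' tradeoff_value(rep(1 / 3, 3), tradeoff_spec(1, p = 3))     # 1
#' tradeoff_value(rep(1 / 9, 3), tradeoff_spec(0.5, p = 3))   # 1
#' @export
tradeoff_value <- function(alpha, spec) {
  if (any(alpha < 0))
    stop("allocation components must be non-negative", call. = FALSE)
  sum(alpha ^ spec$gamma)
}

#' Project a raw allocation vector onto the tradeoff surface
#'
#' Rescales `alpha_raw` by the unique scalar \eqn{\lambda > 0} such that
#' \eqn{\sum_j (\lambda \alpha_j)^{\gamma_j} = E}. For uniform `gamma`
#' the closed form \eqn{\lambda = (E / \sum \alpha_j^\gamma)^{1/\gamma}}
#' is used; otherwise \eqn{\lambda} is bracketed and solved by
#' [stats::uniroot()] followed by Newton polishing to machine precision.
#'
#' @inheritParams tradeoff_value
#' @param alpha_raw Non-negative vector, not all zero.
#' @return Length-`p` numeric vector on the constraint surface
#'   (residual of [tradeoff_value()] below `1e-10`).
#' @examples
#' project_to_constraint(c(2, 2, 2), tradeoff_spec(1, p = 3))
#' @export
project_to_constraint <- function(alpha_raw, spec) {
  if (any(alpha_raw < 0))
    stop("allocation components must be non-negative", call. = FALSE)
  if (all(alpha_raw == 0))
    stop("cannot project the all-zero allocation onto the surface",
         call. = FALSE)
  g <- spec$gamma
  E <- spec$budget
  if (.uniform_gamma(spec)) {
    lam <- (E / sum(alpha_raw ^ g[1])) ^ (1 / g[1])
  } else {
    f <- function(l) sum((l * alpha_raw) ^ g) - E
    lo <- hi <- 1
    while (f(hi) < 0) hi <- hi * 2
    while (f(lo) > 0) lo <- lo / 2
    lam <- if (hi == lo) lo else
      stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
    # Newton polish: d/dl sum((l a)^g) = sum(g (l a)^g) / l
    for (k in 1:4) {
      val <- sum((lam * alpha_raw) ^ g)
      lam <- lam - (val - E) / (sum(g * (lam * alpha_raw) ^ g) / lam)
    }
  }
  lam * alpha_raw
}

#' Per-capita growth rate
#'
#' The per-capita birth-minus-death rate of a strategy `alpha` at resource
#' concentrations `conc`:
#' \deqn{\sum_j \alpha_j^{q_j} r_j(c_j) - \delta.}
#'
#' @param alpha Allocation vector.
#' @param conc Length-`p` resource concentrations.
#' @param env An [environment_spec()].
#' @return Scalar growth rate.
#' @examples
#' env <- environment_spec(supply = c(1, 1, 1), death_rate = 0.25)
#' growth_rate(rep(1 / 3, 3), conc = rep(1e12, 3), env)  # ~0.75
#' @export
growth_rate <- function(alpha, conc, env) {
  sum(alpha ^ env$uptake_exponent * monod_uptake(conc, env$monod_K)) -
    env$death_rate
}

#' Map a non-linear tradeoff onto an equivalent non-linear-uptake model
#'
#' A uniform tradeoff exponent \eqn{\gamma} can be transferred from the
#' constraint surface to the uptake kinetics: the transformed strategy
#' \eqn{\beta_j = \alpha_j^\gamma} lies on the *linear* surface
#' \eqn{\sum_j \beta_j = E}, and uptake exponents \eqn{q' = 1/\gamma}
#' reproduce the original per-capita growth rates
#' (\eqn{\beta_j^{1/\gamma} = \alpha_j}) for every resource state, so the
#' two representations have identical community dynamics.
#'
#' @param alpha Allocation vector on the surface of `spec`.
#' @param spec A [tradeoff_spec()] with uniform `gamma`; the source model
#'   must have uptake exponents 1.
#' @return A list with elements `alpha` (the transformed strategy
#'   \eqn{\beta}), `spec` (linear tradeoff, same budget) and
#'   `uptake_exponent` (length-`p`, all `1/gamma`).
#' @examples
#' reparametrize(rep(1 / 9, 3), tradeoff_spec(0.5, p = 3))
#' @export
reparametrize <- function(alpha, spec) {
  if (!.uniform_gamma(spec))
    stop("reparametrize() supports only a uniform tradeoff exponent",
         call. = FALSE)
  g <- spec$gamma[1]
  list(alpha = alpha ^ g,
       spec = tradeoff_spec(1, p = spec$p, budget = spec$budget),
       uptake_exponent = rep(1 / g, spec$p))
}

#' Community state
#'
#' A multi-strain community: an `S x p` matrix of allocation strategies
#' (one row per strain), strain densities, resource concentrations and a
#' clock time.
#'
#' @param alpha Numeric `S x p` matrix (or a single length-`p` vector) of
#'   allocation strategies.
#' @param density Length-`S` non-negative strain densities.
#' @param conc Length-`p` non-negative resource concentrations.
#' @param time Non-negative clock time (default 0).
#' @param ids Optional integer strain identifiers (default `1:S`).
#' @return Object of class `"community_state"`.
#' @examples
#' community_state(rep(1 / 3, 3), density = 1, conc = c(1, 1, 1))
#' @export
community_state <- function(alpha, density, conc, time = 0, ids = NULL) {
  if (!is.matrix(alpha)) alpha <- matrix(alpha, nrow = 1)
  storage.mode(alpha) <- "double"
  density <- as.numeric(density)
  conc <- as.numeric(conc)
  if (nrow(alpha) != length(density))
    stop("`density` must have one entry per strain (row of `alpha`)",
         call. = FALSE)
  if (ncol(alpha) != length(conc))
    stop("`conc` must have one entry per resource (column of `alpha`)",
         call. = FALSE)
  if (any(alpha < 0) || any(density < 0) || any(conc < 0))
    stop("strategies, densities and concentrations must be non-negative",
         call. = FALSE)
  if (time < 0) stop("`time` must be non-negative", call. = FALSE)
  if (is.null(ids)) ids <- seq_len(nrow(alpha))
  structure(list(alpha = alpha, density = density, conc = conc,
                 time = as.numeric(time), ids = as.integer(ids)),
            class = "community_state")
}

#' @export
print.community_state <- function(x, ...) {
  cat("Community state at t =", signif(x$time, 6), "\n")
  cat("  strains:", nrow(x$alpha), " total density:",
      signif(sum(x$density), 6), "\n")
  cat("  conc:", paste(signif(x$conc, 6), collapse = ", "), "\n")
  invisible(x)
}

# effective allocation matrix alpha^q (columnwise exponents)
.effective_alpha <- function(alpha, q) {
  ae <- alpha
  for (j in seq_len(ncol(alpha))) ae[, j] <- alpha[, j] ^ q[j]
  ae
}
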