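test_that("singular strategy matches the closed form", {
  expect_equal(singular_point(c(1, 1, 1), tradeoff_spec(1, p = 3)),
               rep(1 / 3, 3))
  expect_equal(singular_point(c(1, 1, 1), tradeoff_spec(0.5, p = 3)),
               rep(1 / 9, 3))
  expect_equal(singular_point(c(2, 1, 1), tradeoff_spec(1, p = 3)),
               c(0.5, 0.25, 0.25))
  expect_error(singular_point(c(0, 0, 0), tradeoff_spec(1, p = 3)),
               "positive")
  # lies on the constraint surface identically, also per-direction
  sph <- tradeoff_spec(c(0.7, 1, 1.4))
  a <- singular_point(c(3, 1, 2), sph)
  expect_lt(abs(tradeoff_value(a, sph) - 1), 1e-12)
})

test_that("invasion fitness has the closed-form structure without decay", {
  env <- mu0_env(delta = 0.25)
  res1 <- rep(1 / 3, 3)
  expect_equal(invasion_fitness(res1, res1, env), 0)
  # linear tradeoff: a pure specialist is exactly neutral against the
  # central resident (evolutionary neutrality at gamma = 1)
  expect_equal(invasion_fitness(c(1, 0, 0), res1, env), 0, tolerance = 1e-14)
  # gamma = 0.9: vertex mutant invades the singular resident,
  # f = delta * ((1/3) * 3^(1/0.9) - 1)
  sp <- tradeoff_spec(0.9, p = 3)
  r09 <- singular_point(env$supply, sp)
  expect_equal(invasion_fitness(c(1, 0, 0), r09, env),
               0.25 * ((1 / 3) * 3 ^ (1 / 0.9) - 1), tolerance = 1e-12)
  expect_gt(invasion_fitness(c(1, 0, 0), r09, env), 0)
})

test_that("invasion fitness equals the analytic resident-ratio formula", {
  set.seed(5)
  env <- mu0_env(delta = 0.25)
  sp <- tradeoff_spec(0.9, p = 3)
  for (rep in 1:10) {
    # residents drawn away from the simplex edge so that the mu = 0
    # equilibrium stays feasible (r* < 1)
    res <- project_to_constraint(stats::runif(3, 0.5, 1.5), sp)
    mut <- project_to_constraint(stats::rexp(3) + 0.05, sp)
    f <- invasion_fitness(mut, res, env)
    oracle <- 0.25 * (sum((mut / res) * (env$supply / sum(env$supply))) - 1)
    expect_equal(f, oracle, tolerance = 1e-10)
  }
})

test_that("selection gradient vanishes at the singular strategy", {
  env <- mu0_env(delta = 0.25)
  for (g in c(0.7, 0.9, 1, 1.1, 1.6)) {
    sp <- tradeoff_spec(g, p = 3)
    gr <- selection_gradient(singular_point(env$supply, sp), env, sp)
    expect_lt(sqrt(sum(gr^2)), 1e-6)
  }
})

test_that("selection gradient points towards the singular strategy (p = 2)", {
  env <- environment_spec(supply = c(1, 1), monod_K = 1, decay = 0,
                          death_rate = 0.25)
  sp <- tradeoff_spec(1, p = 2)
  g <- selection_gradient(c(0.6, 0.4), env, sp)
  gvec <- attr(g, "gradient")
  # closed form d f / d alpha'_j = delta s_j / (alpha_j sum s): steeper
  # on the under-allocated resource, so the flow raises alpha_2
  expect_lt(gvec[1], 0)
  expect_gt(gvec[2], 0)
})

test_that("selection gradient is equivariant under resource relabelling", {
  env <- environment_spec(supply = c(2, 1, 0.5), monod_K = 1, decay = 0,
                          death_rate = 0.25)
  sp <- tradeoff_spec(0.9, p = 3)
  res <- project_to_constraint(c(0.4, 0.3, 0.3), sp)
  g1 <- attr(selection_gradient(res, env, sp), "gradient")
  perm <- c(2, 3, 1)
  env_p <- environment_spec(supply = env$supply[perm], monod_K = 1,
                            decay = 0, death_rate = 0.25)
  g2 <- attr(selection_gradient(res[perm], env_p, sp), "gradient")
  expect_equal(g1[perm], g2, tolerance = 1e-8)
})

test_that("boundary residents fall back to one-sided differences", {
  # an unsupplied resource keeps the boundary resident ecologically
  # feasible while the trait sits on the edge of the simplex
  env <- environment_spec(supply = c(1, 1, 0), monod_K = 1, decay = 0,
                          death_rate = 0.25)
  sp <- tradeoff_spec(1.2, p = 3)
  res <- project_to_constraint(c(0.7, 0.3, 0), sp)
  expect_warning(selection_gradient(res, env, sp), "boundary")
})

test_that("tradeoff curvature decides the stability classification", {
  env <- mu0_env(delta = 0.25)
  r09 <- classify_singular_point(env, tradeoff_spec(0.9, p = 3))
  expect_identical(r09$classification, "branching_point")
  expect_gt(max(r09$hessian_eigs), 0)
  r11 <- classify_singular_point(env, tradeoff_spec(1.1, p = 3))
  expect_identical(r11$classification, "ess_endpoint")
  expect_true(all(r11$hessian_eigs < 0))
  r1 <- classify_singular_point(env, tradeoff_spec(1, p = 3))
  expect_identical(r1$classification, "neutral")
  expect_true(all(abs(r1$hessian_eigs) <= r1$tol))
})

test_that("Hessian sign follows sign(1 - gamma); convergence always stable", {
  # asymmetry kept mild: at mu = 0 the singular resident is feasible
  # only while delta * x_j^(1 - 1/gamma) < 1 for every budget share x_j
  supplies <- list(rep(1, 3), c(1.2, 1, 0.9))
  for (s in supplies) {
    env <- environment_spec(supply = s, monod_K = 1, decay = 0,
                            death_rate = 0.25)
    for (g in c(0.5, 0.8, 0.9, 0.99, 1.01, 1.1, 1.5, 2)) {
      rep <- classify_singular_point(env, tradeoff_spec(g, p = 3))
      expect_identical(sign(max(rep$hessian_eigs)), sign(1 - g))
      expect_true(all(Re(rep$jacobian_eigs) < 0))
    }
  }
})

test_that("classification signs are stable under halved/doubled steps", {
  env <- mu0_env(delta = 0.25)
  for (g in c(0.9, 1.1)) {
    sp <- tradeoff_spec(g, p = 3)
    eigs <- sapply(c(5e-4, 1e-3, 2e-3), function(h)
      max(classify_singular_point(env, sp, hessian_step = h)$hessian_eigs))
    expect_true(all(sign(eigs) == sign(1 - g)))
  }
})

test_that("heterogeneous exponents flag exactly the concave directions", {
  env <- mu0_env(delta = 0.25)
  rep <- classify_singular_point(env, tradeoff_spec(c(0.9, 1.1, 1.1)))
  expect_identical(rep$per_direction, c(TRUE, FALSE, FALSE))
  expect_identical(rep$classification, "branching_point")
  # the singular strategy really is singular: gradient vanishes there
  g <- selection_gradient(rep$alpha_star, env, tradeoff_spec(c(0.9, 1.1, 1.1)))
  expect_lt(sqrt(sum(g^2)), 1e-6)
})

test_that("non-linear uptake alone restores or removes disruptive selection", {
  # linear tradeoff but uptake ~ alpha^q: effective curvature gamma/q
  env_sub <- environment_spec(supply = rep(1, 3), monod_K = 1, decay = 0,
                              death_rate = 0.25, uptake_exponent = 0.5)
  rep_sub <- classify_singular_point(env_sub, tradeoff_spec(1, p = 3))
  expect_identical(rep_sub$classification, "ess_endpoint")
  env_sup <- environment_spec(supply = rep(1, 3), monod_K = 1, decay = 0,
                              death_rate = 0.25, uptake_exponent = 2)
  rep_sup <- classify_singular_point(env_sup, tradeoff_spec(1, p = 3))
  expect_identical(rep_sup$classification, "branching_point")
})
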