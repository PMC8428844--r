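test_that("right-hand side matches hand-evaluated resource and growth terms", {
  env <- sym_env(delta = 0.25, mu = 0.1)
  st <- community_state(c(1, 0, 0), density = 1, conc = c(1, 1, 1))
  d <- chemostat_derivatives(st, env)
  # dc1 = 1 - 1*1*0.5 - 0.1*1 = 0.4 ; dn = (0.5 - 0.25)*1
  expect_equal(d$dc, c(0.4, 0.9, 0.9))
  expect_equal(d$dn, 0.25)
  # empty resources, one strain: resources fill at the supply rate
  st0 <- community_state(c(1, 0, 0), density = 0, conc = rep(0, 3))
  d0 <- chemostat_derivatives(st0, env)
  expect_equal(d0$dc, env$supply)
  expect_equal(d0$dn, 0)
  # abiotic equilibrium c = s/mu is stationary without consumers
  ste <- community_state(matrix(0, 0, 3), density = numeric(0),
                         conc = env$supply / env$decay)
  expect_equal(chemostat_derivatives(ste, env)$dc, rep(0, 3))
})

test_that("compiled integrator agrees with the R right-hand side", {
  set.seed(3)
  env <- sym_env()
  sp <- tradeoff_spec(0.9, p = 3)
  alpha <- rbind(project_to_constraint(c(1, 2, 3), sp),
                 project_to_constraint(c(3, 1, 1), sp))
  st <- community_state(alpha, density = c(2, 1), conc = c(0.5, 1, 2))
  # forward-Euler on the R derivatives as a crude short-time oracle
  h <- 1e-4
  ref <- st
  for (i in 1:100) {
    d <- chemostat_derivatives(ref, env)
    ref$density <- ref$density + h * d$dn
    ref$conc <- ref$conc + h * d$dc
  }
  got <- chemostat_integrate(st, env, integration_control(), duration = 100 * h)
  expect_equal(got$density, ref$density, tolerance = 1e-5)
  expect_equal(got$conc, ref$conc, tolerance = 1e-5)
})

test_that("an empty chemostat relaxes to the abiotic equilibrium", {
  env <- sym_env()
  st <- community_state(matrix(0, 0, 3), density = numeric(0),
                        conc = rep(0, 3))
  out <- chemostat_integrate(st, env, integration_control(), duration = 300)
  expect_equal(out$conc, env$supply / env$decay, tolerance = 1e-6)
})

test_that("two identical strains behave exactly like one merged strain", {
  env <- sym_env()
  sp <- tradeoff_spec(0.9, p = 3)
  a <- project_to_constraint(c(1, 1, 2), sp)
  split <- community_state(rbind(a, a), density = c(0.5, 0.5),
                           conc = c(1, 1, 1))
  merged <- community_state(a, density = 1, conc = c(1, 1, 1))
  ctrl <- integration_control(rel_tol = 1e-10, abs_tol = 1e-12)
  s1 <- chemostat_integrate(split, env, ctrl, 200)
  s2 <- chemostat_integrate(merged, env, ctrl, 200)
  expect_equal(sum(s1$density), sum(s2$density), tolerance = 1e-8)
  expect_equal(s1$conc, s2$conc, tolerance = 1e-8)
})

test_that("closed-form equilibrium without decay matches the algebra", {
  env <- mu0_env(delta = 0.25)
  eq <- resident_equilibrium_mu0(rep(1 / 3, 3), env)
  expect_equal(eq$n_star, 12)
  expect_equal(eq$r_star, rep(0.25, 3))
  expect_equal(eq$c_star, rep(1 / 3, 3))
  # single resource: n* = s/delta and r* = delta/alpha from dn/dt = 0
  env1 <- environment_spec(supply = 2, monod_K = 1, decay = 0,
                           death_rate = 0.5)
  eq1 <- resident_equilibrium_mu0(1, env1)
  expect_equal(eq1$n_star, 4)
  expect_equal(eq1$r_star, 0.5)
  # delta = 1 pushes the required uptake factor to 1: infeasible
  expect_error(resident_equilibrium_mu0(rep(1 / 3, 3), mu0_env(delta = 1)),
               class = "crevo_infeasible_equilibrium")
  expect_error(resident_equilibrium_mu0(rep(1 / 3, 3), sym_env()),
               "mu = 0")
})

test_that("closed-form equilibrium agrees with long-time integration", {
  # mu = 1e-6 as a numerical proxy for the decay-free model
  env <- environment_spec(supply = rep(1, 3), monod_K = 1, decay = 1e-6,
                          death_rate = 0.25)
  a <- rep(1 / 3, 3)
  st <- community_state(a, density = 1, conc = rep(1, 3))
  res <- chemostat_stationary(st, env, integration_control(), max_time = 2e4)
  eq <- resident_equilibrium_mu0(a, mu0_env(delta = 0.25))
  expect_true(res$stationary)
  expect_lt(abs(res$state$density - eq$n_star) / eq$n_star, 1e-3)
  # supply balance at stationarity: consumption matches supply per resource
  r <- monod_uptake(res$state$conc, env$monod_K)
  consumption <- res$state$density * a * r
  expect_lt(max(abs(consumption - env$supply)), 1e-5)
})

test_that("relabelling resources permutes the trajectory", {
  env <- sym_env()
  sp <- tradeoff_spec(0.9, p = 3)
  alpha <- rbind(project_to_constraint(c(3, 2, 1), sp),
                 project_to_constraint(c(1, 1, 4), sp))
  st <- community_state(alpha, density = c(1, 2), conc = c(0.3, 0.6, 0.9))
  perm <- c(3, 1, 2)
  env_p <- environment_spec(supply = env$supply[perm],
                            monod_K = env$monod_K[perm],
                            decay = env$decay[perm],
                            death_rate = env$death_rate)
  st_p <- community_state(alpha[, perm], density = c(1, 2),
                          conc = st$conc[perm])
  o1 <- chemostat_integrate(st, env, integration_control(), 150)
  o2 <- chemostat_integrate(st_p, env_p, integration_control(), 150)
  expect_equal(o1$density, o2$density, tolerance = 1e-8)
  expect_equal(o1$conc[perm], o2$conc, tolerance = 1e-8)
})

test_that("single resident sits stationary at its equilibrium", {
  env <- sym_env(delta = 0.25)
  sp <- tradeoff_spec(1.1, p = 3)
  a <- singular_point(env$supply, sp)
  st <- community_state(a, density = sum(env$supply) / env$death_rate,
                        conc = env$monod_K)
  res <- chemostat_stationary(st, env, integration_control(), max_time = 1e4)
  expect_true(res$stationary)
  d <- chemostat_derivatives(res$state, env)
  expect_lt(max(abs(c(d$dn, d$dc))), 1e-7)
})
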