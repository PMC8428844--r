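test_that("mutants stay on the tradeoff surface, vertices included", {
  set.seed(21)
  sp <- tradeoff_spec(0.9, p = 3)
  parent <- singular_point(rep(1, 3), sp)
  for (i in 1:100) {
    child <- mutate_phenotype(parent, 0.05, sp)
    expect_lt(abs(tradeoff_value(child, sp) - 1), 1e-10)
    expect_true(all(child >= 0))
  }
  # a vertex parent stays near its vertex and remains feasible
  for (i in 1:50) {
    child <- mutate_phenotype(c(1, 0, 0), 0.05, sp)
    expect_lt(abs(tradeoff_value(child, sp) - 1), 1e-10)
    expect_gt(child[1], 0)
  }
  # vanishing step size recovers the parent
  child <- mutate_phenotype(parent, 1e-8, sp)
  expect_lt(sqrt(sum((child - parent)^2)), 1e-6)
})

test_that("projection removes the constraint-normal mutation component", {
  set.seed(33)
  sp <- tradeoff_spec(1, p = 3)
  parent <- rep(1 / 3, 3)
  nrm <- rep(1, 3) / sqrt(3)  # constraint normal on the linear surface
  disp <- replicate(10000, sum((mutate_phenotype(parent, 0.01, sp) -
                                  parent) * nrm))
  expect_lt(abs(mean(disp)), 1e-3)
})

test_that("identical seeds reproduce runs bitwise", {
  sp <- tradeoff_spec(1.1, p = 3)
  env <- sym_env(delta = 0.25)
  evo <- evolution_params(rng_seed = 7L, max_epochs = 40L)
  t1 <- run_evolution(off_center_start(sp), sp, env, evo)
  t2 <- run_evolution(off_center_start(sp), sp, env, evo)
  expect_identical(t1$events, t2$events)
  expect_identical(t1$final$alpha, t2$final$alpha)
  expect_identical(t1$final$density, t2$final$density)
  expect_identical(t1$mean_path, t2$mean_path)
})

test_that("every strain in every snapshot satisfies the constraint", {
  sp <- tradeoff_spec(0.9, p = 3)
  env <- sym_env()
  traj <- run_evolution(off_center_start(sp), sp, env,
                        evolution_params(rng_seed = 2L, max_epochs = 60L),
                        snapshot_every = 10L)
  for (st in traj$snapshots) {
    res <- apply(st$alpha, 1, function(a) abs(tradeoff_value(a, sp) - 1))
    expect_lt(max(res), 1e-10)
  }
})

test_that("a linear tradeoff broadens diffusively where a convex one
           stabilizes", {
  env <- sym_env(delta = 0.25)
  cloud <- function(gamma) {
    sp <- tradeoff_spec(gamma, p = 3)
    run_evolution(singular_point(env$supply, sp), sp, env,
                  evolution_params(rng_seed = 3L, max_epochs = 500L,
                                   stop_window = 500L))$trait_variance
  }
  v_neutral <- cloud(1)
  v_ess <- cloud(1.1)
  # gamma = 1: no restoring selection, the cloud keeps broadening
  expect_gt(mean(v_neutral[401:500]), 1.5 * mean(v_neutral[26:75]))
  # gamma = 1.1: stabilizing selection caps and erodes the early spread
  expect_lt(mean(v_ess[401:500]), mean(v_ess[76:175]))
  # the neutral cloud ends up markedly wider than the stabilized one
  expect_gt(mean(v_neutral[401:500]), 2 * mean(v_ess[401:500]))
})

test_that("weaker curvature gives broader specialist clouds", {
  # mutation-selection balance: stabilizing selection at a vertex scales
  # with 1 - gamma, so clouds at gamma = 0.95 are wider than at 0.8
  env <- sym_env(delta = 0.25)
  width <- function(gamma, seed) {
    sp <- tradeoff_spec(gamma, p = 3)
    st_alpha <- diag(3)
    traj <- run_evolution(c(1, 0, 0), sp, env,
                          evolution_params(rng_seed = seed,
                                           max_epochs = 250L,
                                           stop_window = 250L))
    # within-cluster variance of the resource-1 specialist cloud
    cs <- cluster_phenotypes(traj$final, sp)
    sel <- cs$membership == which.max(cs$centers[, 1])
    a <- traj$final$alpha[sel, , drop = FALSE]
    w <- traj$final$density[sel]
    ctr <- colSums(a * w) / sum(w)
    sum(w * rowSums(sweep(a, 2, ctr)^2)) / sum(w)
  }
  v095 <- sapply(1:5, function(s) width(0.95, s))
  v080 <- sapply(1:5, function(s) width(0.80, s))
  expect_gt(mean(v095), mean(v080))
})

test_that("monomorphic populations converge to the singular strategy first", {
  env <- sym_env(delta = 0.25)
  # gamma > 1: approach and stay, never branch
  sp11 <- tradeoff_spec(1.1, p = 3)
  m11 <- monomorphic_convergence_test(off_center_start(sp11), sp11, env,
                                      evolution_params(rng_seed = 1L))
  d11 <- m11$distance
  expect_true(all(d11$n_clusters == 1))
  expect_lt(d11$distance[nrow(d11)], 0.05)
  expect_lt(min(d11$distance), d11$distance[1])
  # started exactly at alpha*: stays within mutational noise
  m0 <- monomorphic_convergence_test(m11$alpha_star, sp11, env,
                                     evolution_params(rng_seed = 1L,
                                                      max_epochs = 150L))
  expect_lt(max(m0$distance$distance), 3 * 0.03)
  # gamma < 1: convergence below 0.05 precedes any branching
  sp09 <- tradeoff_spec(0.9, p = 3)
  m09 <- monomorphic_convergence_test(off_center_start(sp09), sp09, env,
                                      evolution_params(rng_seed = 1L))
  d09 <- m09$distance
  e_conv <- min(which(d09$distance < 0.05))
  e_branch <- min(c(which(d09$n_clusters > 1), Inf))
  expect_lt(e_conv, e_branch)
})
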