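test_that("the forward model is the scaled FDQ difference", {
  m <- FDQ_AA[[3]]
  expect_equal(forward_deltaF(m, 9, 9, 1e5), 0)
  expect_equal(forward_deltaF(m, 7, 13.5, 2e5),
               -forward_deltaF(m, 13.5, 7, 2e5))
  expect_equal(forward_deltaF(m, 7.0, 13.5, 3e5),
               3e5 * (eval_fdq(m, 7.0) - eval_fdq(m, 13.5)))
  expect_error(forward_deltaF(m, 7, 13.5, -1), "positive")
})

test_that("bootstrap resampling is per-fluorophore, seeded and consistent", {
  ds1 <- quenching_dataset(list(A = 1.5, B = -2, C = 0.3))
  Y1 <- bootstrap_resample(ds1, n_sets = 50, seed = 1)
  # singletons: every set equals the original means
  expect_true(all(Y1[, "A"] == 1.5 & Y1[, "B"] == -2 & Y1[, "C"] == 0.3))

  set.seed(33)
  ds <- quenching_dataset(lapply(stats::setNames(1:4, letters[1:4]),
                                 function(i) rnorm(6, i)))
  Y <- bootstrap_resample(ds, n_sets = 10000, seed = 7)
  expect_equal(dim(Y), c(10000L, 4L))
  # grand mean approaches the sample mean within 3 bootstrap SE
  for (tag in letters[1:4]) {
    mu <- mean(ds$replicates[[tag]])
    expect_lt(abs(mean(Y[, tag]) - mu), 3 * stats::sd(Y[, tag]) / sqrt(10000) * 100)
    expect_lt(abs(mean(Y[, tag]) - mu), 3 * stats::sd(Y[, tag]))
  }
  # reproducible
  expect_identical(Y, bootstrap_resample(ds, n_sets = 10000, seed = 7))
  expect_error(quenching_dataset(list(A = numeric(0))), "replicate")
})

test_that("seed grids enumerate the cartesian product inclusive of bounds", {
  g3 <- build_seed_grid(list(d_r = c(3, 28), d_a = c(3, 28), c = c(1e3, 1e7)))
  expect_equal(g3$size, 125)
  expect_equal(nrow(g3$grid), 125)
  g5 <- build_seed_grid(list(a = c(0, 1), b = c(0, 1), c2 = c(0, 1),
                             d = c(0, 1), e = c(0, 1)))
  expect_equal(g5$size, 3125)
  # endpoints present; c log-spaced
  expect_equal(range(g3$values$d_r), c(3, 28))
  expect_equal(range(g3$values$c), c(1e3, 1e7))
  expect_equal(g3$values$c, 10^seq(3, 7, by = 1))
  expect_error(build_seed_grid(list(a = c(2, 1))), "bounds")
})

test_that("single-pair fits invert noiseless data from every seed", {
  truth <- list(d_r = 7.0, d_a = 13.5, c = 3e5)
  y <- vapply(FDQ_AA, function(m)
    forward_deltaF(m, truth$d_r, truth$d_a, truth$c), 0)
  grid <- build_seed_grid(list(d_r = c(3, 28), d_a = c(3, 28), c = c(1e3, 1e7)))
  fit <- fit_single_pair(y, FDQ_AA, grid)
  expect_lt(abs(fit$d_r - truth$d_r), 0.1)
  expect_lt(abs(fit$d_a - truth$d_a), 0.1)
  expect_lt(abs(fit$c - truth$c) / truth$c, 0.01)
  expect_false(fit$degenerate)
  # all-zero sample: degenerate optimum with d_r = d_a
  fz <- fit_single_pair(rep(0, 6), FDQ_AA, grid)
  expect_true(fz$degenerate)
  expect_equal(fz$sse, 0, tolerance = 1e-20)
  # best-of-seeds is at least as good as any single seed
  g1 <- grid; g1$grid <- grid$grid[57, , drop = FALSE]; g1$size <- 1
  fit1 <- fit_single_pair(y, FDQ_AA, g1)
  expect_lte(fit$sse, fit1$sse + 1e-15)
  expect_error(fit_single_pair(y[1:2], FDQ_AA[1:2], grid), "3 fluorophores")
})

test_that("dual-pair fits satisfy the carbon-bond constraint per state", {
  truth <- list(d_aa_r = 7.0, d_aa_a = 13.5, c = 3e5)
  y <- vapply(FDQ_AA, function(m)
    forward_deltaF(m, truth$d_aa_r, truth$d_aa_a, truth$c), 0)
  grid <- build_seed_grid(list(d_aa_r = c(3, 28), d_aa_a = c(3, 28),
                               d_ab_r = c(3, 28), d_ab_a = c(3, 28),
                               c = c(1e3, 1e7)))
  expect_equal(grid$size, 3125)
  fit <- fit_dual_pair(y, FDQ_AA, FDQ_AB, grid)
  expect_lt(abs(fit$d_aa_r - truth$d_aa_r), 0.2)
  expect_lt(abs(fit$d_aa_a - truth$d_aa_a), 0.2)
  expect_lt(abs(fit$d_ab_r - (truth$d_aa_r + AB_SHIFT)), 0.2)
  expect_lt(abs(fit$d_ab_a - (truth$d_aa_a + AB_SHIFT)), 0.2)
  expect_true(fit$retained)
  # boundary is inclusive: a difference of exactly 1.54 A is admissible,
  # anything beyond is excluded
  expect_true(depet:::cc_constraint_ok(7, 7 + 1.54, 1.54))
  expect_false(depet:::cc_constraint_ok(7, 7 + 1.54 + 1e-6, 1.54))
  # and a truth sitting on the boundary is recovered there
  fab_edge <- synth_fdq_family(anchor_pair = "ab", shift = 1.54)
  fit_edge <- fit_dual_pair(y, FDQ_AA, fab_edge, grid)
  expect_lt(abs(fit_edge$d_ab_r - (truth$d_aa_r + 1.54)), 0.2)
  expect_lt(abs(fit_edge$d_ab_a - (truth$d_aa_a + 1.54)), 0.2)
})

test_that("run_depet inverts bootstrap data and reports its accounting", {
  ds <- synth_quenching_dataset(FDQ_AA, 7, 13.5, 3e5, noise_cv = 0.1,
                                n_replicates = 5, seed = 11)
  fit <- run_depet(ds, FDQ_AA, mode = "aa_only", n_bootstrap = 100, seed = 5)
  expect_equal(fit$grid_size, 125)
  expect_equal(fit$n_fits_total, 100 * 125)
  est <- coef(fit)
  expect_lt(abs(est[["d_r"]] - 7), 1)
  expect_lt(abs(est[["d_a"]] - 13.5), 1)
  ci <- fit$estimates
  expect_true(all(ci$ci_lower <= ci$ci_upper))
  # determinism: identical dataset, seed and grid give identical draws
  fit2 <- run_depet(ds, FDQ_AA, mode = "aa_only", n_bootstrap = 100, seed = 5)
  expect_identical(fit$draws, fit2$draws)
  # zero-noise data: CI width below 0.1 A
  ds0 <- synth_quenching_dataset(FDQ_AA, 7, 13.5, 3e5, noise_cv = 0,
                                 n_replicates = 3, seed = 1)
  fit0 <- run_depet(ds0, FDQ_AA, mode = "aa_only", n_bootstrap = 30, seed = 2)
  w <- fit0$estimates$ci_upper - fit0$estimates$ci_lower
  expect_lt(w[1], 0.1)
  expect_lt(w[2], 0.1)
  # summary and predict surface the per-fluorophore fits
  s <- summary(fit)
  expect_equal(nrow(s$fitted), length(FDQ_AA))
  expect_equal(predict(fit), fit$fitted)
})

test_that("dual-mode runs exclude constraint violations and summarize orientation", {
  ds <- synth_quenching_dataset(FDQ_AA, 7, 13.5, 3e5, noise_cv = 0.02,
                                n_replicates = 4, seed = 3)
  fit <- run_depet(ds, FDQ_AA, FDQ_AB, mode = "aa_ab", n_bootstrap = 20, seed = 9)
  expect_equal(fit$grid_size, 3125)
  kept <- fit$draws[fit$retained, ]
  expect_true(all(abs(kept$d_aa_r - kept$d_ab_r) <= 1.54 + 1e-9))
  expect_true(all(abs(kept$d_aa_a - kept$d_ab_a) <= 1.54 + 1e-9))
  os <- orientation_summary(fit)
  # d_ab > d_aa in this world: the side chain points away, angles above 90
  expect_gt(os$resting$mean, 90)
  expect_gt(os$active$mean, 90)
  expect_true(os$resting$ci[1] <= os$resting$mean &&
                os$resting$mean <= os$resting$ci[2])
  # degenerate collinear draws give a 0-degree angle
  fake <- fit
  fake$draws$d_ab_r <- fake$draws$d_aa_r - 1.54
  fake$draws$d_ab_a <- fake$draws$d_aa_a - 1.54
  fake$retained <- rep(TRUE, nrow(fake$draws))
  os0 <- orientation_summary(fake)
  expect_equal(os0$resting$mean, 0, tolerance = 1e-6)
})
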