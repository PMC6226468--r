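test_that("the quench curve matches a single-shell hand evaluation", {
  dr <- 0.05
  f <- rigid_ensemble(3.0, 40)    # fluorophore centroid fixed at 3.0 A
  q <- rigid_ensemble(1.5, 40)    # quencher centroid fixed at 1.5 A
  fd <- ensemble_to_density(f, anchor_kind = "Ca", moiety_kind = "xanthene")
  qd <- ensemble_to_density(q, anchor_kind = "Ca", moiety_kind = "indole")
  cv <- quench_probability_curve(fd, qd, "rigid")
  R <- 3.0; r <- 1.5
  manual <- vapply(cv$distances, function(d) {
    v <- shell_intersection_volume(d, R, r, dr)
    (v / shell_volume(R, dr)) * (v / shell_volume(r, dr))
  }, 0)
  expect_equal(cv$probabilities, manual, tolerance = 1e-12)
  expect_true(all(cv$probabilities >= 0 & cv$probabilities <= 1))
  # zero beyond the summed supports
  expect_equal(cv$probabilities[cv$distances > R + r], numeric(0))
  expect_equal(max(cv$distances), R + r)
  expect_equal(cv$probabilities[length(cv$probabilities)], 0)
})

test_that("the quench curve is symmetric under swapping the densities", {
  fd <- ensemble_to_density(synth_conformer_cloud(4, n_frames = 800, seed = 1),
                            anchor_kind = "Ca", moiety_kind = "xanthene")
  qd <- ensemble_to_density(synth_conformer_cloud(2, n_frames = 800, seed = 2),
                            anchor_kind = "Ca", moiety_kind = "indole")
  a <- quench_probability_curve(fd, qd)
  b <- quench_probability_curve(qd, fd)
  expect_equal(a$probabilities, b$probabilities, tolerance = 1e-10)
  expect_error(quench_probability_curve(fd,
    ensemble_to_density(rigid_ensemble(2), bin_width = 0.1)), "bin width")
})

test_that("isomer mixing is the pointwise average", {
  fd <- ensemble_to_density(rigid_ensemble(3), anchor_kind = "Ca")
  qd <- ensemble_to_density(rigid_ensemble(1.5), anchor_kind = "Ca")
  qd2 <- ensemble_to_density(rigid_ensemble(2.5), anchor_kind = "Ca")
  a <- quench_probability_curve(fd, qd, "iso5")
  b <- quench_probability_curve(fd, qd2, "iso6")
  mixed_same <- mix_isomers(a, a)
  expect_equal(mixed_same$probabilities, a$probabilities)
  m <- mix_isomers(a, b)
  n <- length(m$probabilities)
  pa <- c(a$probabilities, rep(0, n - length(a$probabilities)))
  pb <- c(b$probabilities, rep(0, n - length(b$probabilities)))
  expect_equal(m$probabilities, (pa + pb) / 2)
  # a zero curve halves the other
  z <- a; z$probabilities <- rep(0, length(a$probabilities))
  expect_equal(mix_isomers(z, a)$probabilities, a$probabilities / 2)
})

test_that("eval_fdq computes the printed mixture term by term", {
  m <- fdq_model(gauss_amplitudes = sqrt(2 * pi), gauss_means = 10,
                 gauss_sds = 1)
  expect_equal(eval_fdq(m, 10), 1)
  expect_lt(eval_fdq(m, 1e4), 1e-12)
  m2 <- fdq_model(c(0.2, 0.1), c(1.5, 4), c(0.5, 0.3, 0.1), c(5, 9, 14),
                  c(1, 2, 1.5), ksv_scale = 0.8)
  d <- c(0, 3.3, 7.7, 12.1)
  manual <- 0.8 * pmax(
    0.2 * exp(-d / 1.5) + 0.1 * exp(-d / 4) +
      0.5 / (1 * sqrt(2 * pi)) * exp(-(d - 5)^2 / 2) +
      0.3 / (2 * sqrt(2 * pi)) * exp(-(d - 9)^2 / 8) +
      0.1 / (1.5 * sqrt(2 * pi)) * exp(-(d - 14)^2 / (2 * 1.5^2)), 0)
  expect_equal(eval_fdq(m2, d), manual)
  expect_equal(predict(m2, d), manual)
  expect_error(eval_fdq(m2, -1), ">= 0")
})

test_that("fit_fdq recovers an exact mixture and honors its contract", {
  truth <- fdq_model(0.3, 2.0, c(0.5, 0.2), c(8, 14), c(1.2, 2.0), "T", "aa")
  dg <- seq(0, 25, by = 0.05)
  cv <- structure(list(distances = dg, probabilities = eval_fdq(truth, dg),
                       fluorophore_tag = "T", anchor_pair = "aa",
                       bin_width = 0.05), class = "quench_curve")
  m <- fit_fdq(cv, tol_rel = 1e-6)
  expect_lt(attr(m, "rel_rms"), 1e-6)
  # contract: evaluations reproduce the curve within the reported residual
  resid <- eval_fdq(m, dg) - cv$probabilities
  expect_lte(sqrt(mean(resid^2)), attr(m, "rms_residual") * (1 + 1e-9))

  # all-zero curve: the empty model
  z <- cv; z$probabilities <- rep(0, length(dg))
  mz <- fit_fdq(z)
  expect_length(mz$exp_amplitudes, 0)
  expect_length(mz$gauss_amplitudes, 0)
  expect_equal(eval_fdq(mz, c(0, 5, 10)), c(0, 0, 0))

  # a pipeline-built curve is fit within the default tolerance
  fd <- ensemble_to_density(synth_conformer_cloud(6, n_frames = 3000, seed = 2),
                            anchor_kind = "Ca", moiety_kind = "xanthene")
  qd <- ensemble_to_density(synth_conformer_cloud(2, n_frames = 3000, seed = 3),
                            anchor_kind = "Ca", moiety_kind = "indole")
  cp <- quench_probability_curve(fd, qd, "chain6")
  mp <- fit_fdq(cp)
  expect_lt(attr(mp, "rel_rms"), 1e-3)
  expect_true(all(mp$gauss_sds > 0))
  expect_true(all(mp$exp_length_constants > 0))
})

test_that("Stern-Volmer scaling is a multiplicative reference ratio", {
  m <- FDQ_AA[[2]]
  expect_equal(eval_fdq(scale_by_ksv(m, 40, 40), 7), eval_fdq(m, 7))
  expect_equal(eval_fdq(scale_by_ksv(m, 80, 40), c(5, 9)),
               2 * eval_fdq(m, c(5, 9)))
  # constants from the reported TMRM range
  d <- seq(3, 20, by = 0.5)
  expect_equal(eval_fdq(scale_by_ksv(m, 36, 41), d), (36 / 41) * eval_fdq(m, d))
  expect_error(scale_by_ksv(m, -1, 40), "positive")
})

test_that("FDQ tables round-trip through JSON at full precision", {
  path <- file.path(tempdir(), "fdq.json")
  save_fdq_table(FDQ_AA, path)
  back <- load_fdq_table(path)
  expect_equal(length(back), length(FDQ_AA))
  for (i in seq_along(back)) {
    expect_identical(back[[i]]$gauss_means, FDQ_AA[[i]]$gauss_means)
    expect_identical(back[[i]]$exp_amplitudes, FDQ_AA[[i]]$exp_amplitudes)
    expect_identical(back[[i]]$fluorophore_tag, FDQ_AA[[i]]$fluorophore_tag)
    d <- seq(0, 30, by = 0.25)
    expect_identical(eval_fdq(back[[i]], d), eval_fdq(FDQ_AA[[i]], d))
  }
  # schema violation
  jsonlite::write_json(list(list(tag = "x")), path, auto_unbox = TRUE)
  expect_error(load_fdq_table(path), "malformed")
})
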