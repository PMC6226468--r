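test_that("shell volume matches the closed form and degenerates to a ball", {
  expect_equal(shell_volume(0.05, 0.05), 4 * pi / 3 * 0.05^3)
  expect_equal(shell_volume(1, 0.05), 4 * pi / 3 * (1 - 0.95^3))
  # strictly increasing in the maximal radius
  rho <- seq(0.05, 10, by = 0.05)
  expect_true(all(diff(shell_volume(rho, 0.05)) > 0))
  expect_error(shell_volume(0.01, 0.05), "radius")
  expect_error(shell_volume(1, -1), "thickness")
})

test_that("lens volume handles tangent and contained bounds and matches MC", {
  expect_equal(lens_volume(3, 2, 1), 0)
  expect_equal(lens_volume(1, 2, 1), 4 * pi / 3, tolerance = 1e-12)
  mc <- mc_volume_oracle(function(p) {
    sqrt(rowSums(p^2)) <= 1.2 & sqrt((p[, 1] - 1.5)^2 + p[, 2]^2 + p[, 3]^2) <= 1
  }, rbind(c(0.3, -1, -1), c(1.2, 1, 1)), n_points = 1e6, seed = 42)
  expect_lt(abs(lens_volume(1.5, 1.2, 1) - mc$volume), 3 * mc$se)
  expect_error(lens_volume(0, 1, 1), "concentric")
  expect_error(lens_volume(5, 1, 1), "clamp")
})

test_that("shell intersection reproduces the published case table", {
  dr <- 0.05
  # concentric equal shells: the full shell volume
  expect_equal(shell_intersection_volume(0, 2, 2, dr), shell_volume(2, dr))
  # beyond reach, nested shells, concentric unequal: zero
  expect_equal(shell_intersection_volume(5, 2, 2, dr), 0)
  expect_equal(shell_intersection_volume(0.2, 2, 1, dr), 0)   # d <= R - r - dr
  expect_equal(shell_intersection_volume(0, 2, 1, dr), 0)     # concentric, R != r
  # single tangent lens at d = R + r - dr
  d <- 1.6 + 1.2 - dr
  expect_equal(shell_intersection_volume(d, 1.6, 1.2, dr),
               lens_volume(d, 1.6, 1.2), tolerance = 1e-12)
  # two-term difference at d = R - r
  d <- 1.6 - 1.2
  expect_equal(shell_intersection_volume(d, 1.6, 1.2, dr),
               lens_volume(d, 1.6, 1.2) - lens_volume(d, 1.6 - dr, 1.2),
               tolerance = 1e-12)
  expect_error(shell_intersection_volume(1, 2, 2, dr = -0.01), "thickness")
})

test_that("every dispatch branch agrees with the Monte-Carlo oracle", {
  dr <- 0.05
  set.seed(101)
  # randomized triples plus deliberate boundary cases, spanning all branches
  triples <- rbind(
    t(replicate(12, {
      R <- runif(1, 0.4, 2.5); r <- runif(1, 0.4, 2.5)
      c(runif(1, abs(R - r) * 0.5, R + r - 1e-3), R, r)
    })),
    c(0, 1.3, 1.3),                 # concentric equal
    c(1.6 + 1.2 - dr, 1.6, 1.2),    # tangent single lens
    c(1.6 - 1.2, 1.6, 1.2),         # outer containment boundary
    c(1.6 - 1.2, 1.2, 1.6),         # same, swapped roles
    c(2.3, 1.6, 1.2)                # generic four-term case
  )
  for (k in seq_len(nrow(triples))) {
    d <- triples[k, 1]; R <- triples[k, 2]; r <- triples[k, 3]
    v <- shell_intersection_volume(d, R, r, dr)
    if (d < 1e-9) next  # MC box below handles the offset geometry only
    mc <- mc_volume_oracle(shell_pair_predicate(d, R, r, dr),
                           shell_pair_box(d, R, r), n_points = 2e5, seed = k)
    expect_lt(abs(v - mc$volume), 3 * mc$se + 1e-12)
  }
})

test_that("shell-sum conservation, symmetry and monotone decay hold", {
  dr <- 0.05
  set.seed(7)
  for (k in 1:10) {
    d <- runif(1, 0.1, 3); R <- runif(1, 0.3, 2); rmax <- runif(1, 0.5, 2.5)
    rmax <- round(rmax / dr) * dr
    s <- sum(shell_intersection_volume(d, R, seq(dr, rmax, by = dr), dr))
    clip <- depet:::ball_overlap_volume(d, R, rmax) -
      depet:::ball_overlap_volume(d, R - dr, rmax)
    expect_equal(s, clip, tolerance = 1e-8)
    # symmetry in the two shells
    r2 <- runif(1, 0.3, 2)
    expect_equal(shell_intersection_volume(d, R, r2, dr),
                 shell_intersection_volume(d, r2, R, dr))
  }
  # non-increasing in d beyond |R - r| + dr
  d <- seq(0.45, 3, by = 0.05)
  v <- shell_intersection_volume(d, 1.6, 1.2, dr)
  expect_true(all(diff(v) <= 1e-12))
})

test_that("orientation angle follows the law of cosines", {
  # collinear cases: acos amplifies double rounding near +/-1, so allow a
  # microdegree of slack
  expect_equal(angle_from_distances(10, 10 - 1.54), 0, tolerance = 1e-4)
  expect_equal(angle_from_distances(10, 10 + 1.54), 180, tolerance = 1e-4)
  # coordinate round trip at a known angle
  theta <- 120 * pi / 180
  ca <- 10 * c(sin(theta), cos(theta))    # Walpha at origin, Wbeta at (0, 1.54)
  d_ab <- sqrt(sum((ca - c(0, 1.54))^2))
  expect_equal(angle_from_distances(10, d_ab), 120, tolerance = 1e-6)
  expect_error(angle_from_distances(10, 20), "triangle")
  # d_aa < d_ab means the side chain points away: angle above 90 degrees
  expect_gt(angle_from_distances(7, 7.9), 90)
})

test_that("planar coordinates preserve the norm and reproduce d_ab", {
  pc <- planar_coordinates(c(17, 9.3), c(41, 133))
  expect_equal(sqrt(pc$x^2 + pc$y^2), c(17, 9.3))
  # collinear case: distance to (0, cc) is d_aa - cc
  p0 <- planar_coordinates(10, 0)
  expect_equal(sqrt(p0$x^2 + (p0$y - 1.54)^2), 10 - 1.54)
  # generic angle: implied d_ab equals the law-of-cosines inversion
  p41 <- planar_coordinates(17, 41)
  d_ab <- sqrt(p41$x^2 + (p41$y - 1.54)^2)
  expect_equal(angle_from_distances(17, d_ab), 41, tolerance = 1e-9)
  expect_error(planar_coordinates(5, 200), "angle")
})

test_that("the Monte-Carlo oracle is calibrated on known volumes", {
  ball <- mc_volume_oracle(function(p) rowSums(p^2) < 1,
                           rbind(c(-1, -1, -1), c(1, 1, 1)),
                           n_points = 1e6, seed = 1)
  expect_lt(abs(ball$volume - 4 * pi / 3), 3 * ball$se)
  empty <- mc_volume_oracle(function(p) rep(FALSE, nrow(p)),
                            rbind(c(-1, -1, -1), c(1, 1, 1)),
                            n_points = 1e4, seed = 1)
  expect_equal(empty$volume, 0)
  # reproducible under seed
  b2 <- mc_volume_oracle(function(p) rowSums(p^2) < 1,
                         rbind(c(-1, -1, -1), c(1, 1, 1)),
                         n_points = 1e6, seed = 1)
  expect_identical(ball$volume, b2$volume)
  expect_error(mc_volume_oracle(function(p) TRUE, rbind(c(0, 0, 0), c(0, 1, 1)),
                                1e4, 1), "box")
  expect_error(mc_volume_oracle(function(p) TRUE,
                                rbind(c(-1, -1, -1), c(1, 1, 1)), 100, 1),
               "1e4")
})
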