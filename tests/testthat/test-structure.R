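test_that("the polyproline II builder reproduces nominal ruler lengths", {
  pep <- build_ppii(3)
  expect_s3_class(pep, "structure_coords")
  # the worked length standard: Cys-(Pro)3-Trp spans ~12.4 A
  expect_lt(abs(attr(pep, "nominal_length") - 12.4), 0.3)
  expect_equal(nrow(pep$atoms), 5 * 4)    # N, CA, C, O per residue
  expect_equal(pep$atoms$residue_name[1], "CYS")
  expect_equal(pep$atoms$residue_name[nrow(pep$atoms)], "TRP")
})

test_that("the helix is screw-symmetric: constant rise, increasing length", {
  pep <- build_ppii(10)
  ca <- t(vapply(1:12, function(r) get_atom(pep, r), numeric(3)))
  rises <- sqrt(rowSums(diff(ca)^2))
  expect_lt(diff(range(rises)), 1e-6)     # identical virtual-bond steps
  lens <- vapply(0:7, function(n) attr(build_ppii(n), "nominal_length"), 0)
  expect_true(all(diff(lens) > 0))
  # n_pro = 0: one virtual-bond step of the same helix
  expect_equal(lens[1], rises[1], tolerance = 1e-6)
})

test_that("trilateration returns the base point and its mirror for zero deltas", {
  anchors <- rbind(c(0, 0, 0), c(10, 0, 0), c(3, 9, 0))
  base <- c(4, 3, -5)
  tri <- trilaterate_displaced(anchors, base, c(0, 0, 0))
  pts <- list(tri$branch_upper$point, tri$branch_lower$point)
  errs <- vapply(pts, function(p) max(abs(p - base)), 0)
  expect_lt(min(errs), 1e-9)
  # the other branch is the mirror through the anchor plane (z = 0 here)
  other <- pts[[which.max(errs)]]
  expect_equal(other[1:2], base[1:2], tolerance = 1e-9)
  expect_equal(other[3], -base[3], tolerance = 1e-9)
  # both branches satisfy all three sphere equations
  for (p in pts)
    expect_equal(sqrt(rowSums((anchors - matrix(p, 3, 3, byrow = TRUE))^2)),
                 tri$radii, tolerance = 1e-9)
})

test_that("trilateration inverts a forward-constructed displacement", {
  anchors <- rbind(c(1, 0, 2), c(8, 1, -1), c(4, 7, 1))
  base <- c(3, 2, -6)
  target <- c(5, 4, 6)
  rb <- sqrt(rowSums((anchors - matrix(base, 3, 3, byrow = TRUE))^2))
  rt <- sqrt(rowSums((anchors - matrix(target, 3, 3, byrow = TRUE))^2))
  tri <- trilaterate_displaced(anchors, base, rt - rb)
  err <- min(max(abs(tri$branch_upper$point - target)),
             max(abs(tri$branch_lower$point - target)))
  expect_lt(err, 1e-6)
  # anchor order does not change the branch point set
  perm <- c(3, 1, 2)
  tri2 <- trilaterate_displaced(anchors[perm, ], base, (rt - rb)[perm])
  pts1 <- rbind(tri$branch_upper$point, tri$branch_lower$point)
  pts2 <- rbind(tri2$branch_upper$point, tri2$branch_lower$point)
  d12 <- vapply(1:2, function(i)
    min(sqrt(rowSums((pts2 - matrix(pts1[i, ], 2, 3, byrow = TRUE))^2))), 0)
  expect_lt(max(d12), 1e-6)
  expect_error(trilaterate_displaced(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                                     base, c(0, 0, 0)), "collinear")
  expect_error(trilaterate_displaced(anchors, base, c(30, 0, 0)), "intersect")
})

test_that("bootstrap trilateration summarizes the solution clouds", {
  anchors <- rbind(c(0, 0, 0), c(10, 0, 0), c(3, 9, 0))
  base <- c(4, 3, -5)
  # degenerate distributions collapse to the exact two points
  tri0 <- trilaterate_bootstrap(anchors, base,
                                list(rep(0, 5), rep(0, 5), rep(0, 5)),
                                n_draws = 50, seed = 1)
  expect_equal(nrow(tri0$cloud_upper), 50)
  expect_lt(max(apply(tri0$cloud_lower, 1, function(p) max(abs(p - base)))), 1e-9)
  # jittered deltas around a known displacement: branch mean near truth
  target <- c(5, 4, 6)
  rb <- sqrt(rowSums((anchors - matrix(base, 3, 3, byrow = TRUE))^2))
  rt <- sqrt(rowSums((anchors - matrix(target, 3, 3, byrow = TRUE))^2))
  set.seed(8)
  dists <- lapply(rt - rb, function(d) d + rnorm(500, 0, 0.1))
  tb <- trilaterate_bootstrap(anchors, base, dists, n_draws = 400, seed = 3)
  truth_z <- sum((target - base) * tb$normal)
  hit <- which.min(abs(tb$summary$mean - truth_z))
  expect_lt(abs(tb$summary$mean[hit] - truth_z), 3 * 0.1)
  expect_true(all(tb$summary$ci_lower <= tb$summary$ci_upper))
  # reproducible under seed
  tb2 <- trilaterate_bootstrap(anchors, base, dists, n_draws = 400, seed = 3)
  expect_identical(tb$summary, tb2$summary)
})

test_that("Kabsch superposition recovers rigid transforms", {
  set.seed(3)
  X <- matrix(rnorm(30), 10)
  k0 <- kabsch_superpose(X, X)
  expect_equal(k0$rmsd, 0, tolerance = 1e-9)
  expect_equal(k0$rotation, diag(3), tolerance = 1e-9)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  Y <- X %*% R + matrix(c(1, 2, 3), 10, 3, byrow = TRUE)
  k <- kabsch_superpose(X, Y)
  expect_lt(k$rmsd, 1e-9)
  expect_equal(k$rotation, R, tolerance = 1e-9)
  expect_equal(det(k$rotation), 1, tolerance = 1e-9)
  # translation-only case: identity rotation
  kt <- kabsch_superpose(X, X + matrix(c(0, 0, 9), 10, 3, byrow = TRUE))
  expect_equal(kt$rotation, diag(3), tolerance = 1e-9)
  # the optimal transform never does worse than identity placement
  expect_lte(k$rmsd, sqrt(mean(rowSums((X - Y)^2))))
  expect_error(kabsch_superpose(X[1:2, ], Y[1:2, ]), "3 paired")
})

test_that("displacement maps isolate moved residues after alignment", {
  pep <- build_ppii(6)
  # an identical copy: all zeros
  expect_equal(residue_displacement_map(pep, pep)$displacement, rep(0, 8),
               tolerance = 1e-9)
  # a rigidly moved copy: still all zeros after superposition
  th <- 0.5
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  moved <- pep
  xyz <- as.matrix(moved$atoms[, c("x", "y", "z")]) %*% R
  moved$atoms$x <- xyz[, 1] + 4; moved$atoms$y <- xyz[, 2] - 1
  moved$atoms$z <- xyz[, 3] + 2
  dm <- residue_displacement_map(pep, moved)
  expect_lt(max(dm$displacement), 1e-6)
  # one displaced residue reports its shift, the others remain small
  shifted <- pep
  i <- shifted$atoms$residue_id == 4
  shifted$atoms$z[i] <- shifted$atoms$z[i] + 2
  dm2 <- residue_displacement_map(pep, shifted)
  expect_gt(dm2$displacement[dm2$residue_id == 4], 1.5)
  expect_lt(max(dm2$displacement[dm2$residue_id != 4]), 0.5)
  # unshared residues are dropped and counted
  sub <- pep; sub$atoms <- sub$atoms[sub$atoms$residue_id <= 5, ]
  dm3 <- residue_displacement_map(pep, sub)
  expect_equal(nrow(dm3), 5)
  expect_equal(attr(dm3, "n_dropped"), 3)
})

test_that("PDB structures round-trip through write and read", {
  pep <- build_ppii(2)
  path <- file.path(tempdir(), "pep.pdb")
  write_structure_pdb(pep, path)
  back <- read_structure(path)
  expect_equal(nrow(back$atoms), nrow(pep$atoms))
  expect_equal(get_atom(back, 4), get_atom(pep, 4), tolerance = 1e-3)
  expect_equal(back$atoms$residue_name, pep$atoms$residue_name)
  expect_error(get_atom(back, 99), "not found")
})
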