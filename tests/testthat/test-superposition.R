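test_that("superposing a structure on itself gives zero RMSD and identity", {
  set.seed(1)
  a <- matrix(rnorm(15), 5, 3)
  fit <- kabsch_superpose(a, a)
  expect_lt(fit$rmsd_mean, 1e-12)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-8)
  expect_true(all(fit$per_residue_dev >= 0))
})

test_that("rigid motions are recovered exactly and never by reflection", {
  set.seed(2)
  for (rep in 1:20) {
    a <- matrix(rnorm(30), 10, 3)
    b <- apply_rigid(a, random_rigid_motion())
    fit <- kabsch_superpose(a, b)
    expect_lt(fit$rmsd_mean, 1e-6)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-8)
    expect_equal(crossprod(fit$rotation), diag(3), tolerance = 1e-8)
  }
  # mirrored target cannot be matched by a proper rotation
  a <- matrix(rnorm(30), 10, 3)
  b <- a; b[, 1] <- -b[, 1]
  expect_gt(kabsch_superpose(a, b)$rmsd_mean, 0.1)
})

test_that("Kabsch RMSD matches quaternion-parameterized minimization", {
  set.seed(3)
  for (rep in 1:30) {
    a <- matrix(rnorm(30), 10, 3)
    b <- matrix(rnorm(30), 10, 3)
    expect_equal(kabsch_superpose(a, b)$rmsd_mean,
                 quaternion_rmsd_oracle(a, b), tolerance = 1e-6)
  }
})

test_that("Kabsch RMSD agrees with bio3d's fitter", {
  set.seed(4)
  a <- matrix(rnorm(60), 20, 3)
  b <- matrix(rnorm(60), 20, 3)
  fit <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.vector(t(b)), mobile = as.vector(t(a))))
  rmsd_bio3d <- sqrt(mean(rowSums((matrix(fit, 20, 3, byrow = TRUE) - b)^2)))
  expect_equal(kabsch_superpose(a, b)$rmsd_mean, rmsd_bio3d,
               tolerance = 1e-6)
})

test_that("degenerate superposition inputs error", {
  a <- matrix(rnorm(30), 10, 3)
  expect_error(kabsch_superpose(a, a[1:5, ]), "mismatch")
  expect_error(kabsch_superpose(a[1:2, ], a[1:2, ]), "3")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line + 1), "collinear")
  expect_error(kabsch_superpose(a, a, fit_mask = rep(FALSE, 10)), "3")
})

test_that("per-residue deviations are symmetric and localize displacements", {
  set.seed(5)
  a <- matrix(rnorm(90), 30, 3)
  b <- matrix(rnorm(90), 30, 3)
  expect_equal(per_residue_rmsd(a, b), per_residue_rmsd(b, a),
               tolerance = 1e-9)
  expect_equal(per_residue_rmsd(a, a), rep(0, 30), tolerance = 1e-12)

  # one residue pushed 5 A away from a large rigid body
  body <- matrix(rnorm(300, sd = 10), 100, 3)
  moved <- body
  moved[50, ] <- moved[50, ] + c(0, 0, 5)
  dev <- per_residue_rmsd(moved, body)
  expect_gte(dev[50], 4.5)
  expect_lte(dev[50], 5.0)
  expect_true(all(dev[-50] < 0.5))
})

test_that("scRMSD aggregates are the RMS and median of per-residue deviations", {
  set.seed(6)
  a <- matrix(rnorm(120, sd = 5), 40, 3)
  b <- a + matrix(rnorm(120, sd = 1), 40, 3)
  dev <- per_residue_rmsd(a, b)
  expect_equal(scrmsd(a, b, "mean"), sqrt(mean(dev^2)), tolerance = 1e-9)
  expect_equal(scrmsd(a, b, "median"), median(dev), tolerance = 1e-9)
  expect_equal(scrmsd(a, a, "mean"), 0, tolerance = 1e-12)
  expect_equal(scrmsd(a, a, "median"), 0, tolerance = 1e-12)
})

test_that("a small displaced minority separates mean from median scRMSD", {
  # 80 anchored residues, 20 displaced ~8 A: median stays near zero while
  # the mean approaches sqrt(20 * 64 / 100)
  set.seed(7)
  body <- matrix(rnorm(300, sd = 12), 100, 3)
  moved <- body
  dirs <- matrix(rnorm(60), 20, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  moved[81:100, ] <- moved[81:100, ] + 8 * dirs
  expect_lt(scrmsd(moved, body, "median"), 0.5)
  expect_gt(scrmsd(moved, body, "mean"), 3.0)
  expect_lt(scrmsd(moved, body, "mean"), 4.5)
})

test_that("scRMSD is invariant under rigid motion of either structure", {
  set.seed(8)
  pair <- make_hinged_pair(seed = 8)
  for (rep in 1:5) {
    m <- random_rigid_motion()
    a2 <- apply_rigid(pair$mobile, m)
    expect_equal(scrmsd(a2, pair$target, "mean"),
                 scrmsd(pair$mobile, pair$target, "mean"), tolerance = 1e-6)
    expect_equal(scrmsd(a2, pair$target, "median"),
                 scrmsd(pair$mobile, pair$target, "median"), tolerance = 1e-6)
    expect_equal(corrected_scrmsd(a2, pair$target)$scrmsd,
                 corrected_scrmsd(pair$mobile, pair$target)$scrmsd,
                 tolerance = 1e-6)
  }
})

test_that("corrected scRMSD equals plain scRMSD when no outlier is possible", {
  set.seed(9)
  a <- matrix(rnorm(45), 15, 3)
  res <- corrected_scrmsd(a, a)
  expect_equal(res$scrmsd, 0)
  expect_false(any(res$outlier_mask))

  # rigidly shifted copy: all deviations equal, MAD = 0, no outliers
  b <- a + rep(1, 15) %o% c(3, 0, 0)
  res2 <- corrected_scrmsd(a, b, aggregate = "median")
  expect_equal(res2$scrmsd, scrmsd(a, b, "median"), tolerance = 1e-12)
  expect_false(any(res2$outlier_mask))
})

test_that("masked realignment rescues a hinged tail", {
  pair <- make_hinged_pair(n_core = 80, n_tail = 20, seed = 10)
  plain_mean <- scrmsd(pair$mobile, pair$target, "mean")
  res <- corrected_scrmsd(pair$mobile, pair$target, aggregate = "median")
  expect_gt(plain_mean, 2.0)
  expect_lt(res$scrmsd, 0.1)
  expect_true(all(res$outlier_mask[pair$tail_idx]))
  # correction dominance on tailed pairs
  expect_lte(res$scrmsd, plain_mean)
})

test_that("iterating the rejection cycle converges and matches definitions", {
  set.seed(11)
  # no outliers on the first pass: identical to the single-pass correction
  a <- matrix(rnorm(60, sd = 5), 20, 3)
  b <- a + rep(1, 20) %o% c(1, 1, 0)
  it <- iterative_outlier_superpose(a, b)
  cc <- corrected_scrmsd(a, b)
  expect_equal(it$scrmsd, cc$scrmsd, tolerance = 1e-12)
  expect_identical(it$outlier_mask, cc$outlier_mask)

  # max_iter = 1 is definitionally the single-pass correction
  pair <- make_hinged_pair(seed = 11)
  it1 <- iterative_outlier_superpose(pair$mobile, pair$target, max_iter = 1)
  cc1 <- corrected_scrmsd(pair$mobile, pair$target)
  expect_equal(it1$scrmsd, cc1$scrmsd, tolerance = 1e-12)

  # hinge construction converges quickly to the core fit
  itc <- iterative_outlier_superpose(pair$mobile, pair$target, max_iter = 10)
  expect_lte(itc$iterations, 3)
  expect_lt(itc$scrmsd, 0.1)
  expect_true(all(itc$outlier_mask[pair$tail_idx]))
})

test_that("too few surviving residues falls back to the plain fit", {
  # 3 tight core points + 4 wild points: rejection would leave < 3
  core <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(0, 3.8, 0))
  wild <- matrix(rnorm(12, sd = 40), 4, 3)
  a <- rbind(core, wild)
  b <- rbind(core, matrix(rnorm(12, sd = 40), 4, 3))
  res <- suppressWarnings(corrected_scrmsd(a, b))
  if (res$fit$fallback)
    expect_equal(res$fit$fit_mask, rep(TRUE, 7))
  expect_true(is.finite(res$scrmsd))
})
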