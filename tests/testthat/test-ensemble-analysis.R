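random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         3, 3, byrow = TRUE)
}

test_that("Kabsch recovers random rigid transforms to numerical precision", {
  set.seed(11)
  ref <- matrix(stats::rnorm(60), 20)
  fit0 <- kabsch_superpose(ref, ref)
  expect_lt(fit0$rmsd, 1e-12)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-10)
  for (i in 1:25) {
    rot <- random_rotation()
    shift <- stats::rnorm(3, sd = 10)
    mob <- sweep(ref %*% rot, 2, shift, "+")
    fit <- kabsch_superpose(mob, ref)
    expect_lt(fit$rmsd, 1e-8)
    expect_lt(max(abs(apply_transform(mob, fit) - ref)), 1e-8)
  }
})

test_that("Kabsch matches an exhaustive in-plane rotation search", {
  # planar point sets: the optimal rotation is about z, so a fine 1D grid
  # over the rotation angle is an exhaustive oracle
  pts <- cbind(c(0, 2, 1, -1), c(0, 0, 2, 1), c(0, 0, 0, 0))
  th0 <- 0.9
  rotz <- function(th) matrix(c(cos(th), -sin(th), 0,
                                sin(th), cos(th), 0, 0, 0, 1), 3, 3,
                              byrow = TRUE)
  mob <- sweep(pts %*% rotz(th0), 2, c(3, -1, 0), "+")
  mob[, 1:2] <- mob[, 1:2] + 0.05   # slight offset so the fit is non-trivial
  grid <- seq(0, 2 * pi, by = pi / 1800)
  grid_rmsd <- vapply(grid, function(th) {
    m <- mob %*% rotz(th)
    m <- sweep(m, 2, colMeans(m) - colMeans(pts), "-")
    sqrt(mean(rowSums((m - pts)^2)))
  }, numeric(1))
  fit <- kabsch_superpose(mob, pts)
  # the grid can only approach the optimum to its angular resolution
  expect_lt(abs(fit$rmsd - min(grid_rmsd)), 2e-3)
  expect_lte(fit$rmsd, min(grid_rmsd) + 1e-12)
  best <- grid[which.min(grid_rmsd)]
  expect_lt(min(abs(c(best - (2 * pi - th0), best - th0))), pi / 1800 + 1e-9)
})

test_that("degenerate superposition inputs are refused", {
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(kabsch_superpose(line, line + 1),
               class = "phosready_superposition_error")
  expect_error(kabsch_superpose(diag(3)[1:2, ], diag(3)[1:2, ]),
               class = "phosready_superposition_error")
})

test_that("post-fit RMSD is invariant under rigid transforms of either input", {
  set.seed(5)
  a <- matrix(stats::rnorm(45), 15)
  b <- a + matrix(stats::rnorm(45, sd = 0.5), 15)
  base <- kabsch_superpose(a, b)$rmsd
  for (i in 1:5) {
    rot <- random_rotation()
    shift <- stats::rnorm(3, sd = 5)
    expect_lt(abs(kabsch_superpose(sweep(a %*% rot, 2, shift, "+"), b)$rmsd -
                    base), 1e-8)
    expect_lt(abs(kabsch_superpose(a, sweep(b %*% rot, 2, shift, "+"))$rmsd -
                    base), 1e-8)
  }
})

test_that("RMSD series is zero for identical or rigidly shifted frames", {
  s <- as_structure(small_complex())
  frames <- list(s, s, s)
  shifted <- s
  coords(shifted) <- sweep(coords(s), 2, c(4, -2, 7), "+")
  frames[[4]] <- shifted
  ens <- ensemble_from_frames(frames)
  sr <- rmsd_series(ens, "initial")
  expect_equal(sr$values, rep(0, 4), tolerance = 1e-10)
  expect_error(rmsd_series(ens, selection = integer(0)),
               class = "phosready_selection_error")
})

test_that("mean RMSD of a Gaussian ensemble matches the analytic value", {
  s <- as_structure(small_complex())
  sigma <- 0.4
  ens <- gaussian_ensemble(s, sigma, n_frames = 1000, seed = 21)
  sr <- rmsd_series(ens, reference = "average", selection = "all")
  # isotropic displacement: E[RMSD] ~ sigma * sqrt(3) about the mean structure
  expect_lt(abs(mean(sr$values) - sigma * sqrt(3)) / (sigma * sqrt(3)), 0.1)
})

test_that("convergence calls depend only on the trailing window", {
  s <- as_structure(small_complex())
  ens <- gaussian_ensemble(s, 1e-6, n_frames = 50, seed = 2)
  sr0 <- rmsd_series(ens)
  cv <- assess_convergence(sr0)
  expect_true(cv$converged)
  expect_identical(cv$window, c(41L, 50L))
  # ramp up in the tail -> not converged
  ramp <- sr0
  ramp$values <- seq(0, 5, length.out = 50)
  expect_false(assess_convergence(ramp, threshold = 2)$converged)
  # early noise outside the window is forgiven
  spike <- sr0
  spike$values[5] <- 8
  expect_true(assess_convergence(spike)$converged)
})

test_that("neighbour clustering recovers the generated conformer families", {
  a <- as_structure(small_complex(seed = 31))
  b <- hinge_deform(a, angle_deg = 70)
  sep <- kabsch_superpose(coords(b), coords(a))$rmsd
  expect_gt(sep, 2)   # families far beyond cutoff + jitter
  ts <- two_state_trajectory(a, b, weights = c(0.6, 0.4), n_frames = 90,
                             jitter = 0.2, seed = 13)
  cl <- cluster_gromos(ts$ensemble, cutoff = 1.0, selection = "backbone")
  expect_identical(length(cl$clusters), 2L)
  expect_identical(sum(lengths(lapply(cl$clusters, `[[`, "members"))), 90L)
  # memberships equal the generator's truth labels exactly (up to label swap)
  agree <- max(mean(cl$assignment == ts$labels),
               mean((3L - cl$assignment) == ts$labels))
  expect_identical(agree, 1)
  # huge cutoff: one cluster holding 100% of frames
  cl1 <- cluster_gromos(ts$ensemble, cutoff = 1e4)
  expect_identical(length(cl1$clusters), 1L)
  expect_identical(length(cl1$clusters[[1]]$members), 90L)
  # cutoff below the smallest nonzero pairwise RMSD: all singletons
  cl2 <- cluster_gromos(ts$ensemble, cutoff = 1e-6)
  expect_identical(length(cl2$clusters), 90L)
})

test_that("average structure equals the brute-force per-atom mean", {
  s <- as_structure(small_complex())
  expect_equal(coords(average_structure(ensemble_from_frames(list(s)))),
               coords(s))
  up <- s; dn <- s
  coords(up) <- coords(s) + 0.5
  coords(dn) <- coords(s) - 0.5
  # frames symmetric about the base: the average returns it (no fit needed
  # for pure translations after superposition)
  avg <- average_structure(ensemble_from_frames(list(up, dn)))
  expect_equal(kabsch_superpose(coords(avg), coords(s))$rmsd, 0,
               tolerance = 1e-8)
  # general case against a direct loop (fit each frame to frame 1 first)
  ens <- gaussian_ensemble(s, 0.3, n_frames = 7, seed = 77)
  avg <- average_structure(ens, fit_selection = "all")
  ref <- coords(ens_frame(ens, 1))
  acc <- 0
  for (i in 1:7) {
    fr <- coords(ens_frame(ens, i))
    acc <- acc + apply_transform(fr, kabsch_superpose(fr, ref))
  }
  expect_equal(unname(coords(avg)), unname(acc / 7), tolerance = 1e-10)
})

test_that("RMSF and B-factors satisfy their analytic calibration", {
  s <- as_structure(small_complex())
  frozen <- gaussian_ensemble(s, 0, n_frames = 10, seed = 1)
  pf <- rmsf_profile(frozen)
  expect_equal(max(pf$rmsf), 0, tolerance = 1e-12)
  expect_equal(max(pf$b), 0, tolerance = 1e-12)

  sigma <- 0.5
  ens <- gaussian_ensemble(s, sigma, n_frames = 2000, seed = 8)
  pf <- rmsf_profile(ens)
  expect_lt(abs(mean(pf$rmsf) - sigma * sqrt(3)) / (sigma * sqrt(3)), 0.05)
  # the Debye-Waller identity holds atom by atom
  expect_equal(pf$b, 8 * pi^2 / 3 * pf$rmsf^2, tolerance = 1e-12)
  expect_error(rmsf_profile(ens, window = c(5, 5)),
               class = "phosready_window_error")
})

test_that("RMSF about the mean is minimal among reference structures", {
  s <- as_structure(small_complex())
  ens <- gaussian_ensemble(s, 0.6, n_frames = 300, seed = 15)
  pf_mean <- rmsf_profile(ens)
  # fluctuation about a fixed non-mean structure (frame 2), no re-averaging
  ref <- coords(ens_frame(ens, 2))
  dev2 <- 0
  for (i in 1:300) {
    fr <- coords(ens_frame(ens, i))
    dev2 <- dev2 + rowSums((apply_transform(fr, kabsch_superpose(fr, ref)) - ref)^2)
  }
  rmsf_other <- sqrt(dev2 / 300)
  expect_lt(mean(pf_mean$rmsf), mean(rmsf_other))
})

test_that("generator sigma is recovered from B-factors within 10%", {
  s <- as_structure(small_complex())
  for (sigma in c(0.2, 0.5, 1.0)) {
    ens <- gaussian_ensemble(s, sigma, n_frames = 2000,
                             seed = 100 + round(100 * sigma))
    pf <- rmsf_profile(ens)
    sigma_hat <- sqrt(mean(pf$b) / (8 * pi^2))
    expect_lt(abs(sigma_hat - sigma) / sigma, 0.10)
  }
})

test_that("replica aggregation uses the sample-sd convention", {
  s <- as_structure(small_complex())
  p1 <- rmsf_profile(gaussian_ensemble(s, 0.5, 200, seed = 1))
  p2 <- rmsf_profile(gaussian_ensemble(s, 0.5, 200, seed = 2))
  same <- replica_aggregate(list(p1, p1, p1))
  expect_equal(max(same$replica_sd), 0, tolerance = 1e-12)
  agg <- replica_aggregate(list(p1, p2))
  expect_equal(agg$rmsf, (p1$rmsf + p2$rmsf) / 2, tolerance = 1e-12)
  expect_equal(agg$replica_sd, abs(p1$rmsf - p2$rmsf) / sqrt(2),
               tolerance = 1e-12)
  expect_equal(agg$b, 8 * pi^2 / 3 * agg$rmsf^2, tolerance = 1e-12)
  # permutation invariance
  expect_equal(replica_aggregate(list(p2, p1))$rmsf, agg$rmsf,
               tolerance = 1e-15)
})

test_that("model-set B-factors agree with the ensemble estimator", {
  s <- as_structure(small_complex())
  ens <- gaussian_ensemble(s, 0.4, n_frames = 500, seed = 44)
  models <- lapply(seq(1, 500, by = 1), function(i) ens_frame(ens, i))
  pf_models <- bfactor_from_models(models)
  expect_identical(pf_models$aggregation, "model_set")
  # duplicates fluctuate not at all
  dup <- bfactor_from_models(list(s, s, s))
  expect_equal(max(dup$b), 0, tolerance = 1e-12)
  # analytic calibration at n = 500
  expect_lt(abs(mean(pf_models$b) - 8 * pi^2 * 0.4^2) / (8 * pi^2 * 0.4^2),
            0.10)
  # cross-implementation consistency with rmsf_profile on the same frames
  pf_ens <- rmsf_profile(ens)
  expect_equal(pf_models$b, pf_ens$b, tolerance = 1e-10)
  expect_error(bfactor_from_models(models[1]))
})
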