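test_that("kabsch superposition is exact on rigid motions and rejects degenerate input", {
  set.seed(42)
  m <- matrix(rnorm(15, sd = 3), 5, 3)
  self <- kabsch_superpose(m, m)
  expect_equal(self$rmsd, 0, tolerance = 1e-10)
  expect_equal(self$rotation, diag(3), tolerance = 1e-8)
  expect_equal(det(self$rotation), 1, tolerance = 1e-10)

  th <- pi / 2
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
               3, 3, byrow = TRUE)
  moved <- sweep(m %*% t(Rz), 2, c(5, 0, 0), "+")
  fit <- kabsch_superpose(m, moved)
  expect_lt(fit$rmsd, 1e-8)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)

  expect_error(kabsch_superpose(m[1:2, ], m[1:2, ]), "at least 3")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("kabsch rmsd matches the quaternion-grid brute-force oracle", {
  set.seed(7)
  for (k in 1:10) {
    a <- matrix(rnorm(15, sd = 2), 5, 3)
    b <- a %*% t(rand_rotation()) + matrix(rnorm(15, sd = 0.4), 5, 3)
    expect_equal(kabsch_superpose(a, b)$rmsd, brute_force_min_rmsd(a, b),
                 tolerance = 1e-6)
  }
})

test_that("weighted superposition downweights the intended atoms", {
  set.seed(3)
  a <- matrix(rnorm(18, sd = 2), 6, 3)
  b <- a; b[1, ] <- b[1, ] + c(4, 0, 0)   # one outlier atom
  w_out <- c(1, rep(1, 5))
  w_in <- c(1e-6, rep(1, 5))
  expect_lt(kabsch_superpose(a, b, w_in)$rmsd,
            kabsch_superpose(a, b, w_out)$rmsd)
})

test_that("rmsd series vanishes on rigid-body ensembles and bounds single displacements", {
  ref <- build_ideal_helix(8, "alpha")
  rigid <- rigid_body_ensemble(ref, 20, seed = 5)
  r <- rmsd_series(rigid, ref)
  expect_true(all(r$values < 1e-6))

  # displace one CA by d in one frame: that frame's RMSD is <= d, others 0
  traj <- trajectory_ensemble(
    matrix(rep(as.vector(t(ref$xyz)), 4), nrow = 4, byrow = TRUE), ref)
  ca <- select_atoms(ref, "calpha")[3]
  d <- 2.5
  traj$xyz[2, 3 * ca - 2] <- traj$xyz[2, 3 * ca - 2] + d
  r2 <- rmsd_series(traj, ref)
  expect_equal(r2$values[-2], rep(0, 3), tolerance = 1e-8)
  expect_gt(r2$values[2], 0)
  expect_lt(r2$values[2], d)

  expect_error(rmsd_series(traj, ref, selection = integer()), "selection|indices")
})

test_that("gaussian ensembles reproduce the closed-form mean RMSD near sigma*sqrt(3)", {
  ref <- build_ideal_helix(40, "alpha")
  sigma <- 0.5
  traj <- gaussian_ensemble(ref, sigma, n_frames = 150, seed = 9)
  vals <- rmsd_series(traj, ref)$values
  expected <- sigma * sqrt(3)
  # superposition removes 6 of the 3n dof, so the mean sits just below
  expect_lt(mean(vals), expected)
  expect_gt(mean(vals), 0.95 * expected)
})

test_that("rmsf recovers prescribed Gaussian amplitudes and their ratios", {
  ref <- build_ideal_helix(15, "alpha")
  sigma <- 0.4041
  traj <- gaussian_ensemble(ref, sigma, n_frames = 4000, seed = 21)
  prof <- rmsf_per_residue(traj, "calpha", align = FALSE)
  expect_equal(mean(prof$rmsf), sigma * sqrt(3), tolerance = 0.02)

  # residue 5 with doubled sigma shows doubled RMSF
  s <- rep(0.3, 15); s[5] <- 0.6
  traj2 <- gaussian_ensemble(ref, s, n_frames = 4000, seed = 22)
  prof2 <- rmsf_per_residue(traj2, "calpha", align = FALSE)
  expect_equal(prof2$rmsf[5] / mean(prof2$rmsf[-5]), 2, tolerance = 0.05)
})

test_that("rmsf is invariant under a global rigid motion when alignment is on", {
  ref <- build_ideal_helix(10, "alpha")
  traj <- gaussian_ensemble(ref, 0.4, n_frames = 300, seed = 13)
  prof <- rmsf_per_residue(traj, "calpha", align = TRUE)
  set.seed(99)
  moved <- transform_trajectory(traj, rand_rotation(), c(3, -8, 2))
  prof_moved <- rmsf_per_residue(moved, "calpha", align = TRUE)
  expect_equal(prof_moved$rmsf, prof$rmsf, tolerance = 1e-8)

  rmsd_moved <- rmsd_series(moved, ref)$values
  rmsd_orig <- rmsd_series(traj, ref)$values
  expect_equal(rmsd_moved, rmsd_orig, tolerance = 1e-8)

  rigid <- rigid_body_ensemble(ref, 30, seed = 4)
  expect_true(all(rmsf_per_residue(rigid, "calpha", align = TRUE)$rmsf < 1e-6))
  expect_error(rmsf_per_residue(traj, window = c(0, 10)), "window")
})

test_that("radius of gyration matches closed forms and direct summation", {
  two <- structure_model(c("CA", "CA"), c(0L, 1L),
                         rbind(c(0, 0, 0), c(2, 0, 0)),
                         rep("ALA", 2), element = c("C", "C"))
  expect_equal(radius_of_gyration(two, "all", mass_weighted = FALSE), 1.0)

  one <- structure_model("CA", 0L, matrix(c(1, 2, 3), 1), "ALA",
                         element = "C")
  expect_equal(radius_of_gyration(one, "all"), 0)

  corners <- as.matrix(expand.grid(c(0, 2), c(0, 2), c(0, 2)))
  cube <- structure_model(rep("CA", 8), 0:7, corners, rep("ALA", 8),
                          element = rep("C", 8))
  expect_equal(radius_of_gyration(cube, "all", mass_weighted = FALSE),
               sqrt(3), tolerance = 1e-12)
  expect_equal(radius_of_gyration(cube, "all", mass_weighted = FALSE),
               rg_direct(corners), tolerance = 1e-12)

  # mass weighting agrees with the weighted direct sum
  set.seed(2)
  xyz <- matrix(rnorm(30, sd = 4), 10, 3)
  mdl <- structure_model(rep(c("C", "N", "O", "S", "CA"), 2), 0:9, xyz,
                         rep("ALA", 10),
                         element = rep(c("C", "N", "O", "S", "C"), 2))
  expect_equal(radius_of_gyration(mdl, "all", mass_weighted = TRUE),
               rg_direct(xyz, mdl$masses), tolerance = 1e-12)

  rigid <- rigid_body_ensemble(build_ideal_helix(6, "pi"), 25, seed = 8)
  rg <- radius_of_gyration_series(rigid)$values
  expect_lt(diff(range(rg)), 1e-8)
})

test_that("block averaging reproduces means exactly and errors sanely", {
  const <- time_series(rep(3.2, 100))
  bs <- block_average(const, 10)
  expect_equal(bs$mean, 3.2)
  expect_equal(bs$standard_error, 0)
  expect_equal(bs$n_blocks, 10)

  set.seed(5)
  v <- rnorm(1200)
  for (bl in c(10, 20, 60)) {   # block length divides the window
    expect_equal(block_average(v, bl)$mean, mean(v), tolerance = 1e-12)
  }
  # trailing partial block is discarded, never padded
  expect_equal(block_average(v, 500)$mean, mean(v[1:1000]), tolerance = 1e-12)

  expect_error(block_average(v, 1200), "insufficient")
})

test_that("block standard errors track the i.i.d. sampling distribution", {
  # oracle: 400 replicate series, 16 blocks of 500, unit variance
  set.seed(17)
  ses <- replicate(400, block_average(rnorm(8000), 500)$standard_error)
  expect_equal(mean(ses), 1 / sqrt(8000), tolerance = 0.05)
})

test_that("density estimates are normalized and match uniform ground truth", {
  d1 <- distribution_estimate(time_series(rep(12, 50)), 0.5)
  expect_equal(sum(d1$density) * 0.5, 1, tolerance = 1e-12)
  expect_equal(max(d1$density), 1 / 0.5)

  set.seed(31)
  u <- runif(40000, 10, 14)
  du <- distribution_estimate(u, 0.5)
  expect_equal(sum(du$density) * 0.5, 1, tolerance = 1e-12)
  inner <- du$density[du$bin_mid > 10.5 & du$bin_mid < 13.5]
  expect_equal(inner, rep(0.25, length(inner)), tolerance = 0.05)

  set.seed(32)
  g <- rnorm(500, 5, 2)
  dg <- distribution_estimate(g, 0.3)
  expect_equal(sum(dg$density) * 0.3, 1, tolerance = 1e-12)
  expect_error(distribution_estimate(g, -1), "positive")
})
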