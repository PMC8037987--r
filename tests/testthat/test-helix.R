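test_that("dihedral extraction honours constructed torsion geometry", {
  mk <- function(p4) {
    xyz <- rbind(c(1, 1, 0), c(1, 0, 0), c(0, 0, 0), p4)
    model <- structure_model(c("C", "N", "CA", "C"), c(0L, 1L, 1L, 1L),
                            xyz, c("ACE", "ALA"), element = c("C", "N", "C", "C"))
    # phi of residue 2 is the torsion over these four atoms
    traj <- trajectory_ensemble(matrix(as.vector(t(xyz)), nrow = 1), model)
    suppressWarnings(backbone_dihedrals(traj))$phi[1, 2]
  }
  expect_equal(mk(c(-1, -1, 0)), 180)          # planar trans zigzag
  expect_equal(mk(c(-1, 1, 0)), 0)             # cis
  expect_equal(abs(mk(c(-1, 0, 1))), 90)
  # chirality: z-negation flips the sign
  expect_equal(mk(c(-1, 0, 1)), -mk(c(-1, 0, -1)))
})

test_that("builder and dihedral extractor are mutual inverses", {
  for (ty in c("alpha", "pi", "three_ten")) {
    h <- build_ideal_helix(15, ty)
    traj <- trajectory_ensemble(matrix(as.vector(t(h$xyz)), nrow = 1), h)
    d <- backbone_dihedrals(traj)
    target <- switch(ty, alpha = c(-57, -47), pi = c(-57, -70),
                     three_ten = c(-49, -26))
    expect_equal(unname(d$phi[1, 2:15]), rep(target[1], 14), tolerance = 0.5)
    expect_equal(unname(d$psi[1, 1:14]), rep(target[2], 14), tolerance = 0.5)
    expect_true(is.na(d$phi[1, 1]) && is.na(d$psi[1, 15]))
  }
  # arbitrary dihedral series rebuild to the same angles
  set.seed(12)
  dih <- two_state_dihedral_series(runif(8, 0.2, 0.8), "alpha",
                                   n_frames = 5, seed = 3)
  traj <- dihedral_ensemble(dih)
  back <- backbone_dihedrals(traj)
  expect_equal(back$phi[, 2:8], dih$phi[, 2:8], tolerance = 1e-6)
  expect_equal(back$psi[, 1:7], dih$psi[, 1:7], tolerance = 1e-6)
})

test_that("sequential classification requires runs of three in-window residues", {
  all_in <- const_dihedrals(rep(-60, 15), rep(-45, 15))
  expect_true(all(classify_sequential_alpha(all_in)))

  alt_phi <- rep(c(-60, 100), length.out = 15)
  alternating <- const_dihedrals(alt_phi, rep(-45, 15))
  expect_false(any(classify_sequential_alpha(alternating)))

  phi <- rep(100, 15); psi <- rep(100, 15)
  phi[3:5] <- -60; psi[3:5] <- -45
  run3 <- classify_sequential_alpha(const_dihedrals(phi, psi))
  expect_equal(which(run3[1, ]), 3:5)

  phi[3:4] <- -60; phi[5] <- 100
  run2 <- classify_sequential_alpha(const_dihedrals(phi, psi))
  expect_false(any(run2))

  # undefined residues break runs
  phi <- rep(-60, 7); psi <- rep(-45, 7)
  d <- const_dihedrals(phi, psi)
  d$phi[1, 4] <- NA; d$defined[1, 4] <- FALSE
  broken <- classify_sequential_alpha(d)
  expect_equal(which(broken[1, ]), c(1:3, 5:7))
})

test_that("pairwise windows label their centres and boundaries as specified", {
  lab_for <- function(psi_i, phi_next) {
    phi <- c(-120, rep(phi_next, 5))
    psi <- c(rep(psi_i, 5), 140)
    classify_pairwise_helix(const_dihedrals(phi, psi))[1, 3]
  }
  expect_equal(lab_for(-50, -55), "alpha")       # s = -105
  expect_equal(lab_for(-70, -55), "pi")          # s = -125
  expect_equal(lab_for(-30, -45), "three_ten")   # s = -75
  # boundaries: -115 shared edge resolved in favour of alpha
  expect_equal(lab_for(-60, -55), "alpha")       # s = -115
  expect_equal(lab_for(-61, -55), "pi")          # s = -116
  expect_equal(lab_for(-80, -55), "pi")          # s = -135
  expect_equal(lab_for(-81, -55), "none")        # s = -136
  expect_equal(lab_for(-40, -55), "alpha")       # s = -95
  expect_equal(lab_for(-39, -55), "none")        # s = -94
  expect_equal(lab_for(-30, -55), "three_ten")   # s = -85
  expect_equal(lab_for(-10, -55), "three_ten")   # s = -65
  expect_equal(lab_for(-9, -55), "none")         # s = -64
})

test_that("first and last residue pairs are excluded and termini unlabelled", {
  lab <- classify_pairwise_helix(const_dihedrals(rep(-57, 8), rep(-47, 8)))
  expect_true(all(is.na(lab[, c(1, 7, 8)])))
  expect_true(all(lab[, 2:6] == "alpha"))
  expect_error(classify_pairwise_helix(const_dihedrals(rep(-57, 3), rep(-47, 3))),
               ">= 4")
})

test_that("pairwise windows never double-label on random dihedrals", {
  set.seed(23)
  phi <- matrix(runif(200 * 12, -180, 180), 200, 12)
  psi <- matrix(runif(200 * 12, -180, 180), 200, 12)
  d <- dihedral_series(wrap_angle_public(phi), wrap_angle_public(psi))
  lab <- classify_pairwise_helix(d)
  expect_true(all(lab[!is.na(lab)] %in% c("alpha", "pi", "three_ten", "none")))
  # independently recompute the sums and check each label's window once
  s <- psi[, -12] + phi[, -1]
  s <- s - 360 * floor((s + 180) / 360)
  s[, c(1, 11)] <- NA
  sl <- lab[, 1:11]
  expect_true(all(s[sl == "pi" & !is.na(sl)] >= -135 &
                    s[sl == "pi" & !is.na(sl)] < -115))
  expect_true(all(s[sl == "alpha" & !is.na(sl)] >= -115 &
                    s[sl == "alpha" & !is.na(sl)] <= -95))
  expect_true(all(s[sl == "three_ten" & !is.na(sl)] >= -85 &
                    s[sl == "three_ten" & !is.na(sl)] <= -65))
  out <- s[sl == "none" & !is.na(sl)]
  expect_false(any((out >= -135 & out <= -95) | (out >= -85 & out <= -65)))
})

test_that("fraction profiles and temperature comparisons do plain arithmetic", {
  lab <- matrix("none", 10, 6)
  lab[, 2] <- "alpha"                       # always alpha
  lab[1:5, 3] <- "pi"                       # half the frames pi
  lab[, c(1, 6)] <- NA
  prof <- helical_fraction_profile(lab, temperature_label = "300K")
  expect_equal(prof$alpha[2], 100)
  expect_equal(prof$combined[2], 100)
  expect_equal(prof$pi[3], 50)
  expect_equal(prof$combined[3], 50)
  expect_equal(prof$combined[1], 0)
  expect_true(all(prof$combined >= pmax(prof$alpha, prof$pi, prof$three_ten)))
  expect_true(all(prof$combined <= prof$alpha + prof$pi + prof$three_ten))

  same <- compare_temperatures(prof, prof)
  expect_true(all(same$combined == 0))
  # a profile uniformly 5 points lower gives differences of exactly +5
  lower <- helical_fraction_profile(lab, temperature_label = "360K")
  for (cc in c("sequential_alpha", "alpha", "pi", "three_ten", "combined")) {
    lower[[cc]] <- lower[[cc]] - 5
  }
  cmp <- compare_temperatures(prof, lower)
  expect_true(all(cmp$combined == 5))
  expect_equal(unname(attr(cmp, "mean_abs_change")["combined"]), 5)
  bad <- helical_fraction_profile(lab[, 1:4])
  expect_error(compare_temperatures(prof, bad), "residue counts")
})

test_that("sequential alpha content does not exceed combined pairwise on helices and coils", {
  # ideal alpha helix: both definitions saturate the interior
  h <- build_ideal_helix(12, "alpha")
  traj <- trajectory_ensemble(matrix(as.vector(t(h$xyz)), nrow = 1), h)
  d <- backbone_dihedrals(traj)
  prof <- helical_fraction_profile(classify_pairwise_helix(d),
                                   classify_sequential_alpha(d))
  expect_true(all(prof$combined[3:10] == 100))
  expect_true(all(prof$sequential_alpha[2:11] == 100))

  # random-coil torus: sequential runs are rarer than pairwise hits
  set.seed(77)
  nr <- 10; nf <- 4000
  d2 <- dihedral_series(
    wrap_angle_public(matrix(runif(nf * nr, -180, 180), nf, nr)),
    wrap_angle_public(matrix(runif(nf * nr, -180, 180), nf, nr)))
  p2 <- helical_fraction_profile(classify_pairwise_helix(d2),
                                 classify_sequential_alpha(d2))
  expect_lt(mean(p2$sequential_alpha), mean(p2$combined))
})
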