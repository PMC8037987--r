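# Programmatic fixtures: tiny PDB texts and small reference models built
# in code at test time.

# 3-residue Ala-Ala-Ala with backbone + CB, hand-positioned coordinates.
tripeptide_pdb_lines <- function(drop_ca2 = FALSE, with_waters = FALSE) {
  atoms <- list(
    # name, resno, x, y, z
    list("N", 1, 0.000, 0.000, 0.000), list("CA", 1, 1.458, 0.000, 0.000),
    list("C", 1, 2.009, 1.420, 0.000), list("O", 1, 1.251, 2.390, 0.000),
    list("CB", 1, 1.988, -0.773, -1.199),
    list("N", 2, 3.332, 1.536, 0.000), list("CA", 2, 4.037, 2.809, 0.110),
    list("C", 2, 5.530, 2.591, 0.330), list("O", 2, 6.010, 1.460, 0.350),
    list("CB", 2, 3.810, 3.680, -1.130),
    list("N", 3, 6.260, 3.690, 0.500), list("CA", 3, 7.700, 3.640, 0.720),
    list("C", 3, 8.410, 4.980, 0.650), list("O", 3, 7.780, 6.030, 0.540),
    list("CB", 3, 8.320, 2.700, 1.760))
  lines <- character()
  serial <- 0
  for (a in atoms) {
    if (drop_ca2 && a[[1]] == "CA" && a[[2]] == 2) next
    serial <- serial + 1
    name <- if (nchar(a[[1]]) >= 4) a[[1]] else formatC(paste0(" ", a[[1]]), width = -4)
    lines <- c(lines, sprintf(
      "ATOM  %5d %4s ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           %2s",
      serial, name, a[[2]], a[[3]], a[[4]], a[[5]], substr(a[[1]], 1, 1)))
    if (with_waters && a[[1]] == "O") {   # interleave a water after each O
      serial <- serial + 1
      lines <- c(lines, sprintf(
        "HETATM%5d  O   HOH A%4d    %8.3f%8.3f%8.3f  1.00  0.00           O",
        serial, 100 + a[[2]], a[[3]] + 5, a[[4]] + 5, a[[5]] + 5))
    }
  }
  c(lines, "TER", "END")
}

write_tripeptide_pdb <- function(path = tempfile(fileext = ".pdb"), ...) {
  writeLines(tripeptide_pdb_lines(...), path)
  path
}

# Uniformly random proper rotation matrix.
rand_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# Apply one rigid motion to every frame of a trajectory.
transform_trajectory <- function(traj, R, t) {
  xyz <- t(apply(traj$xyz, 1, function(row) {
    m <- matrix(row, ncol = 3, byrow = TRUE)
    as.vector(t(sweep(m %*% t(R), 2, t, "+")))
  }))
  trajectory_ensemble(xyz, traj$topology)
}

# Wrap angles to (-180, 180] (local copy, kept independent of the package).
wrap_angle_public <- function(x) {
  w <- x - 360 * floor((x + 180) / 360)
  w[!is.na(w) & w == -180] <- 180
  w
}

# DihedralSeries from constant per-residue angles replicated over frames.
const_dihedrals <- function(phi, psi, n_frames = 1) {
  dihedral_series(matrix(phi, n_frames, length(phi), byrow = TRUE),
                  matrix(psi, n_frames, length(psi), byrow = TRUE))
}
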