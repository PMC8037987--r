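## Ensembles with known ground truth — ideal helices, Gaussian-fluctuation
## ensembles, rigid-body ensembles and two-state helix/coil dihedral
## series — so every analysis stage is testable without running MD.

## Canonical backbone dihedrals (degrees) of the three helix types.
.helix_dihedrals <- list(
  alpha     = c(phi = -57, psi = -47),
  pi        = c(phi = -57, psi = -70),
  three_ten = c(phi = -49, psi = -26)
)

## Fixed standard backbone geometry for internal-coordinate chain building.
.bb_geometry <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329,        # bond lengths, A
  a_n_ca_c = 111.2, a_ca_c_n = 116.6, a_c_n_ca = 121.7, # bond angles, deg
  omega = 180                                            # trans peptide
)

## Place a new atom at distance `bond` from c, bond angle `angle` (deg) to
## b-c, and torsion `torsion` (deg) about b-c measured a-b-c-new (NeRF).
place_atom <- function(a, b, c, bond, angle, torsion) {
  th <- angle * pi / 180
  ph <- -torsion * pi / 180   # sign matches the IUPAC convention of torsion_angle()
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  n <- c((b - a)[2] * bc[3] - (b - a)[3] * bc[2],
         (b - a)[3] * bc[1] - (b - a)[1] * bc[3],
         (b - a)[1] * bc[2] - (b - a)[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d <- c(-bond * cos(th), bond * sin(th) * cos(ph), bond * sin(th) * sin(ph))
  c + cbind(bc, m, n) %*% d
}

## Internal-coordinate chain building of an N/CA/C backbone from
## per-residue (phi, psi) vectors; phi[1] and psi[n] are unused.
chain_xyz <- function(phi, psi) {
  g <- .bb_geometry
  n <- length(phi)
  xyz <- matrix(NA_real_, 3L * n, 3)
  ## first residue placed in the xy-plane
  xyz[1, ] <- c(0, 0, 0)                                  # N1
  xyz[2, ] <- c(g$b_n_ca, 0, 0)                           # CA1
  th <- g$a_n_ca_c * pi / 180
  xyz[3, ] <- xyz[2, ] + g$b_ca_c * c(-cos(th), sin(th), 0)  # C1
  for (i in 2:n) {
    k <- 3L * (i - 1L)
    xyz[k + 1, ] <- place_atom(xyz[k - 2, ], xyz[k - 1, ], xyz[k, ],
                               g$b_c_n, g$a_ca_c_n, psi[i - 1])   # N(i)
    xyz[k + 2, ] <- place_atom(xyz[k - 1, ], xyz[k, ], xyz[k + 1, ],
                               g$b_n_ca, g$a_c_n_ca, g$omega)     # CA(i)
    xyz[k + 3, ] <- place_atom(xyz[k, ], xyz[k + 1, ], xyz[k + 2, ],
                               g$b_ca_c, g$a_n_ca_c, phi[i])      # C(i)
  }
  xyz
}

backbone_model <- function(xyz, n) {
  structure_model(
    atom_names = rep(c("N", "CA", "C"), n),
    residue_index = rep(seq_len(n) - 1L, each = 3L),
    xyz = xyz,
    residue_names = rep("ALA", n),
    element = rep(c("N", "C", "C"), n),
    chain_id = "A")
}

#' Build a poly-alanine backbone from prescribed dihedrals
#'
#' Internal-coordinate chain building of an N/CA/C backbone with standard
#' bond lengths and angles and trans peptide bonds (omega = 180), from
#' per-residue phi/psi vectors. `phi[1]` and `psi[n]` are undefined for a
#' chain and ignored.
#'
#' @param phi,psi numeric vectors of equal length (>= 2), degrees.
#' @return a [structure_model()] with atoms N, CA, C per residue.
#' @export
build_backbone <- function(phi, psi) {
  stopifnot(length(phi) == length(psi), length(phi) >= 2)
  backbone_model(chain_xyz(phi, psi), length(phi))
}

#' Build an ideal poly-alanine helix
#'
#' Constructs an N/CA/C backbone by internal-coordinate chain building with
#' canonical dihedrals — alpha (phi, psi) = (-57, -47), pi (-57, -70),
#' 3-10 (-49, -26) degrees — standard bond lengths and angles, and trans
#' peptide bonds (omega = 180).
#'
#' @param n_residues chain length (>= 4).
#' @param helix_type `"alpha"`, `"pi"` or `"three_ten"`.
#' @return a [structure_model()] with atoms N, CA, C per residue.
#' @export
build_ideal_helix <- function(n_residues,
                              helix_type = c("alpha", "pi", "three_ten")) {
  helix_type <- match.arg(helix_type)
  if (n_residues < 4)
    stop("an ideal helix needs at least 4 residues", call. = FALSE)
  ang <- .helix_dihedrals[[helix_type]]
  build_backbone(rep(ang["phi"], n_residues), rep(ang["psi"], n_residues))
}

#' Coordinate ensemble realizing a dihedral series
#'
#' Rebuilds a poly-alanine backbone frame by frame from a
#' [dihedral_series()], giving a coordinate trajectory whose ground-truth
#' dihedrals are known exactly — the bridge that lets dihedral-level
#' generators (e.g. [two_state_dihedral_series()]) exercise the full
#' coordinate-level pipeline.
#'
#' @param dihedrals a `DihedralSeries` with no missing interior angles
#'   (`phi[, 1]` / `psi[, n]` may be anything).
#' @return a [trajectory_ensemble()].
#' @export
dihedral_ensemble <- function(dihedrals) {
  stopifnot(inherits(dihedrals, "DihedralSeries"))
  phi <- dihedrals$phi; psi <- dihedrals$psi
  nr <- ncol(phi)
  if (anyNA(phi[, -1]) || anyNA(psi[, -nr]))
    stop("interior dihedrals must all be defined", call. = FALSE)
  phi[is.na(phi)] <- -120; psi[is.na(psi)] <- 140   # unused terminal slots
  topo <- backbone_model(chain_xyz(phi[1, ], psi[1, ]), nr)
  xyz <- matrix(NA_real_, nrow(phi), 9L * nr)
  for (f in seq_len(nrow(phi))) {
    xyz[f, ] <- mat2vec(chain_xyz(phi[f, ], psi[f, ]))
  }
  trajectory_ensemble(xyz, topo)
}

expand_sigma <- function(reference, per_atom_sigma) {
  na <- n_atoms(reference)
  s <- as.numeric(per_atom_sigma)
  if (any(s < 0)) stop("`per_atom_sigma` must be non-negative", call. = FALSE)
  if (length(s) == 1) s <- rep(s, na)
  else if (length(s) == n_residues(reference))
    s <- s[reference$residue_index + 1L]
  else if (length(s) != na)
    stop("`per_atom_sigma` must be scalar, per-residue or per-atom",
         call. = FALSE)
  s
}

#' Gaussian-fluctuation ensemble around a rigid reference
#'
#' Each frame is the reference plus independent zero-mean Gaussian
#' displacements with per-coordinate standard deviation sigma (scalar,
#' per-residue or per-atom). The isotropic displacement makes closed-form
#' ground truth available: the expected RMSF of every atom is sigma*sqrt(3).
#'
#' @param reference a `StructureModel`.
#' @param per_atom_sigma displacement sigma in Angstrom.
#' @param n_frames number of frames (>= 1).
#' @param seed RNG seed for reproducibility.
#' @return a [trajectory_ensemble()].
#' @export
gaussian_ensemble <- function(reference, per_atom_sigma, n_frames,
                              seed = NULL) {
  if (n_frames < 1) stop("`n_frames` must be >= 1", call. = FALSE)
  s <- expand_sigma(reference, per_atom_sigma)
  sd_coord <- rep(s, each = 3)          # x, y, z share the per-atom sigma
  ref <- mat2vec(reference$xyz)
  noise <- with_seed(seed,
    matrix(stats::rnorm(n_frames * length(ref)), nrow = n_frames, byrow = TRUE))
  xyz <- sweep(noise, 2, sd_coord, "*")
  xyz <- sweep(xyz, 2, ref, "+")
  trajectory_ensemble(xyz, reference)
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Rigid-body ensemble
#'
#' Each frame is the reference under a uniformly random proper rotation
#' (quaternion method) and a bounded uniform random translation. All
#' internal coordinates are exactly preserved, so aligned RMSD/RMSF vanish
#' and Rg is constant.
#'
#' @param reference a `StructureModel`.
#' @param n_frames number of frames (>= 1).
#' @param seed RNG seed.
#' @param max_translation half-width of the uniform translation cube (A).
#' @return a [trajectory_ensemble()].
#' @export
rigid_body_ensemble <- function(reference, n_frames, seed = NULL,
                                max_translation = 10) {
  if (n_frames < 1) stop("`n_frames` must be >= 1", call. = FALSE)
  ref <- reference$xyz
  xyz <- with_seed(seed, {
    out <- matrix(NA_real_, n_frames, 3 * nrow(ref))
    for (f in seq_len(n_frames)) {
      R <- random_rotation()
      tr <- stats::runif(3, -max_translation, max_translation)
      out[f, ] <- mat2vec(sweep(ref %*% t(R), 2, tr, "+"))
    }
    out
  })
  trajectory_ensemble(xyz, reference)
}

## Coil-state dihedral region (broad beta-like basin). Chosen, together
## with the small helical jitter, so that psi(i) + phi(i+1) stays outside
## every pairwise helix window for coil/coil, coil/helix and helix/coil
## pairs; only helix/helix pairs classify as helical, making the
## prescribed state probability the exact expected recovered helicity.
.coil_phi_range <- c(-180, -130)
.coil_psi_range <- c(120, 170)

#' Two-state helix/coil dihedral series with prescribed helicity
#'
#' Per frame, each dihedral pair (psi(i), phi(i+1)) independently draws the
#' helical state with probability `helicity_probs[i]` — canonical dihedrals
#' of `helix_type` plus small Gaussian jitter — and otherwise the coil
#' state (uniform over a broad non-helical basin). Attaching the two-state
#' variable to the pair (rather than to a single residue's two angles)
#' makes `helicity_probs` the exact expected per-residue helicity under the
#' pairwise classifier, so parameter-recovery ground truth is exact.
#'
#' @param helicity_probs per-residue helical probability in `[0, 1]`;
#'   probability i governs the pair (i, i+1), so the last entry and the
#'   classifier-excluded first/last pairs do not contribute.
#' @param helix_type `"alpha"`, `"pi"` or `"three_ten"`.
#' @param n_frames number of frames.
#' @param seed RNG seed.
#' @param jitter_sd Gaussian jitter on helical dihedrals, degrees. The
#'   default 2 keeps the in-window probability of a helical pair above
#'   99.9%.
#' @return a [dihedral_series()].
#' @export
two_state_dihedral_series <- function(helicity_probs,
                                      helix_type = c("alpha", "pi", "three_ten"),
                                      n_frames, seed = NULL, jitter_sd = 2) {
  helix_type <- match.arg(helix_type)
  p <- as.numeric(helicity_probs)
  if (any(p < 0 | p > 1))
    stop("`helicity_probs` must lie in [0, 1]", call. = FALSE)
  nr <- length(p)
  if (nr < 4) stop("need at least 4 residues", call. = FALSE)
  ang <- .helix_dihedrals[[helix_type]]
  with_seed(seed, {
    ## state[f, i] governs psi(i) and phi(i+1)
    state <- matrix(stats::runif(n_frames * nr), n_frames, nr) <=
      matrix(p, n_frames, nr, byrow = TRUE)
    draw <- function(helical_value, coil_range, h) {
      v <- matrix(stats::runif(length(h), coil_range[1], coil_range[2]),
                  nrow(h), ncol(h))
      nh <- sum(h)
      if (nh > 0) v[h] <- helical_value + stats::rnorm(nh, 0, jitter_sd)
      v
    }
    psi <- draw(ang["psi"], .coil_psi_range, state)
    phi <- matrix(NA_real_, n_frames, nr)
    phi[, -1] <- draw(ang["phi"], .coil_phi_range,
                      state[, -nr, drop = FALSE])
    phi[, 1] <- stats::runif(n_frames, .coil_phi_range[1], .coil_phi_range[2])
    psi[, nr] <- stats::runif(n_frames, .coil_psi_range[1], .coil_psi_range[2])
    dihedral_series(wrap_angle(phi), wrap_angle(psi))
  })
}
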