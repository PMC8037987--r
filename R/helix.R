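## Backbone dihedrals and residue-resolved helicity under two definitions:
## the sequential three-residue alpha criterion and the pairwise
## psi(i) + phi(i+1) criterion that distinguishes alpha, pi and 3(10)
## helices.

#' Construct a DihedralSeries
#'
#' @param phi,psi numeric matrices, frames x residues, angles in degrees on
#'   (-180, 180], `NA` where undefined (terminal or missing-atom residues).
#' @param residue_labels per-residue labels (original residue numbers).
#' @return object of class `DihedralSeries`; `defined` marks residues with
#'   both angles defined in a frame.
#' @export
dihedral_series <- function(phi, psi, residue_labels = NULL) {
  phi <- as.matrix(phi); psi <- as.matrix(psi)
  stopifnot(identical(dim(phi), dim(psi)))
  rng <- range(c(phi, psi), na.rm = TRUE)
  if (rng[1] <= -180 || rng[2] > 180)
    stop("angles must lie in (-180, 180] degrees", call. = FALSE)
  if (is.null(residue_labels)) residue_labels <- seq_len(ncol(phi))
  structure(list(phi = phi, psi = psi,
                 defined = !is.na(phi) & !is.na(psi),
                 residue_labels = as.integer(residue_labels)),
            class = "DihedralSeries")
}

#' @export
print.DihedralSeries <- function(x, ...) {
  cat(sprintf("DihedralSeries: %d frames x %d residues (%.1f%% defined)\n",
              nrow(x$phi), ncol(x$phi), 100 * mean(x$defined)))
  invisible(x)
}

## Per-residue indices of one named backbone atom (NA when absent).
backbone_atom_index <- function(model, name) {
  idx <- rep(NA_integer_, n_residues(model))
  hit <- which(model$atom_names == name)
  hit <- hit[!duplicated(model$residue_index[hit])]
  idx[model$residue_index[hit] + 1L] <- hit
  idx
}

#' Backbone phi/psi dihedral angles over a trajectory
#'
#' phi(i) from C(i-1)-N(i)-CA(i)-C(i) and psi(i) from
#' N(i)-CA(i)-C(i)-N(i+1). Terminal residues (or residues with missing
#' backbone atoms) are masked undefined; Ace/Nme capping residues, when
#' present in the topology, contribute the flanking C/N atoms and so extend
#' the defined range by one residue at each end.
#'
#' @param traj a `TrajectoryEnsemble` whose topology provides N, CA, C
#'   atoms.
#' @return a [dihedral_series()] (frames x residues, degrees).
#' @export
backbone_dihedrals <- function(traj) {
  model <- traj$topology
  nr <- n_residues(model)
  nf <- n_frames(traj)
  iN  <- backbone_atom_index(model, "N")
  iCA <- backbone_atom_index(model, "CA")
  iC  <- backbone_atom_index(model, "C")
  ## residues usable as dihedral centres need their own N, CA, C
  centre_ok <- !is.na(iN) & !is.na(iCA) & !is.na(iC)
  if (any(!centre_ok & model$residue_names %in% .aa3)) {
    bad <- model$residue_labels[!centre_ok & model$residue_names %in% .aa3]
    warning(sprintf("missing backbone atoms; residue(s) %s masked undefined",
                    paste(bad, collapse = ", ")), call. = FALSE)
  }
  grab <- function(atom_idx) traj$xyz[, xyz_cols(atom_idx), drop = FALSE]
  phi <- matrix(NA_real_, nf, nr)
  psi <- matrix(NA_real_, nf, nr)
  for (i in seq_len(nr)) {
    if (!centre_ok[i]) next
    if (i > 1 && !is.na(iC[i - 1])) {
      phi[, i] <- torsion_angle(grab(iC[i - 1]), grab(iN[i]),
                                grab(iCA[i]), grab(iC[i]))
    }
    if (i < nr && !is.na(iN[i + 1])) {
      psi[, i] <- torsion_angle(grab(iN[i]), grab(iCA[i]),
                                grab(iC[i]), grab(iN[i + 1]))
    }
  }
  ## cap residues themselves carry no (phi, psi)
  is_cap <- model$residue_names %in% .caps
  phi[, is_cap] <- NA_real_
  psi[, is_cap] <- NA_real_
  dihedral_series(phi, psi, model$residue_labels)
}

## Classification windows (degrees). Pairwise windows on s = psi(i) +
## phi(i+1): the shared boundary at -115 between the pi and alpha windows
## is resolved half-open in favour of alpha.
.seq_phi_window <- c(-160, -30)
.seq_psi_window <- c(-67, -7)
.pairwise_windows <- list(
  pi        = c(-135, -115),   # [-135, -115)
  alpha     = c(-115, -95),    # [-115, -95]
  three_ten = c(-85, -65)      # [-85, -65]
)

#' Sequential three-residue alpha-helix classification
#'
#' A residue is helical in a frame iff it belongs to a run of at least
#' three consecutive residues whose dihedrals all fall in the broad
#' alpha-basin windows phi in [-160, -30] and psi in [-67, -7] in that
#' frame. Undefined residues break runs.
#'
#' @param dihedrals a `DihedralSeries`.
#' @return logical matrix, frames x residues.
#' @export
classify_sequential_alpha <- function(dihedrals) {
  stopifnot(inherits(dihedrals, "DihedralSeries"))
  phi <- dihedrals$phi; psi <- dihedrals$psi
  w <- !is.na(phi) & !is.na(psi) &
    phi >= .seq_phi_window[1] & phi <= .seq_phi_window[2] &
    psi >= .seq_psi_window[1] & psi <= .seq_psi_window[2]
  nr <- ncol(w)
  pad <- function(k) {           # w shifted by k residues, FALSE beyond ends
    out <- matrix(FALSE, nrow(w), nr)
    src <- seq_len(nr) + k
    ok <- src >= 1 & src <= nr
    out[, ok] <- w[, src[ok], drop = FALSE]
    out
  }
  l1 <- pad(-1); l2 <- pad(-2); r1 <- pad(1); r2 <- pad(2)
  (w & l1 & l2) | (l1 & w & r1) | (w & r1 & r2)
}

#' Pairwise helix classification (alpha / pi / 3-10)
#'
#' For each residue pair (i, i+1) the sum s = psi(i) + phi(i+1), wrapped to
#' (-180, 180], is tested against -125 +/- 10 (pi), -105 +/- 10 (alpha) and
#' -75 +/- 10 (3-10); the label is attributed to residue i. The pair
#' involving the first defined residue and the pair involving the last
#' defined residue are excluded.
#'
#' @param dihedrals a `DihedralSeries` covering at least 4 residues.
#' @return character matrix, frames x residues, values `"alpha"`, `"pi"`,
#'   `"three_ten"` or `"none"`; `NA` for residues with no classified pair.
#' @export
classify_pairwise_helix <- function(dihedrals) {
  stopifnot(inherits(dihedrals, "DihedralSeries"))
  nr <- ncol(dihedrals$phi)
  if (nr < 4) stop("pairwise classification needs >= 4 residues", call. = FALSE)
  s <- wrap_angle(dihedrals$psi[, -nr, drop = FALSE] +
                  dihedrals$phi[, -1, drop = FALSE])
  pair_defined <- colSums(!is.na(s)) > 0
  if (any(pair_defined)) {
    dr <- range(which(pair_defined))
    s[, dr] <- NA_real_                 # first and last residue pairs excluded
  }
  lab <- matrix(NA_character_, nrow(s), nr)
  sl <- matrix("none", nrow(s), ncol(s))
  sl[s >= .pairwise_windows$pi[1] & s < .pairwise_windows$pi[2]] <- "pi"
  sl[s >= .pairwise_windows$alpha[1] & s <= .pairwise_windows$alpha[2]] <- "alpha"
  sl[s >= .pairwise_windows$three_ten[1] & s <= .pairwise_windows$three_ten[2]] <- "three_ten"
  sl[is.na(s)] <- NA_character_
  lab[, seq_len(nr - 1)] <- sl
  lab
}

#' Per-residue helical fraction profile
#'
#' Percent of frames in which each residue carries each pairwise label,
#' plus `combined` (any of alpha/pi/3-10) and, when supplied, the
#' sequential-alpha fraction. Residues without a classified pair (terminal
#' and excluded pairs) count as non-helical.
#'
#' @param pairwise character label matrix from [classify_pairwise_helix()].
#' @param sequential optional logical matrix from
#'   [classify_sequential_alpha()].
#' @param temperature_label free-text label (e.g. `"300K"`).
#' @param residue_labels optional per-residue labels.
#' @return data frame of class `HelixProfile` (one row per residue) with
#'   percentages in 0-100; frame count and temperature label stored as
#'   attributes.
#' @export
helical_fraction_profile <- function(pairwise, sequential = NULL,
                                     temperature_label = "",
                                     residue_labels = NULL) {
  nf <- nrow(pairwise); nr <- ncol(pairwise)
  if (nf < 1) stop("need at least one frame", call. = FALSE)
  pct <- function(m) 100 * colSums(m, na.rm = TRUE) / nf
  out <- data.frame(
    residue = residue_labels %||% seq_len(nr),
    sequential_alpha = if (is.null(sequential)) NA_real_ else pct(sequential),
    alpha = pct(pairwise == "alpha"),
    pi = pct(pairwise == "pi"),
    three_ten = pct(pairwise == "three_ten"),
    combined = pct(!is.na(pairwise) &
                     (pairwise == "alpha" | pairwise == "pi" |
                        pairwise == "three_ten")))
  attr(out, "n_frames") <- nf
  attr(out, "temperature_label") <- temperature_label
  class(out) <- c("HelixProfile", "data.frame")
  out
}

#' Per-residue helicity change between two conditions
#'
#' Differences (a - b) of the per-residue percentages for every category,
#' with the mean absolute change per category as a summary attribute —
#' e.g. helicity at two temperatures to quantify a disorder-to-order
#' transition.
#'
#' @param profile_a,profile_b `HelixProfile` objects with equal residue
#'   counts.
#' @return data frame of class `HelixComparison`; `mean_abs_change`
#'   attribute holds the per-category summary.
#' @export
compare_temperatures <- function(profile_a, profile_b) {
  stopifnot(inherits(profile_a, "HelixProfile"),
            inherits(profile_b, "HelixProfile"))
  if (nrow(profile_a) != nrow(profile_b))
    stop("profiles cover different residue counts", call. = FALSE)
  cats <- c("sequential_alpha", "alpha", "pi", "three_ten", "combined")
  out <- data.frame(residue = profile_a$residue)
  for (cc in cats) out[[cc]] <- profile_a[[cc]] - profile_b[[cc]]
  attr(out, "mean_abs_change") <-
    vapply(cats, function(cc) mean(abs(out[[cc]])), numeric(1))
  attr(out, "labels") <- c(attr(profile_a, "temperature_label"),
                           attr(profile_b, "temperature_label"))
  class(out) <- c("HelixComparison", "data.frame")
  out
}
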