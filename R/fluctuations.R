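## Superposition RMSD series, per-residue RMSF, radius-of-gyration series
## and distributions, and block-averaged statistics.

#' Construct a TimeSeries
#'
#' @param values per-frame scalar values (Angstrom for RMSD/Rg).
#' @param times optional frame times in ns.
#' @param label descriptive label.
#' @return object of class `TimeSeries`.
#' @export
time_series <- function(values, times = NULL, label = "") {
  structure(list(values = as.numeric(values), times = times,
                 label = as.character(label)), class = "TimeSeries")
}

#' @export
print.TimeSeries <- function(x, ...) {
  cat(sprintf("TimeSeries '%s': %d frames, mean %.4g\n",
              x$label, length(x$values), mean(x$values)))
  invisible(x)
}

series_values <- function(series) {
  if (inherits(series, "TimeSeries")) series$values else as.numeric(series)
}

#' Optimal rigid superposition (weighted Kabsch)
#'
#' Least-squares rigid-body alignment of `mobile` onto `reference`,
#' restricted to proper rotations (reflections excluded), with optional
#' non-negative per-atom weights. The closed-form SVD solution is used.
#'
#' @param mobile n x 3 coordinate matrix to move.
#' @param reference n x 3 target coordinate matrix.
#' @param weights non-negative per-atom weights (default uniform).
#' @return list with `rotation` (3 x 3, det +1), `translation` (length 3)
#'   such that `aligned = mobile %*% t(rotation) + translation`, and the
#'   minimized weighted `rmsd` in Angstrom.
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  n <- nrow(mobile)
  if (nrow(reference) != n)
    stop("point counts differ between mobile and reference", call. = FALSE)
  if (n < 3) stop("superposition needs at least 3 points", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0) || sum(weights) == 0)
    stop("weights must be non-negative with positive sum", call. = FALSE)
  w <- weights / sum(weights)
  cm <- colSums(mobile * w)
  cr <- colSums(reference * w)
  mc <- sweep(mobile, 2, cm)
  rc <- sweep(reference, 2, cr)
  sv_m <- svd(mc * sqrt(w))$d
  if (sv_m[2] <= 1e-8 * max(sv_m[1], 1e-12))
    stop("degenerate (collinear) point configuration", call. = FALSE)
  H <- crossprod(mc, w * rc)            # sum_i w_i m_i r_i^T
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  aligned <- mc %*% t(R)
  rmsd <- sqrt(sum(w * rowSums((aligned - rc)^2)))
  list(rotation = R, translation = as.numeric(cr - R %*% cm), rmsd = rmsd)
}

## Apply a kabsch_superpose() transform to an n x 3 matrix.
apply_transform <- function(xyz, fit) {
  sweep(xyz %*% t(fit$rotation), 2, fit$translation, "+")
}

resolve_reference_coords <- function(reference, sel) {
  if (inherits(reference, "StructureModel")) reference$xyz[sel, , drop = FALSE]
  else as.matrix(reference)
}

#' Per-frame RMSD to a reference after optimal superposition
#'
#' @param traj a `TrajectoryEnsemble`.
#' @param reference a `StructureModel` sharing the trajectory topology, or
#'   an explicit coordinate matrix for the selected atoms.
#' @param selection atom selection (see [select_atoms()]); default
#'   C-alpha, the convention under which the similarity thresholds and
#'   Lindemann reference values are calibrated.
#' @return a [time_series()] of RMSD values in Angstrom.
#' @export
rmsd_series <- function(traj, reference = traj$topology, selection = "calpha") {
  sel <- select_atoms(traj$topology, selection)
  ref <- resolve_reference_coords(reference, sel)
  if (nrow(ref) != length(sel))
    stop("reference selection size does not match trajectory selection",
         call. = FALSE)
  cols <- xyz_cols(sel)
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    kabsch_superpose(vec2mat(traj$xyz[f, cols]), ref)$rmsd
  }, numeric(1))
  time_series(vals, traj$times, label = "rmsd")
}

#' Per-residue root-mean-square fluctuation
#'
#' RMSF of each residue's selected atoms about their time-mean positions
#' over a frame window. With `align = TRUE` each frame is first superposed
#' (on the selection) onto the window-mean structure, one iteration.
#'
#' @param traj a `TrajectoryEnsemble`.
#' @param selection atom selection (default C-alpha).
#' @param window integer `c(first, last)` frame range; `NULL` uses all
#'   frames. Pipeline defaults for production trajectories are set in
#'   [run_validation()].
#' @param align superpose frames onto the window mean first (default `TRUE`).
#' @return object of class `FluctuationProfile` with per-residue `rmsf`
#'   (Angstrom), residue labels and the window used.
#' @export
rmsf_per_residue <- function(traj, selection = "calpha", window = NULL,
                             align = TRUE) {
  nf <- n_frames(traj)
  if (is.null(window)) window <- c(1L, nf)
  window <- as.integer(window)
  if (length(window) != 2 || window[1] < 1 || window[2] > nf ||
      window[2] < window[1])
    stop("`window` out of trajectory range", call. = FALSE)
  frames <- seq(window[1], window[2])
  if (length(frames) < 2)
    stop("RMSF needs at least 2 frames", call. = FALSE)
  sel <- select_atoms(traj$topology, selection)
  cols <- xyz_cols(sel)
  X <- traj$xyz[frames, cols, drop = FALSE]
  if (align) {
    ref <- vec2mat(colMeans(X))
    for (i in seq_len(nrow(X))) {
      fit <- kabsch_superpose(vec2mat(X[i, ]), ref)
      X[i, ] <- mat2vec(apply_transform(vec2mat(X[i, ]), fit))
    }
  }
  mean_pos <- colMeans(X)
  msf_coord <- colMeans(sweep(X, 2, mean_pos)^2)        # per coordinate
  msf_atom <- msf_coord[c(TRUE, FALSE, FALSE)] +
    msf_coord[c(FALSE, TRUE, FALSE)] + msf_coord[c(FALSE, FALSE, TRUE)]
  res_of_sel <- traj$topology$residue_index[sel]
  res_present <- sort(unique(res_of_sel))
  rmsf <- sqrt(vapply(res_present,
                      function(r) mean(msf_atom[res_of_sel == r]), numeric(1)))
  structure(
    list(rmsf = unname(rmsf),
         residue_labels = traj$topology$residue_labels[res_present + 1L],
         residue_names = traj$topology$residue_names[res_present + 1L],
         window = window),
    class = "FluctuationProfile")
}

#' @export
print.FluctuationProfile <- function(x, ...) {
  cat(sprintf("FluctuationProfile: %d residues, <RMSF> %.3f A (frames %d-%d)\n",
              length(x$rmsf), mean(x$rmsf), x$window[1], x$window[2]))
  invisible(x)
}

#' @export
as.data.frame.FluctuationProfile <- function(x, ...) {
  data.frame(residue = x$residue_labels, residue_name = x$residue_names,
             rmsf = x$rmsf)
}

#' Per-frame radius of gyration
#'
#' Rg = sqrt( sum_i w_i |r_i - rbar|^2 / sum_i w_i ), with atomic masses as
#' weights when `mass_weighted` (the default) and unit weights otherwise.
#'
#' @param traj a `TrajectoryEnsemble`.
#' @param selection atom selection; default all heavy atoms.
#' @param mass_weighted use atomic masses as weights (default `TRUE`).
#' @return a [time_series()] of Rg values in Angstrom.
#' @export
radius_of_gyration_series <- function(traj, selection = "heavy",
                                      mass_weighted = TRUE) {
  if (n_frames(traj) < 1) stop("empty trajectory", call. = FALSE)
  sel <- select_atoms(traj$topology, selection)
  w <- if (mass_weighted) traj$topology$masses[sel] else rep(1, length(sel))
  w <- w / sum(w)
  X <- traj$xyz[, xyz_cols(sel), drop = FALSE]
  rg2 <- 0
  for (off in 0:2) {
    comp <- X[, seq(1 + off, ncol(X), by = 3), drop = FALSE]
    mu <- as.numeric(comp %*% w)
    rg2 <- rg2 + as.numeric(comp^2 %*% w) - mu^2
  }
  rg2[rg2 < 0] <- 0                     # guard tiny negative round-off
  time_series(sqrt(rg2), traj$times, label = "rg")
}

#' Radius of gyration of a single structure
#'
#' @param model a `StructureModel`.
#' @inheritParams radius_of_gyration_series
#' @return Rg in Angstrom.
#' @export
radius_of_gyration <- function(model, selection = "heavy",
                               mass_weighted = TRUE) {
  traj <- trajectory_ensemble(matrix(mat2vec(model$xyz), nrow = 1), model)
  radius_of_gyration_series(traj, selection, mass_weighted)$values[1]
}

#' Block-averaged mean and standard error of a time series
#'
#' Splits the window into contiguous blocks of `block_length` frames
#' (trailing partial block discarded), reports the mean of block means and
#' the standard error sd(block means)/sqrt(n_blocks). The block length
#' should exceed the correlation time of the series for the error estimate
#' to be meaningful.
#'
#' @param series a `TimeSeries` or numeric vector.
#' @param block_length block size in frames.
#' @param window integer `c(first, last)` frame range; `NULL` uses all.
#' @return object of class `BlockStats` with `mean`, `standard_error`,
#'   `block_length` and `n_blocks`.
#' @export
block_average <- function(series, block_length, window = NULL) {
  v <- series_values(series)
  if (is.null(window)) window <- c(1L, length(v))
  window <- as.integer(window)
  if (window[1] < 1 || window[2] > length(v) || window[2] < window[1])
    stop("`window` out of series range", call. = FALSE)
  v <- v[seq(window[1], window[2])]
  block_length <- as.integer(block_length)
  if (block_length < 1) stop("`block_length` must be positive", call. = FALSE)
  n_blocks <- length(v) %/% block_length
  if (n_blocks < 2)
    stop(sprintf("insufficient data: %d frames give %d complete block(s) of %d; need >= 2",
                 length(v), n_blocks, block_length), call. = FALSE)
  bm <- colMeans(matrix(v[seq_len(n_blocks * block_length)],
                        nrow = block_length))
  structure(list(mean = mean(bm),
                 standard_error = stats::sd(bm) / sqrt(n_blocks),
                 block_length = block_length, n_blocks = n_blocks),
            class = "BlockStats")
}

#' @export
print.BlockStats <- function(x, ...) {
  cat(sprintf("BlockStats: mean %.4g +/- %.2g (%d blocks of %d frames)\n",
              x$mean, x$standard_error, x$n_blocks, x$block_length))
  invisible(x)
}

#' Histogram probability-density estimate
#'
#' Fixed-width histogram normalized so that sum(density) * bin_width = 1.
#'
#' @param series a `TimeSeries` or numeric vector.
#' @param bin_width bin width in the series' units (Angstrom for Rg).
#' @return data frame with `bin_mid` and `density`; bin width stored as an
#'   attribute.
#' @export
distribution_estimate <- function(series, bin_width) {
  v <- series_values(series)
  if (length(v) < 2) stop("need at least 2 values", call. = FALSE)
  if (!is.numeric(bin_width) || bin_width <= 0)
    stop("`bin_width` must be positive", call. = FALSE)
  lo <- floor(min(v) / bin_width) * bin_width
  breaks <- seq(lo, max(v) + bin_width, by = bin_width)
  h <- graphics::hist(v, breaks = breaks, plot = FALSE)
  out <- data.frame(bin_mid = h$mids, density = h$counts / (length(v) * bin_width))
  attr(out, "bin_width") <- bin_width
  out
}
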