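#' Construct a StructureModel
#'
#' Internal data model for a single protein chain: per-atom names, 0-based
#' residue indices, coordinates in Angstrom and masses in Dalton, plus
#' per-residue names and the original PDB residue numbers kept as labels.
#'
#' @param atom_names character vector of PDB atom names (e.g. "CA").
#' @param residue_index integer vector, per-atom residue index, 0-based and
#'   contiguous (0, 0, ..., 1, 1, ...).
#' @param xyz numeric matrix with one row per atom and columns x, y, z (Angstrom).
#' @param residue_names character vector of 3-letter residue codes, one per
#'   residue.
#' @param residue_labels integer vector of original residue numbers, one per
#'   residue (defaults to 1..n).
#' @param masses per-atom masses in Da; inferred from `element` when `NULL`.
#' @param element per-atom element symbols; inferred from names when `NULL`.
#' @param chain_id single chain identifier string.
#' @return An object of class `StructureModel`.
#' @export
structure_model <- function(atom_names, residue_index, xyz, residue_names,
                            residue_labels = NULL, masses = NULL,
                            element = NULL, chain_id = "A") {
  n_atom <- length(atom_names)
  xyz <- as.matrix(xyz)
  if (nrow(xyz) != n_atom || ncol(xyz) != 3)
    stop("`xyz` must be an n_atom x 3 matrix", call. = FALSE)
  if (length(residue_index) != n_atom)
    stop("`residue_index` must have one entry per atom", call. = FALSE)
  if (any(!is.finite(xyz)))
    stop("coordinates must be finite", call. = FALSE)
  residue_index <- as.integer(residue_index)
  u <- sort(unique(residue_index))
  if (!identical(u, seq_along(u) - 1L))
    stop("residue indices must be 0-based and contiguous", call. = FALSE)
  n_res <- length(u)
  if (length(residue_names) != n_res)
    stop("`residue_names` must have one entry per residue", call. = FALSE)
  if (is.null(residue_labels)) residue_labels <- seq_len(n_res)
  if (length(residue_labels) != n_res)
    stop("`residue_labels` must have one entry per residue", call. = FALSE)
  if (is.null(element)) element <- infer_element(atom_names)
  if (is.null(masses)) masses <- mass_from_element(element)
  structure(
    list(atom_names = as.character(atom_names),
         residue_index = residue_index,
         xyz = unname(xyz),
         residue_names = as.character(residue_names),
         residue_labels = as.integer(residue_labels),
         masses = as.numeric(masses),
         element = as.character(element),
         chain_id = as.character(chain_id)),
    class = "StructureModel")
}

#' @export
print.StructureModel <- function(x, ...) {
  cat(sprintf("StructureModel: %d atoms, %d residues, chain %s\n",
              n_atoms(x), n_residues(x), x$chain_id))
  invisible(x)
}

#' Number of atoms / residues in a model
#' @param model a `StructureModel`.
#' @return integer count.
#' @export
n_atoms <- function(model) length(model$atom_names)

#' @rdname n_atoms
#' @export
n_residues <- function(model) length(model$residue_names)

#' Construct a TrajectoryEnsemble
#'
#' An ordered set of coordinate frames sharing one topology. Frames are
#' stored in the flat row-per-frame layout (x1, y1, z1, x2, ...) used by
#' trajectory files.
#'
#' @param xyz numeric matrix, `n_frames` x `3 * n_atoms(topology)` (Angstrom).
#' @param topology a `StructureModel`.
#' @param times optional numeric vector of frame times in ns, strictly
#'   increasing.
#' @return An object of class `TrajectoryEnsemble`.
#' @export
trajectory_ensemble <- function(xyz, topology, times = NULL) {
  stopifnot(inherits(topology, "StructureModel"))
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3 * n_atoms(topology))
    stop(sprintf("frame width (%d coords) does not match topology (%d atoms)",
                 ncol(xyz), n_atoms(topology)), call. = FALSE)
  if (!is.null(times)) {
    if (length(times) != nrow(xyz))
      stop("`times` must have one entry per frame", call. = FALSE)
    if (any(diff(times) <= 0))
      stop("`times` must be strictly increasing", call. = FALSE)
  }
  structure(list(xyz = unname(xyz), times = times, topology = topology),
            class = "TrajectoryEnsemble")
}

#' @export
print.TrajectoryEnsemble <- function(x, ...) {
  cat(sprintf("TrajectoryEnsemble: %d frames x %d atoms\n",
              n_frames(x), n_atoms(x$topology)))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `TrajectoryEnsemble`.
#' @return integer count.
#' @export
n_frames <- function(traj) nrow(traj$xyz)

#' Coordinates of one frame
#' @param traj a `TrajectoryEnsemble`.
#' @param i frame index (1-based).
#' @return an `n_atoms` x 3 coordinate matrix.
#' @export
frame_coords <- function(traj, i) vec2mat(traj$xyz[i, ])

#' Select atoms from a StructureModel
#'
#' Named selections follow the conventions of trajectory-analysis practice:
#' `"calpha"` (CA atoms), `"backbone"` (N, CA, C, O), `"heavy"` (all
#' non-hydrogen atoms), `"all"`. An integer vector is taken as explicit
#' 1-based atom indices.
#'
#' @param model a `StructureModel`.
#' @param selection selection keyword or integer atom indices.
#' @return integer vector of atom indices; errors if the selection is empty.
#' @export
select_atoms <- function(model, selection = "calpha") {
  if (is.numeric(selection)) {
    idx <- as.integer(selection)
    if (any(idx < 1L | idx > n_atoms(model)))
      stop("atom indices out of range", call. = FALSE)
  } else {
    selection <- match.arg(selection, c("calpha", "backbone", "heavy", "all"))
    idx <- switch(selection,
      calpha   = which(model$atom_names == "CA"),
      backbone = which(model$atom_names %in% c("N", "CA", "C", "O")),
      heavy    = which(model$element != "H"),
      all      = seq_len(n_atoms(model)))
  }
  if (length(idx) == 0)
    stop("empty atom selection", call. = FALSE)
  idx
}
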