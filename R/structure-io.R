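## Reading reference structures and trajectories into the internal data
## model, and writing tabular results. File parsing stands on bio3d; the
## DCD writer is local because the installed stack reads but does not write
## that format.

.aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL", "MSE", "HSD", "HSE", "HSP", "HID", "HIE", "HIP")
.caps <- c("ACE", "NME", "NMA")

#' Read a reference structure from a PDB file
#'
#' Reads the first model of a PDB file, keeps protein residues of one chain
#' (waters, ions and other heteroatoms are excluded; Ace/Nme capping groups
#' are retained so that terminal backbone dihedrals stay defined), and fills
#' atomic masses from element inference.
#'
#' @param path path to a PDB file.
#' @param chain chain identifier; `NULL` takes the first chain containing
#'   protein atoms.
#' @param keep_caps keep Ace/Nme capping residues (default `TRUE`).
#' @return A [structure_model()] for the selected chain.
#' @export
read_structure <- function(path, chain = NULL, keep_caps = TRUE) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)),
    error = function(e)
      stop(sprintf("failed to parse PDB '%s': %s", path, conditionMessage(e)),
           call. = FALSE))
  at <- pdb$atom
  keep_res <- .aa3
  if (keep_caps) keep_res <- c(keep_res, .caps)
  ok <- at$resid %in% keep_res & (is.na(at$alt) | at$alt %in% c("", "A"))
  if (!any(ok))
    stop(sprintf("no protein atoms found in '%s'", path), call. = FALSE)
  at <- at[ok, , drop = FALSE]
  if (is.null(chain)) chain <- at$chain[1]
  at <- at[at$chain %in% chain, , drop = FALSE]
  if (nrow(at) == 0)
    stop(sprintf("no protein atoms in chain '%s' of '%s'", chain, path),
         call. = FALSE)
  ## residues in file order; insertion codes folded into the grouping key
  key <- paste(at$resno, ifelse(is.na(at$insert), "", at$insert))
  res_index <- match(key, unique(key)) - 1L
  first <- !duplicated(res_index)
  structure_model(
    atom_names = trimws(at$elety),
    residue_index = res_index,
    xyz = cbind(at$x, at$y, at$z),
    residue_names = at$resid[first],
    residue_labels = at$resno[first],
    element = infer_element(trimws(at$elety), at$elesy),
    chain_id = as.character(chain))
}

#' Read a coordinate trajectory
#'
#' Supported formats: binary DCD (via the installed trajectory-reading
#' layer) and multi-model PDB (plain text; every MODEL must contain exactly
#' the topology's atoms in order). Coordinates are returned in Angstrom, in
#' file order.
#'
#' @param path trajectory file path.
#' @param topology the matching [structure_model()].
#' @param format `"auto"` (by extension), `"dcd"` or `"pdb"`.
#' @return A [trajectory_ensemble()].
#' @export
read_trajectory <- function(path, topology, format = c("auto", "dcd", "pdb")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)), dcd = "dcd", pdb = "pdb",
                     stop(sprintf("cannot infer trajectory format of '%s'", path),
                          call. = FALSE))
  }
  xyz <- if (format == "dcd") {
    tryCatch(
      unclass(bio3d::read.dcd(path, verbose = FALSE)),
      error = function(e)
        stop(sprintf("failed to read DCD '%s' (file truncated or corrupt): %s",
                     path, conditionMessage(e)), call. = FALSE))
  } else {
    m <- tryCatch(
      suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
      error = function(e)
        stop(sprintf("failed to parse PDB trajectory '%s': %s", path,
                     conditionMessage(e)), call. = FALSE))
    m$xyz
  }
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3 * n_atoms(topology))
    stop(sprintf(
      "topology mismatch: trajectory has %d atoms, topology has %d",
      ncol(xyz) %/% 3, n_atoms(topology)), call. = FALSE)
  trajectory_ensemble(xyz, topology)
}

## -- writers ----------------------------------------------------------------

pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          element) {
  namef <- if (nchar(name) >= 4) substr(name, 1, 4)
           else formatC(paste0(" ", name), width = -4)
  sprintf("ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial %% 100000, namef, resname, chain, resno %% 10000, x, y, z,
          1.0, 0.0, element)
}

model_atom_table <- function(model) {
  ri <- model$residue_index + 1L
  data.frame(name = model$atom_names,
             resname = model$residue_names[ri],
             resno = model$residue_labels[ri],
             element = model$element,
             stringsAsFactors = FALSE)
}

#' Write a StructureModel to a PDB file
#'
#' @param model a `StructureModel`.
#' @param path output path.
#' @param remarks optional character vector written as REMARK lines.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path, remarks = NULL) {
  tab <- model_atom_table(model)
  lines <- mapply(pdb_atom_line, seq_len(n_atoms(model)), tab$name,
                  tab$resname, model$chain_id, tab$resno,
                  model$xyz[, 1], model$xyz[, 2], model$xyz[, 3], tab$element)
  header <- if (is.null(remarks)) character() else paste("REMARK    ", remarks)
  writeLines(c(header, lines, "TER", "END"), path)
  invisible(path)
}

#' Write a trajectory to disk
#'
#' Multi-model PDB (text) or CHARMM-style DCD (binary).
#'
#' @param traj a `TrajectoryEnsemble`.
#' @param path output path; format inferred from the `.pdb` / `.dcd`
#'   extension unless `format` is given.
#' @param format `"auto"`, `"pdb"` or `"dcd"`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, format = c("auto", "pdb", "dcd")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)), dcd = "dcd", pdb = "pdb",
                     stop("cannot infer output trajectory format", call. = FALSE))
  }
  if (format == "dcd") return(write_dcd(traj, path))
  model <- traj$topology
  tab <- model_atom_table(model)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    xyz <- frame_coords(traj, f)
    lines <- mapply(pdb_atom_line, seq_len(n_atoms(model)), tab$name,
                    tab$resname, model$chain_id, tab$resno,
                    xyz[, 1], xyz[, 2], xyz[, 3], tab$element)
    writeLines(c(sprintf("MODEL     %4d", f), lines, "ENDMDL"), con)
  }
  writeLines("END", con)
  invisible(path)
}

## Minimal CHARMM-format DCD writer (Fortran sequential records:
## int32 length, payload, int32 length). Coordinates stored as float32.
write_dcd <- function(traj, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  rec <- function(write_payload, nbytes) {
    writeBin(as.integer(nbytes), con, size = 4, endian = "little")
    write_payload()
    writeBin(as.integer(nbytes), con, size = 4, endian = "little")
  }
  nf <- n_frames(traj)
  na <- n_atoms(traj$topology)
  rec(function() {
    writeBin(charToRaw("CORD"), con)
    writeBin(as.integer(c(nf, 1L, 1L, nf, 0L, 0L, 0L, 0L, 0L)), con,
             size = 4, endian = "little")
    writeBin(1.0, con, size = 4, endian = "little")        # delta (float32)
    writeBin(as.integer(c(rep(0L, 9), 24L)), con, size = 4, endian = "little")
  }, 84)
  title <- formatC("Synthetic trajectory written by ffentropy", width = -80)
  rec(function() {
    writeBin(1L, con, size = 4, endian = "little")
    writeBin(charToRaw(title), con)
  }, 84)
  rec(function() writeBin(as.integer(na), con, size = 4, endian = "little"), 4)
  xi <- seq(1, 3 * na, by = 3)
  for (f in seq_len(nf)) {
    row <- traj$xyz[f, ]
    for (off in 0:2) {
      rec(function() writeBin(as.numeric(row[xi + off]), con, size = 4,
                              endian = "little"), 4 * na)
    }
  }
  invisible(path)
}

#' Write labelled records to CSV or JSON
#'
#' @param rows a data frame, or an object with an `as.data.frame` method
#'   (e.g. a `FluctuationProfile` or `HelixProfile`).
#' @param path output path.
#' @param format `"csv"` or `"json"` (default from the file extension).
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)), json = "json", "csv")
  }
  df <- as.data.frame(rows)
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    jsonlite::write_json(df, path, dataframe = "rows", digits = NA, na = "null")
  }
  invisible(path)
}
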