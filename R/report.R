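## Orchestration: run the full validation pipeline (fluctuation metrics ->
## entropy indicators -> helicity) from one declarative config and emit a
## consolidated report plus per-module tables.

#' Build a validation configuration
#'
#' Central parameter record for [run_validation()]. Paths or in-memory
#' objects are both accepted for the topology and trajectories. Window
#' defaults follow the production-analysis protocol: scalar averages
#' (RMSD, Rg) discard the first 20% of frames and RMSF profiles use the
#' final 10%, both expressed as fractions so they apply to any trajectory
#' length; block statistics default to 16 blocks over the scalar window
#' (about 50 ns blocks over the last 800 ns of a 1 microsecond run saved
#' every 10 ps).
#'
#' @param topology path to a PDB file, or a `StructureModel`.
#' @param trajectory path to a DCD / multi-model PDB file, or a
#'   `TrajectoryEnsemble`.
#' @param selection atom selection for RMSD/RMSF (default `"calpha"`).
#' @param a Lindemann nonbonded distance parameter, Angstrom.
#' @param core_residues residue labels of the structural core (optional;
#'   enables the core/surface decomposition).
#' @param scalar_window_frac `c(start, end)` fractional window for
#'   RMSD/Rg block averages.
#' @param rmsf_window_frac fractional window for the RMSF profile.
#' @param rmsf_align superpose frames on the window mean before the RMSF
#'   (default `TRUE`; disable for ensembles that are already aligned, where
#'   the fit would otherwise absorb part of the fluctuation).
#' @param n_blocks number of blocks for block averaging.
#' @param rg_prefactor,rg_exponent polymer scaling-law parameters.
#' @param mass_weighted mass-weight the radius of gyration.
#' @param helix_trajectories optional named list of trajectories (or
#'   paths) for residue-resolved helicity, names used as temperature
#'   labels (e.g. `list("300K" = ..., "360K" = ...)`).
#' @param output_dir directory for CSV/JSON outputs and the run log
#'   (`NULL` = return the report only).
#' @param seed seed recorded for any stochastic step.
#' @return list of class `ValidationConfig`.
#' @export
validation_config <- function(topology, trajectory = NULL,
                              selection = "calpha", a = 4.375,
                              core_residues = NULL,
                              scalar_window_frac = c(0.2, 1),
                              rmsf_window_frac = c(0.9, 1),
                              rmsf_align = TRUE,
                              n_blocks = 16,
                              rg_prefactor = 2.2, rg_exponent = 0.38,
                              mass_weighted = TRUE,
                              helix_trajectories = NULL,
                              output_dir = NULL, seed = NULL) {
  stopifnot(length(scalar_window_frac) == 2, length(rmsf_window_frac) == 2,
            n_blocks >= 2)
  structure(as.list(environment()), class = "ValidationConfig")
}

frac_window <- function(n, frac) {
  w <- c(max(1L, floor(frac[1] * n) + 1L), floor(frac[2] * n))
  w[1] <- min(w[1], n); w[2] <- max(w[1], w[2])
  w
}

resolve_topology <- function(x) {
  if (inherits(x, "StructureModel")) x else read_structure(x)
}

resolve_trajectory <- function(x, topology) {
  if (inherits(x, "TrajectoryEnsemble")) x else read_trajectory(x, topology)
}

#' Run the validation pipeline
#'
#' Executes, over the configured trajectory: block-averaged RMSD and Rg
#' (with standard errors from block averaging, not standard deviations),
#' the final-window RMSF profile, Lindemann values (core/surface
#' decomposition when a core set is supplied), chain-length similarity
#' thresholds with a verdict on the mean RMSD, polymer-scaling Rg
#' references, and — when helix trajectories are configured —
#' residue-resolved helicity profiles per temperature with a two-condition
#' comparison. Every effective parameter is echoed to the run log. Any
#' stage failure aborts with the stage name; partial outputs are removed.
#'
#' @param config a [validation_config()].
#' @return list of class `ValidationReport`.
#' @export
run_validation <- function(config) {
  stopifnot(inherits(config, "ValidationConfig"))
  out_dir <- config$output_dir
  written <- character()
  log_lines <- character()
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))
  emit <- function(obj, name) {
    if (is.null(out_dir)) return(invisible())
    path <- file.path(out_dir, name)
    write_table(obj, path)
    written <<- c(written, path)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop(sprintf("validation stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  topology <- stage("topology", resolve_topology(config$topology))
  nres <- n_residues(topology) -
    sum(topology$residue_names %in% .caps)   # caps are not chain residues
  note("selection=%s a=%.4g n_residues=%d seed=%s", config$selection,
       config$a, nres, format(config$seed %||% "none"))

  report <- list(n_residues = nres)

  if (!is.null(config$trajectory)) {
    traj <- stage("trajectory", resolve_trajectory(config$trajectory, topology))
    nf <- n_frames(traj)
    sw <- frac_window(nf, config$scalar_window_frac)
    fw <- frac_window(nf, config$rmsf_window_frac)
    block_len <- max(1L, (sw[2] - sw[1] + 1L) %/% as.integer(config$n_blocks))
    note("frames=%d scalar_window=%d-%d rmsf_window=%d-%d block_frames=%d",
         nf, sw[1], sw[2], fw[1], fw[2], block_len)

    rmsd <- stage("rmsd", rmsd_series(traj, topology, config$selection))
    rmsd_stats <- stage("rmsd", block_average(rmsd, block_len, sw))
    rg <- stage("rg", radius_of_gyration_series(
      traj, mass_weighted = config$mass_weighted))
    rg_stats <- stage("rg", block_average(rg, block_len, sw))
    profile <- stage("rmsf", rmsf_per_residue(traj, config$selection, fw,
                                              align = config$rmsf_align))
    emit(data.frame(frame = seq_len(nf), rmsd = rmsd$values, rg = rg$values),
         "series.csv")
    emit(profile, "rmsf.csv")

    lind <- stage("lindemann", {
      if (is.null(config$core_residues))
        list(delta_total = lindemann_value(profile, config$a),
             delta_core = NA_real_, delta_surf = NA_real_)
      else lindemann_partition(profile, config$core_residues, config$a)
    })
    thr <- stage("thresholds", maiorov_crippen_thresholds(nres))
    verdict <- stage("verdict", similarity_verdict(rmsd_stats$mean, thr))
    rg_ref <- stage("rg_reference", polymer_rg_reference(
      nres, config$rg_prefactor, config$rg_exponent,
      rg_pdb = radius_of_gyration(topology,
                                  mass_weighted = config$mass_weighted)))
    note("rmsd=%.4g+/-%.2g rg=%.4g+/-%.2g dL=%.4g verdict=%s",
         rmsd_stats$mean, rmsd_stats$standard_error, rg_stats$mean,
         rg_stats$standard_error, lind$delta_total, verdict)
    report <- c(report, list(
      rmsd = rmsd_stats, rg = rg_stats, rmsf = profile,
      lindemann = lind, thresholds = thr, verdict = verdict,
      rg_reference = rg_ref))
  }

  if (!is.null(config$helix_trajectories)) {
    profiles <- stage("helicity", {
      lapply(seq_along(config$helix_trajectories), function(i) {
        tr <- resolve_trajectory(config$helix_trajectories[[i]], topology)
        dih <- backbone_dihedrals(tr)
        helical_fraction_profile(
          classify_pairwise_helix(dih),
          classify_sequential_alpha(dih),
          temperature_label =
            names(config$helix_trajectories)[i] %||% as.character(i),
          residue_labels = dih$residue_labels)
      })
    })
    names(profiles) <- vapply(profiles, attr, "", "temperature_label")
    for (p in profiles) {
      emit(p, sprintf("helicity_%s.csv", attr(p, "temperature_label")))
    }
    report$helicity <- profiles
    if (length(profiles) == 2) {
      report$helicity_change <- stage(
        "helicity", compare_temperatures(profiles[[1]], profiles[[2]]))
      note("helicity mean |change| (combined) = %.3g",
           attr(report$helicity_change, "mean_abs_change")[["combined"]])
    }
  }

  report$provenance <- list(
    package_version = as.character(utils::packageVersion("ffentropy")),
    parameters = config[setdiff(names(config), c("topology", "trajectory",
                                                 "helix_trajectories"))])
  class(report) <- "ValidationReport"
  if (!is.null(out_dir)) {
    json <- file.path(out_dir, "report.json")
    jsonlite::write_json(report_to_list(report), json, auto_unbox = TRUE,
                         digits = NA, na = "null", force = TRUE)
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }
  report
}

report_to_list <- function(report) {
  scrub <- function(x) {
    if (inherits(x, "data.frame")) return(x)
    if (is.list(x)) return(lapply(unclass(x), scrub))
    x
  }
  scrub(report)
}

#' @export
print.ValidationReport <- function(x, ...) {
  cat("Validation report\n")
  cat(sprintf("  residues: %d\n", x$n_residues))
  if (!is.null(x$rmsd)) {
    cat(sprintf("  <RMSD> %.3f +/- %.3f A -> %s (D0,sim %.2f, D0,dis %.2f)\n",
                x$rmsd$mean, x$rmsd$standard_error, x$verdict,
                x$thresholds$d0_sim, x$thresholds$d0_dis))
    cat(sprintf("  <Rg>   %.3f +/- %.3f A (structure %.2f, scaling law %.2f)\n",
                x$rg$mean, x$rg$standard_error, x$rg_reference$rg_pdb,
                x$rg_reference$rg_scaling))
    cat(sprintf("  Lindemann: total %.3f core %.3f surface %.3f\n",
                x$lindemann$delta_total, x$lindemann$delta_core,
                x$lindemann$delta_surf))
  }
  if (!is.null(x$helicity))
    cat(sprintf("  helicity profiles: %s\n",
                paste(names(x$helicity), collapse = ", ")))
  invisible(x)
}
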