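Package: ffentropy
Title: Structural Fluctuation and Configurational-Entropy Metrics for
    Force-Field Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for validating protein force fields against
    structural-fluctuation criteria. Computes superposition RMSD series,
    per-residue RMSF profiles, radius-of-gyration series and distributions
    with block-averaged statistics from molecular dynamics trajectories;
    converts fluctuation profiles into configurational-entropy indicators
    (Lindemann values with core/surface decomposition, chain-length-dependent
    structural similarity and dissimilarity thresholds, polymer-scaling
    radius-of-gyration references); and classifies residue-resolved helicity
    from backbone dihedrals under a sequential three-residue alpha criterion
    and a pairwise psi(i)+phi(i+1) criterion distinguishing alpha, pi and
    3(10) helices. A synthetic-ensemble generator (ideal helices, Gaussian
    fluctuation ensembles, rigid-body ensembles, two-state helix/coil
    dihedral series) provides ground truth so every stage is testable
    without running molecular dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
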