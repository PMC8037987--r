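# ffentropy

Structural-fluctuation and configurational-entropy metrics for validating
protein force fields against molecular-dynamics ensembles.

## The problem

A force field that keeps a folded protein rigidly pinned to its crystal
structure looks "stable" by eye, but a folded state in water is not a
solid: experimentally, room-temperature globular proteins fluctuate at a
characteristic, nearly universal amplitude, and force fields that suppress
those fluctuations tend to overestimate melting temperatures and to
describe intrinsically disordered proteins (IDPs) as overly collapsed and
rigid. `ffentropy` turns that idea into concrete, desk-computable
validation criteria for people who run MD simulations:

* **Fluctuation metrics** — superposition RMSD series (weighted Kabsch),
  per-residue RMSF over configurable windows, mass-weighted radius of
  gyration Rg, histogram density estimates, and block-averaged means with
  standard errors.
* **Entropy indicators** — the Lindemann criterion adapted to proteins,
  `ΔL = ⟨RMSF⟩ / a` with `a = 4.375 Å` an average nonbonded distance
  (experimental room-temperature reference band ΔL ≈ 0.15–0.16, with
  solid-like cores ~0.05–0.1 and fluid surfaces ~0.15–0.2); empirical
  chain-length-dependent RMSD thresholds `D0,sim(n)` / `D0,dis(n)`
  separating "similar", "intermediate" and "dissimilar" ensembles; and
  polymer scaling-law Rg references `Rg = R0 · n^ν`.
* **Residue-resolved helicity** — backbone φ/ψ dihedrals classified two
  ways: the *sequential* definition (three consecutive residues with
  φ ∈ [−160°, −30°] and ψ ∈ [−67°, −7°]) and the *pairwise* definition on
  `s = ψ(i) + φ(i+1)`, with windows −125° ± 10° (π-helix), −105° ± 10°
  (α-helix) and −75° ± 10° (3₁₀-helix), reported as per-residue
  percentages so that N- versus C-terminal helicity differences and
  temperature-induced melting are visible.
* **Synthetic ensembles with exact ground truth** — ideal α/π/3₁₀ helices
  built by internal-coordinate chain building, Gaussian-fluctuation and
  rigid-body ensembles, and two-state helix/coil dihedral series with
  prescribed per-residue helicity, so every stage of the pipeline is
  testable without running MD.

Input formats: PDB for reference structures, DCD or multi-model PDB for
trajectories; outputs are plain CSV/JSON.

## Worked example

Validate a synthetic ensemble whose ground truth is known: Gaussian
fluctuations of amplitude σ = 0.4 Å per coordinate around a 25-residue
ideal α-helix (so the expected RMSF is σ√3 ≈ 0.693 Å and the expected
Lindemann value is 0.693/4.375 ≈ 0.158).

```r
library(ffentropy)

ref    <- build_ideal_helix(25, "alpha")
traj   <- gaussian_ensemble(ref, per_atom_sigma = 0.4, n_frames = 5000, seed = 7)
cfg    <- validation_config(ref, traj, core_residues = 6:18, rmsf_align = FALSE)
report <- run_validation(cfg)
report
#> Validation report
#>   residues: 25
#>   <RMSD> 0.661 +/- 0.001 A -> similar (D0,sim 0.83, D0,dis 2.77)
#>   <Rg>   11.469 +/- 0.001 A (structure 11.45, scaling law 7.48)
#>   Lindemann: total 0.157 core 0.158 surface 0.157
```

The report reads: the ensemble stays within the similarity threshold for a
25-residue chain (mean RMSD 0.661 Å ≤ D0,sim = 0.83 Å, so the fold is
preserved); its mean Rg matches the reference structure (11.45 Å — the
scaling-law value 7.48 Å is the compact-globule reference, and an ideal
helix is elongated, not globular); and the recovered Lindemann value 0.157
agrees with the prescribed 0.158 and sits inside the experimental folded-
state band. Errors are block-averaging standard errors over the last 80%
of frames.

Threshold calibration and verdicts at the 56-residue TSR4 chain length:

```r
thr <- maiorov_crippen_thresholds(56)
thr
#> Similarity thresholds (n = 56): D0,sim 1.34 A, D0,dis 4.49 A
similarity_verdict(5.5, thr)    # a strongly diverged ensemble
#> [1] "dissimilar"
```

Averaging reported per-protein Lindemann values the way summary tables do
(half-away-from-zero at two decimals):

```r
aggregate_over_systems(c(0.13, 0.16, 0.18, 0.22, 0.13, 0.16, 0.17))
#> $mean
#> [1] 0.1642857
#> $rounded
#> [1] 0.16
```

A thin command-line wrapper for shell pipelines lives at
`inst/cli/ffentropy.R` (subcommands `run`, `rmsd`, `rmsf`, `rg`,
`lindemann`, `verdict`, `helicity`, `synth`).

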