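---
title: "Fluctuation and configurational-entropy metrics for force-field validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fluctuation and configurational-entropy metrics for force-field validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ffentropy)
```

## Motivation and model

A folded globular protein in water is not a static object: its
room-temperature ensemble carries a characteristic fluctuation amplitude,
and that amplitude is itself a validation target for a force field.
`ffentropy` packages three complementary ways of asking "does a simulated
ensemble fluctuate the right amount?":

1. **Fluctuation scale.** RMSD of each frame to the reference after
   optimal superposition, per-residue RMSF about the window-mean
   structure, and the radius of gyration. RMSD/RMSF use the C-alpha atoms
   by default; Rg uses all heavy atoms, mass weighted.

2. **Lindemann criterion.** The melting criterion for crystals carries
   over to proteins by replacing the lattice constant with an average
   nonbonded distance `a`:

   `delta_L = <RMSF> / a`,   `a = 4.375 Angstrom` by default.

   Reported experimental reference points for folded proteins in water
   near 300 K place `delta_L` around 0.15-0.16, with solid-like interior
   cores near 0.05-0.1 and fluid surfaces near 0.15-0.2; values well
   below the band indicate an over-rigid model that will tend to
   overestimate thermal stability. `lindemann_partition()` evaluates the
   total, a user-supplied structural core, and its complement. Core
   membership is an input: identifying beta-sheet cores automatically is
   deliberately out of scope, because published core definitions are
   structural judgements that do not reduce to a universal rule.

3. **Similarity thresholds and Rg references.** Chain-length-dependent
   RMSD thresholds separate ensembles that merely reconfigure loops
   (`rmsd <= D0,sim`, "similar") from ensembles as far from the reference
   as its mirror image (`rmsd >= D0,dis`, "dissimilar"); both boundaries
   are inclusive. A polymer scaling law `Rg = R0 * n^nu` provides a
   compactness reference alongside the reference-structure Rg.

Residue-resolved helicity supplements the global metrics because helical
content — and its temperature dependence — is where over-stabilized force
fields fail visibly on peptides. Two definitions are implemented from
backbone dihedrals:

* **Sequential:** a residue is helical in a frame iff it sits in a run of
  at least three consecutive residues with `phi` in `[-160, -30]` and
  `psi` in `[-67, -7]` degrees.
* **Pairwise:** for each pair `(i, i+1)`, the sum `s = psi(i) + phi(i+1)`
  is tested against `-125 +/- 10` (pi), `-105 +/- 10` (alpha) and
  `-75 +/- 10` (3-10) degrees. The label is attributed to residue `i`,
  and the pairs involving the first and last defined residues are
  excluded. The per-residue `combined` fraction counts frames carrying
  any of the three labels; the sequential fraction is reported as a
  separate curve, never merged into `combined`.

Profiles are reported residue by residue (percent of frames, 0-100)
rather than as a single chain-average percentage, because terminal bias
is precisely the signal of interest in disorder-to-order transitions.

## Tunable parameters

| parameter | default | units | notes |
|---|---|---|---|
| `a` (Lindemann) | 4.375 | Angstrom | average nonbonded distance; configurable because published adaptations use 4-4.75 |
| RMSD/RMSF selection | `"calpha"` | — | the convention under which the threshold and Lindemann reference values are quoted; `"backbone"`/`"heavy"` selectable |
| Rg weighting | masses, heavy atoms | — | unit weights available |
| scalar window | frames in (0.2, 1.0] | fraction | equilibration discard for RMSD/Rg averages |
| RMSF window | frames in (0.9, 1.0] | fraction | short final window, matching production practice of profiling late-trajectory fluctuations |
| blocks | 16 | — | block averaging over the scalar window; trailing partial block discarded, never padded |
| threshold exponent | 0.6 | — | chain-length scaling of both thresholds |
| Rg scaling law | 2.2 · n^0.38 | Angstrom | standard folded-globule empirical fit; poor-solvent exponent 1/3 selectable |
| `rmsf_align` | `TRUE` | — | disable for ensembles generated about a fixed reference, where the closed form `sigma*sqrt(3)` applies exactly |

Window fractions rather than absolute times keep the defaults meaningful
for any trajectory length (for a 1 microsecond run saved every 10 ps they
correspond to averaging over the last 800 ns in ~50 ns blocks and
profiling RMSF over the last 100 ns).

## Threshold calibration

The similarity/dissimilarity thresholds are implemented as power laws
`c * n^0.6`, with prefactors fixed by anchoring both curves at a
56-residue chain — the TSR4 domain length — to 1.34 Angstrom
(similarity) and 4.49 Angstrom (dissimilarity). The anchored form was
chosen over re-deriving prefactors from the original structure-comparison
fits so that the two printed anchor values are reproduced exactly at the
anchor length; the exponent 0.6 carries the chain-length dependence. The
bundled file `inst/extdata/tsr4_backbone_synthetic.pdb` supplies that
chain length as a *synthetic* poly-alanine stand-in — it carries the
residue count, not the real TSR4 coordinates, and is labelled accordingly
in its header. Consequently the calibration test is a consistency check
of the calibration, not an independent prediction of those two numbers.
Below 20 residues the fits are extrapolations and the result carries a
warning attribute.

## The synthetic generators

The generators produce exactly the statistical structure the analyses
assume, and no more:

* `gaussian_ensemble()` — isotropic, frame-independent Gaussian
  displacements about a rigid reference. Expected per-atom RMSF is
  `sigma * sqrt(3)`, making amplitude recovery a closed-form test.
* `rigid_body_ensemble()` — uniformly random proper rotations (quaternion
  method) plus bounded translations; all internal coordinates preserved.
* `build_ideal_helix()` / `build_backbone()` — internal-coordinate chain
  building (bond lengths N-CA 1.458, CA-C 1.525, C-N 1.329 Angstrom;
  angles N-CA-C 111.2, CA-C-N 116.6, C-N-CA 121.7 degrees; omega = 180)
  from canonical or arbitrary phi/psi; `dihedral_ensemble()` rebuilds a
  coordinate trajectory frame by frame from any dihedral series, so
  dihedral-level generators can exercise the full coordinate pipeline.
* `two_state_dihedral_series()` — per frame, each dihedral pair
  `(psi(i), phi(i+1))` is helical with probability `p[i]` (canonical
  dihedrals plus Gaussian jitter) or coil (uniform over
  `phi in [-180, -130]`, `psi in [120, 170]` degrees).

Two design choices in the two-state generator deserve explanation. First,
the helical state is attached to the *pair* `(psi(i), phi(i+1))` rather
than to both angles of one residue: the pairwise classifier reads exactly
that pair, so this convention makes the prescribed `p[i]` the exact
expected recovered helicity (a per-residue state would recover
`p[i] * p[i+1]` instead). Second, the coil basin and the jitter scale
(default 2 degrees) were chosen *jointly* so that the sum
`psi(i) + phi(i+1)` stays outside all three helix windows for every
coil/coil, coil/helix and helix/coil combination, and a helical pair
leaves its own +/-10 degree window with probability below 0.1%. A broader
coil region or a larger jitter silently leaks probability across the
window boundaries (for example, 5-degree jitter on each angle puts about
16% of alpha draws outside the +/-10 degree sum window), which would turn
exact ground truth into an uncontrolled approximation.

What the generators do **not** emulate — and hence what passing tests do
not show about real MD data: time correlation (frames are independent, so
block-averaging error estimates are exercised on white noise only),
anisotropic and collective fluctuations, coupling between backbone
dihedrals and Cartesian fluctuation amplitudes, side chains, solvent, and
periodic-boundary artefacts (inputs are assumed whole).

## Numerical conventions and degenerate inputs

* Angles are wrapped to `(-180, 180]` degrees before window tests; sums
  are wrapped likewise. The shared boundary at `s = -115` between the pi
  window `[-135, -115)` and the alpha window `[-115, -95]` is resolved in
  favour of alpha; sequential-definition bounds are closed intervals.
  These conventions make the three pairwise windows provably disjoint.
* Superposition requires at least three non-collinear points; collinear
  configurations (second singular value below `1e-8` of the first) raise
  a degeneracy error. Reflections are excluded by the determinant
  correction, so the rotation is always proper.
* RMSF alignment performs one iteration against the window-mean
  structure.
* Missing backbone atoms mask the affected residue's dihedrals (with a
  warning) rather than failing; masked residues break sequential runs and
  drop their pairs.
* Residues are indexed 0-based and contiguous internally; original PDB
  numbers are carried as labels for reporting. Only the first model and
  one chain of a PDB are read; waters, ions and heteroatoms are excluded,
  but Ace/Nme caps are kept so terminal dihedrals stay defined.
* Table-reproduction rounding is half-away-from-zero at two decimals
  (`round()`'s half-to-even would turn 0.125 into 0.12).
* Trajectory formats are DCD (read; a minimal CHARMM-format writer is
  included because the installed R stack has none) and multi-model PDB
  (text, used for fixtures). XTC is not supported: no reader exists in
  the R dependency stack, and adding a binary parser for one more format
  was not worth the surface area.

## Test problem sizes

The suite runs entirely on synthetic data: 5-25 residue backbones,
Gaussian ensembles of 3 000-6 000 frames for module tests and 20 000
frames for the parameter-recovery checks, two-state series of 10 000
frames, and 50 random 5-point instances for the superposition oracle
(a quaternion-grid scan refined by Nelder-Mead, independent of the SVD
path it checks). These sizes put binomial and chi-squared sampling errors
comfortably below the asserted tolerances (2% for amplitude recovery,
3 binomial standard errors for helicity recovery).

## Known limitations

* Thresholds and Lindemann reference bands address single-chain globular
  folds; the package deliberately reports, rather than judges, values for
  disordered systems, where no universal band exists.
* Rg distributions are plain histograms; no reweighting across ensembles.
* The similarity verdict uses the block-averaged mean RMSD only; it does
  not test distributional overlap.
* Automatic detection of structural cores, DSSP-style hydrogen-bond
  secondary structure, and helix-coil model fits are out of scope.
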