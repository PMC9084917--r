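---
title: "Selecting near-native peptide/MHC decoys by predicted RMSD: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting near-native peptide/MHC decoys by predicted RMSD: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(decoyrank)
```

## The problem

Structural modeling of nonameric peptides bound to class I MHC proteins
(the dominant antigen-presentation geometry in humans, exemplified by
HLA-A\*02:01) proceeds by sampling many candidate conformations — *decoys* —
and then selecting one as the prediction. The standard selection criterion,
lowest total energy, fails for this system: decoy ensembles routinely span
almost 3 Å of peptide heavy-atom (HA) RMSD from the experimentally determined
structure while differing by only a few energy units, and the lowest-energy
decoy is frequently far from the best one sampled. `decoyrank` implements the
alternative: regression functions that predict each decoy's HA RMSD from
per-residue structural and energetic features, so decoys can be ranked and
selected by *predicted deviation from the true structure* rather than by
energy.

## Geometry: what "RMSD" means here

All RMSDs in this package are **groove-superposed peptide RMSDs**. The
reference (crystal) structure is superposed onto each decoy using only the Cα
atoms of heavy-chain residues 1–180 — the α1/α2 platform that forms the
peptide-binding groove — via the Kabsch algorithm (proper rotations only;
reflections excluded by the usual determinant correction). The peptide never
participates in the fit, so the reported deviation measures modeling error in
the frame of the MHC, not alignment slack. RMSD is then computed over peptide
atoms only, for four atom classes: Cα, heavy (HA), backbone (N, CA, C, O,
plus OXT), and side chain.

Numerical and policy choices:

* **Atom pairing** is by atom name within each residue. No symmetry
  correction is applied for chemically equivalent atoms (e.g. Phe CD1/CD2):
  the upstream protocol does not use one, and adding it silently would change
  reported values. A terminal OXT is compared only when present in both
  structures. Unpaired atoms are skipped with a warning; if more than 10 % of
  a class is unpaired the comparison errors instead of quietly degrading.
* **Superposition with missing residues** falls back to the common groove
  subset (with a warning) and errors below 3 common residues.
* **Alt-locs**: the first conformer listed wins, extending the first-copy
  convention used for asymmetric-unit copies. Hydrogens are always dropped on
  read: crystal references generally lack them and every RMSD here is
  heavy-atom.

Solvent accessible surface area (SASA) uses Shrake–Rupley sphere sampling
with a 1.4 Å probe and, by default, 960 points per atom placed on a
deterministic golden-spiral lattice — no RNG, so SASA is bit-reproducible and
quadrature error falls as 1/n (the 960 → 4000 point difference is below
0.5 % on the bundled fixtures). Van der Waals radii default to a Bondi-type
heavy-atom table (C 1.70, N 1.55, O 1.52, S 1.80 Å) and are replaceable; the
scoring suite that produced the original feature tables uses slightly
different radii, so exact numeric parity with that program is deliberately
not attempted. Hydrophobic SASA counts carbon and sulfur atoms, the
convention of that scoring framework; the predicate is configurable. SASA is
computed on the full complex (peptide in groove), because the features are
meant to describe the bound state's interaction with implicit solvent.

## Features

Per-residue score terms for the 9 peptide positions are ingested from
Rosetta-style per-residue tables or generic CSV, joined with per-residue
SASA/hSASA, and assembled into one row per decoy with columns
`p{position}_{term}` in deterministic position-major, term-alphabetical
order. The filtering rules reproduce the training-data policy: drop columns
with zero variance across decoys, and drop terms that are specific to residue
identity (e.g. an aromatic ring-planarity term) via an explicit exclusion
list. Reference corpora for this system settle near 130 surviving terms; since any
exact list is tied to its corpus, the term universe here is data-driven and
the *rules*, not a fixed list, are what the package implements.

Columns are standardized to mean 0 and sample standard deviation 1
(n − 1 denominator, the convention of the statistical environment the
protocol was developed in). The scaler is a first-class object stored inside
every model, so new decoys are always scaled with training statistics.
Two orderings are possible around the 80/20 train/test split: the upstream
protocol scales first and splits second; fitting the scaler on the training
rows only avoids a (mild) leakage. Both are available — the fit functions
reuse an existing scaling attribute if present — and the split itself is
seeded, with optional stratification by target-RMSD quantile bins so the
train and test RMSD distributions are comparable.

Total energy and peptide-only energy are carried as metadata and are
*never* predictor features: they are the selection baselines the regression
functions are compared against.

## Regression functions

Four function families predict HA RMSD from the standardized features:

* **OLS** — interpretable per-term weights plus intercept; rank-deficient
  designs fall back to the minimum-norm pseudo-inverse with a warning
  (feature counts close to or above decoy counts make collinearity a real
  possibility).
* **PLS** — NIPALS with deflation; with a univariate response this equals
  SIMPLS, and with `ncomp = rank(X)` it reproduces OLS exactly (a property
  the tests assert). The default of 10 components is where cross-validated
  error stops improving on this class of feature matrices.
* **linSVR / radSVR** — ε-insensitive support vector regression, linear or
  Gaussian-RBF kernel. The solver is an SMO on the standard 2n-variable
  dual with maximal-violating-pair selection (second-order choice of the
  partner index when the kernel matrix is in memory), KKT tolerance 1e-4 and
  an iteration cap of 1e6. ε defaults to 0.1 Å — the conventional default of
  the reference SVR implementations, since the training protocol leaves it
  unstated — and is configurable everywhere.

A solver note that matters in practice: when the number of decoys exceeds
the number of features, the linear-kernel dual is singular and SMO-type
solvers (this one and libsvm alike — the two match iteration-for-iteration
on small problems) stall near the optimum without formally reaching a tight
KKT tolerance. The returned function is still near-optimal; the package
warns on a capped fit and keeps it, and grid search ranks such fits by their
honest cross-validated RMSE rather than discarding them. Hard solver errors
become missing grid cells. Large training runs in the test suite therefore
pass an explicit, smaller iteration budget (2e5) as a documented scale-down;
held-out R² changes only in the third decimal.

Hyperparameters come from a seeded, k-fold (default 10) cross-validated grid
search on decade-spaced lattices: C from 1e-8 to 1e8 for linSVR; C from 1e-4
to 1e10 crossed with γ from 1e-11 to 1e2 for radSVR. The γ grid is capped at
1e2 by design even where CV error is still falling — large γ localizes each
support vector's influence and overfits. Fold assignments are shared across
grid points and model kinds so comparisons are paired; RMSE ties within
1e-12 break toward the smallest C, then the smallest γ, preferring the
simpler model. radSVR fits carry a guard against the known failure mode of
an overfit RBF function: if more than 20 % of training predictions collapse
within ±0.05 Å of a single value while actual RMSDs span more than 1 Å, the
fit warns.

Models serialize to a versioned JSON schema at full numeric precision;
a reloaded model reproduces predictions to better than 1e-12.

## Ranking, selection and evaluation

Decoys are ranked per target by any criterion (true HA RMSD, total energy,
peptide energy, or model-predicted RMSD) with average ranks for ties, and
selected by argmin with a deterministic lexical tie-break on decoy id.
Ensembles whose criterion is constant — the limited-sampling case where all
decoys cluster at one RMSD and there are simply no good vs. bad decoys to
discriminate — report an `NA` Spearman correlation with a warning rather
than an error.

`compare_methods()` evaluates selection strategies across targets and runs
paired tests on per-target selected-decoy RMSDs: a Wilcoxon matched-pairs
signed-rank test (zero differences dropped; exact null by dynamic-programming
enumeration over the possibly tied mid-ranks for n ≤ 25, tie-corrected
normal approximation with continuity correction above) and a paired t-test.
One-tailed alternatives follow the convention that the newer method's RMSDs
are *smaller*. Identical selections make a paired test undefined
(zero-variance differences); `paired_t()` errors in that case, and
`compare_methods()` reports the degenerate result (statistic 0, p 1) with an
explanatory note instead of failing an entire evaluation.

Selected-decoy error can be stratified by peptide position and atom class,
and by (position, amino acid) with a minimum-representation rule: cells
backed by fewer than 3 peptides are omitted entirely, never reported as 0.

## The synthetic world

Everything above is testable without external modeling software because the
package ships a generator with known ground truth. Its defaults state the
emulated world once:

* per-target mean HA RMSD ~ log-normal(meanlog = log 1.3, sdlog = 0.45),
  spanning roughly 0.5–3.5 Å — the range decoy ensembles for this system
  actually cover;
* within-target variance 0.27 Å², matching the conformational-sampling
  breadth of the most aggressive sampling protocol (reported per-target variance
  figures for such protocols do not state units; Å² of HA RMSD is assumed
  and exposed as `per_target_variance`);
* 9 × 14 = 126 feature columns (≈ the 129-term corpus), block-correlated
  within positions, with a sparse planted linear map (or a quadratic map for
  kernel-advantage checks) from features to RMSD plus 0.15 Å residual noise,
  clipped at zero;
* a total-energy column blended in closed form from the true-RMSD channel
  and an orthogonalized noise channel so its sample correlation with true
  RMSD *exactly* equals the requested value — zero by default, emulating an
  energy function that is blind to decoy quality.

Coordinate-level fixtures come from an idealized extended nonamer placed in
a stylized 180-residue Cα groove scaffold, perturbed by per-residue Gaussian
displacements smoothed over a 3-residue window and scaled by a center-peaked
position bias (peptide centers bulge out of the groove and are hardest to
model). These decoys are geometrically valid but make no claim of physical
realism: bond lengths are approximate, side-chain geometry is schematic, and
no force field is involved. Achieved RMSDs are therefore always *measured*
through the geometry module, never assumed from the perturbation magnitude.

What a green test establishes, and what it does not: the synthetic suite
verifies the machinery — superposition, feature plumbing, solvers, selection
statistics — under a known data-generating process. It does not certify
performance on real Rosetta decoys, whose feature distributions, error
structure and energy correlations differ from any Gaussian plant; performance
figures obtained on real decoy corpora are not reproducible from this
package alone and are not claimed by it.

## Seeds and determinism

Every stochastic operation takes an explicit seed. Suites use named
per-target RNG streams derived from the master seed, so adding targets never
shifts existing ones; fold assignments, splits and SASA quadrature are all
deterministic. Regenerating any suite from its recorded spec and seed is
bit-identical, and the command-line entry point stamps a provenance header
or block on every output.

## Known limitations

* No mmCIF input, no symmetry/assembly handling, no electron-density logic.
* Non-standard residues are rejected rather than mapped.
* The SVR solver, like its references, is practical to a few thousand
  training rows on one core; corpus-scale training (tens of thousands of
  rows) calls for long runs or a primal linear solver, out of scope here.
* Exact numeric parity with any specific external SASA implementation is a
  radii-table away but not asserted.
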