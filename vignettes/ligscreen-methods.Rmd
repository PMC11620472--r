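---
title: "Methods: fingerprint QSAR screening, decoy validation and trajectory analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fingerprint QSAR screening, decoy validation and trajectory analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ligscreen)
```

`ligscreen` implements a ligand-based virtual-screening workflow of the
kind used to search natural-product libraries for inhibitors of a
protein target (the motivating application is TNF-&alpha;, the central
pro-inflammatory cytokine in rheumatoid arthritis): a deep
feed-forward regression model maps binary molecular fingerprints to
pIC50, the trained model ranks a screening library, rule filters prune
the hits, a decoy benchmark quantifies how well similarity ranking
separates known actives from property-matched decoys, and a trajectory
analytics layer summarises molecular-dynamics output for the
top-ranked complexes. This vignette records the models, conventions
and design choices in one place.

## Activity data and descriptors

IC50 values (nM) are converted to pIC50 = 9 − log10(IC50~nM~), the
negative log of the molar concentration; the log scale makes the
response roughly symmetric and comparable across potency ranges.
Records lacking a SMILES or a positive activity are dropped and
counted, never silently. Duplicate structures are detected by Open
Babel canonical SMILES and collapsed to one record; duplicate
activities are aggregated by the **median** of pIC50 (robust to a
single bad assay; mean and first-seen are selectable).

Descriptors are binary fingerprints. Two generators are built in:

* **Morgan (circular)** — iteratively hashed atom environments up to a
  radius (default 2), folded to `nbits` (default 2048). Atom
  invariants: atomic number, heavy degree, attached hydrogens, formal
  charge, ring membership.
* **Layered (path-based)** — hashed element/bond-order sequences of
  all simple paths of 1–9 bonds (defaults), folded to `nbits`.

Both canonicalise the input SMILES first, so every spelling of a
molecule maps to the same bit vector. Precomputed 881-bit PubChem
fingerprint tables (the PaDEL CSV dialect) are *ingested*, not
regenerated: the 881 bit definitions are tool-specific, and
re-implementing them would add nothing testable. Tables whose width is
not 881 load with an explicit mismatch flag.

**Variance filtering.** A binary column with a fraction *p* of ones
has variance *p*(1 − *p*); near-constant bits carry no
structure–activity information. The threshold default is 0.16 — the
0.8 × 0.2 convention for binary descriptors — because the workflow the
package reproduces does not state its threshold. Train and library
matrices are filtered separately, the retained name sets are
**merged by set union** (order: train names, then novel library
names), and both matrices are projected onto the merged schema
(missing columns zero-filled). Union is the only reading consistent
with retained-set sizes of 235 and 251 combining to 342 (235 + 251 −
144); an intersection mode exists but is not the default.

## The pIC50 regressor

`qsar_net()` fits a fully connected network: input → five hidden
layers of 600 (tanh), 560 (relu), 300 (relu), 420 (elu), 700 (tanh)
units with dropout 0.1/0.1/0.3/0.2/0.4 and per-layer kernel penalties
L1 = 0.00113, L2 = 0.00015 → one linear output. Training minimises
mean-squared error plus the penalties with Adam (learning rate 1e-4,
β₁ = 0.9, β₂ = 0.999), batch size 32 (unstated upstream; the common
default), for up to 120 epochs. Early stopping on a validation series
is available but off by default: "terminating training after 120
epochs" is read as an epoch cap, with patience exposed for users who
want the callback reading. Penalties apply to hidden-layer kernels
only, not biases or the output layer. Initialisers are the classic
schemes (He normal, Glorot uniform/normal, and scaled uniform on
±0.05); all randomness — initial weights, shuffling, dropout masks —
funnels through `config$seed`, so refitting reproduces the model
bit-for-bit. On 342 inputs this architecture has exactly 1,132,481
trainable parameters.

The implementation is plain BLAS matrix arithmetic (no deep-learning
framework): each minibatch step is a handful of dense GEMMs, which
trains fingerprint-scale models (≈10³ compounds × ≈10² descriptors) in
seconds to a few minutes on one CPU.

Evaluation uses the standard error metrics over *k* observations —
MSE = (1/k)Σ(yᵢ−ŷᵢ)², MAE = (1/k)Σ|yᵢ−ŷᵢ|, MAPE =
(100/k)Σ|(yᵢ−ŷᵢ)/yᵢ| — with MAPE flagged undefined when any target is
zero (cannot occur for realistic pIC50, but the guard is there).
`random_search()` samples hyperparameter candidates with a seed,
trains each on one fixed split and ranks by validation MSE.

## Screening and rule filters

"Upper fourth quartile" selection supports two readings.
**Value-range** (default): select scores ≥ min + 0.75·(max − min).
**Rank**: select scores ≥ Q3 (linear-interpolation quantile, type 7).
The default is value-range because a rank quartile always selects at
least a quarter of the library, which is inconsistent with the
workflow's reported 186 of 2563 selections; the mode used is recorded
in every output row. Ties at the cut are included in both modes.

Drug-likeness follows the SwissADME conventions: Lipinski passes with
at most one violation of {MW ≤ 500, MLOGP ≤ 4.15, HBD ≤ 5, HBA ≤ 10};
Ghose, Veber, Egan and Muegge are conjunctive, with bounds as given in
`?apply_rule_filters`. MW, Wildman–Crippen logP (WLOGP), molar
refractivity, TPSA and donor counts come from Open Babel's property
engine; acceptor counts use Lipinski counting (N + O); rotatable bonds
are non-ring single bonds between non-terminal heavy atoms excluding
amide C–N; ring count is the cyclomatic number of the heavy-atom
graph. **MLOGP is a truncated Moriguchi-type estimate** built from the
dominant terms (weighted carbon/halogen count, N+O count, N/O
proximity, unsaturation, quaternary N, nitro, alkane and ring
corrections); the omitted terms (intramolecular H-bond, aromatic polar
substituents, amphoteric, isothiocyanate, β-lactam flags) need
SMARTS-level typing and matter mainly for specialised chemotypes. It
serves the Lipinski MLOGP ≤ 4.15 bound, not accurate logP prediction.
Muegge's original XLOGP3 bound is likewise approximated by WLOGP.

## Retrospective decoy validation

Given actives, decoys and a reference control compound, every molecule
is scored by Tanimoto similarity (|A∩B|/|A∪B|; 0 for two empty
bitsets) to the control. The ROC curve is a descending-threshold sweep
with trapezoid AUC, which under the midrank tie convention equals
P(s~active~ > s~decoy~) + ½P(equal) — the package tests both routes
against each other. The enrichment factor at fraction *f* takes the
top n = ⌈f·N⌉ of the ranking and reports (x/n)/(A/N); ceiling is the
only slice convention consistent with the reference EF values
(24.81 and 12.40 at N = 521, A = 21, n = 6), the control is counted
as an active (24.81 = 521/21 requires it), and boundary ties are
broken by stable id order and recorded. Distributional separation is
tested with a Mann–Whitney U (exact for small untied samples, normal
approximation with tie correction otherwise); the test is rank-based
to match the heavy-tailed, bounded similarity scores. Docking scores
should be negated before ranking so that higher is uniformly better.

## Trajectory analytics

Internal units are GROMACS conventions: nm, ps, amu; PDB Å are
converted at ingest (multi-model parsing is delegated to bio3d, with a
pre-scan that names the first model whose atom count deviates).
Superposition is the Kabsch algorithm — SVD of the cross-covariance
with determinant correction, so only proper rotations are used; a
collinear selection is rejected because its rotation is not unique.
Conventions chosen where the upstream description is silent:

* **RMSD**: each frame is fitted to the reference over the selection
  before the deviation is measured.
* **RMSF**: the reference is the *mean structure*, computed after an
  initial fit to frame 1 and refined with one more fit pass.
* **Rg**: mass-weighted, √(Σmᵢ|rᵢ−r~com~|²/Σmᵢ).
* **SASA**: Shrake–Rupley with probe 0.14 nm and 960 quadrature points
  per atom on a deterministic Fibonacci sphere (no RNG); accuracy
  scales as ~2/n~points~ relative. Radii are Bondi values.
* **H-bonds**: counted when donor–acceptor distance ≤ 0.35 nm and
  H–D–A angle ≤ 30° (the GROMACS default geometry).
* **PCA / DCCM**: computed on a trailing window of frames (mirroring
  the practice of analysing the equilibrated tail of a simulation),
  Cα selections by default, after superposition on the window mean.
  PCA eigendecomposes the 3s×3s coordinate covariance; eigenvalue
  fractions sum to 1 and eigenvectors are orthonormal by construction.
  DCCM entries are ⟨Δrᵢ·Δrⱼ⟩/√(⟨|Δrᵢ|²⟩⟨|Δrⱼ|²⟩); atoms with zero
  fluctuation get 0 and are flagged rather than NaN.

MM/GBSA bookkeeping consumes the four per-complex component averages
(ΔE~vdW~, ΔE~elec~, ΔG~GB~, ΔG~SA~) and completes
ΔG~gas~ = ΔE~vdW~ + ΔE~elec~ (bonded terms cancel in single-trajectory
analyses), ΔG~sol~ = ΔG~GB~ + ΔG~SA~, and ΔG~bind~ = ΔG~gas~ + ΔG~sol~
with the entropy term TΔS taken as zero — its contribution is
negligible when ranking ligands against one receptor, which is the
only use made of the numbers here. No force-field energies are ever
computed; the component averages are inputs.

## Synthetic data: what it emulates, and what it does not

The generators reproduce the *shapes and statistical structure* of the
real inputs so the full pipeline is testable offline:

* `sim_fingerprint_activity()` — defaults n = 953 compounds × d = 881
  bits (the emulated training scale), i.i.d. Bernoulli(0.2) bits, 20
  informative bits with uniform weights in ±1, Gaussian noise sd 0.3
  pIC50 units around an intercept of 6. Ground truth is returned, so
  parameter recovery is checkable: held-out MSE should approach the
  noise floor σ² = 0.09 as n grows.
* `sim_active_decoy_library()` — defaults 20 actives, 500 decoys, one
  control at bit density 0.1 (sparse, fingerprint-like); actives are
  the control with each bit flipped at rate 0.05, decoys are fresh
  draws. This plants a controlled Tanimoto separation with expected
  active-vs-decoy contrast but no chemistry.
* `sim_trajectory()` — frames are base + Σₖ cₖ(t)·vₖ + isotropic
  Gaussian noise, with deterministic sinusoidal coefficients of unit
  time-averaged variance, so the planted covariance is
  Σₖ aₖ²vₖvₖᵀ + σ²I and the expected PC1 variance fraction has the
  closed form (a² + σ²)/(a² + 3Nσ²). `sim_rigid_trajectory()` applies
  random proper rotations/translations to a fixed frame.

What passing these tests does **not** show: real fingerprints have
correlated bits and nonlinear structure–activity relationships; real
decoys are property-matched rather than random; real trajectories have
anharmonic, non-sinusoidal dynamics. The synthetic suite validates the
*arithmetic and statistical machinery*, not chemical or biophysical
realism. One geometric subtlety is inherent to superposition, not to
the generators: a planted mode with a large rigid-body component is
(correctly) absorbed by fitting, so fixtures that test mode recovery
use spatially interleaved blocks or rigid-free mode vectors, and
few-atom noise trajectories show small spurious correlations because
six rigid degrees of freedom are removed.

## Numerical choices and problem sizes

* Hashing uses exact double-precision modular arithmetic
  (mod 2147483629), deterministic across platforms.
* Weight storage round-trips at `%.17g`, so reloaded models predict
  bit-identically.
* Quantiles are linear-interpolation (type 7) everywhere.
* The recovery benchmark in the test suite uses n = 4000, d = 100, 10
  informative bits, noise sd 0.3, a single 128-unit hidden layer
  (lr 0.01, L2 1e-4, 100 epochs) — a deliberately compact architecture
  for a linear planted signal; the full five-layer stack remains the
  package default for real fingerprint data. The end-to-end pipeline
  demo (`pipeline_config()`) similarly uses a 64/32 network, keeping a
  complete synthetic run in the seconds range; all stage logic is
  identical under the full architecture.
* Monotone-recovery checks run n ∈ {500, 2000, 8000} over 3 seeds with
  a 64-unit net and 40 epochs.

## Known limitations

* The 881 PubChem bit definitions are not reproduced; external tables
  are ingested as-is.
* MLOGP is approximate (above); compounds whose Lipinski pass hinges
  on MLOGP within ~0.5 of 4.15 may be classified differently than by
  tools with full Moriguchi typing.
* Hashed fingerprints use Open Babel kekulised bond orders; exotic
  tautomer/aromaticity edge cases follow Open Babel's perception.
* The feed-forward trainer is single-threaded BLAS; it is not meant
  for networks beyond a few million parameters.
* Binding-affinity-based enrichment (docking-score ranking) is
  supported by negating scores, but docking itself is out of scope.
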