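---
title: "Ensemble virtual screening with a naive Bayesian consensus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble virtual screening with a naive Bayesian consensus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dockscreen)
library(dplyr)
```

## The problem and the model

Single-structure docking treats a flexible binding site as rigid. The
protocol implemented here approximates receptor flexibility by screening
against an *ensemble* of crystallographic conformations of one target and
combining the per-conformation docking scores with a naive Bayesian
classifier (NBC). The package covers the pipeline around the docking engine,
which remains external: conformer selection, validation, consensus scoring,
and sequential hit triage.

### Conformer selection

All conformers share one sequence, so structural correspondence is known a
priori. The binding site is the set of residues with any atom within 10 Å
(inclusive) of the co-crystallized ligand. Pairs of conformers are superposed
on the shared binding-site CA atoms by the Kabsch SVD algorithm — since the
correspondence is fixed, a sequence-aware aligner would add nothing but
nondeterminism — and the pairwise RMSD matrix is clustered by UPGMA (average
linkage), cut at *k* = 10 groups by default. UPGMA is written in-package
because we pin a deterministic tie-break (the lexicographically smallest id
pair merges first); on matrices without ties it agrees with
`hclust(method = "average")`, which the test suite asserts. Within each
cluster the structure with the best (numerically smallest) resolution is the
representative. Whether CA or all heavy atoms should feed the RMSD is
genuinely open; CA is the default because it measures backbone pocket
geometry rather than side-chain rotamer noise, and a `"heavy"` switch is
provided.

### Validation: docking power and screening power

*Docking power* asks whether re-docking the crystallographic ligand
reproduces its pose: success is heavy-atom RMSD ≤ 2.0 Å (inclusive), computed
without superposition since both poses share the receptor frame.
Chemically equivalent atoms (a flipped carboxylate, a rotated phenyl) make
the naive ordered RMSD overestimate; `pose_rmsd(..., "element_hungarian")`
solves the minimum-cost assignment within each element class (a
Jonker–Volgenant solver, validated against brute-force permutation
enumeration — no assignment solver was available among the package's
dependencies).

*Screening power* asks whether a conformation separates known inhibitors
from decoys. Two measures are used: a two-sample t-test on the score
distributions (Student by default; Welch behind a flag because the design is
1:20 imbalanced) and the ROC AUC by the rank (Mann–Whitney) method with ties
counted ½. Score separations at realistic scale push p-values far below
double underflow, so the p-value is always computed in log space and reported
alongside as `log10_p`; mode selection (e.g. SP vs XP) compares `log10_p`,
then AUC, then listing order.

### The consensus classifier

Scores of conformation *j* are discretized into `n_bins = 10`
equal-frequency bins fitted on the full training pool — quantile binning
makes the classifier invariant to any monotone rescaling of a docking
function, which differs arbitrarily between engines. Bin *b*, holding
`A_b` actives of `N_b` compounds, receives the Laplacian-corrected relative
likelihood weight `w_b = ln[(A_b+1)/((N_b+1)π)]` with prior
`π = A_total/N_total`. The correction shrinks sparse bins toward the prior
(an empty bin scores `ln(1/π)` at `A_b = N_b = 0`), which is what makes a
10-feature product usable at 1:20 imbalance without resampling. A useful
audit identity follows directly from the formula:
`Σ_b (N_b+1)·π·exp(w_b) = A_total + n_bins_effective`, asserted to 1e-9 in
the tests. Scoring sums bin weights across conformations; values outside the
training range clamp to the terminal bins, and missing scores (failed
dockings) marginalize out, a compound missing every score being an error.
The headline `model_auc()` is resubstitution — matching standard screening
practice, where the validation set is the training set — with an optional
stratified k-fold `nbc_cv_auc()` for an unbiased view; on a null feature
resubstitution shows a small upward refit bias that shrinks with n, which the
tests document rather than hide. A Gaussian class-conditional likelihood
(`likelihood = "gaussian"`) is included only as a sensitivity check.

### The sequential cascade

`run_cascade()` triages a library in five deterministic stages:
ensemble-dock rank (minimum score across conformations by default — the
common ensemble-docking convention; mean as alternative; missing scores
imputed as worst observed + 1.0) → Bayesian re-score → Lipinski/Veber then
REOS → Butina diversity clustering → hot-residue interaction filter. The
shipped full-scale profile keeps 10,000 / 2,000 / 200 / 100 / 49; tests and
the acceptance script run a 1/10-scale profile (1,000 / 200 / 20 / 10 / 5) on
a 20,000-compound synthetic screen. Boundary ties break by compound id,
survivors nest stage over stage, and every decision lands in a per-compound
log.

Filter windows: Lipinski (MW ≤ 500 Da, logP ≤ 5, HBD ≤ 5, HBA ≤ 10, with a
configurable violation allowance) plus Veber (RotB ≤ 10, TPSA ≤ 140 Å²,
never waivable); REOS as the published property windows (MW 200–500,
logP −5..5, HBD ≤ 5, HBA ≤ 10, charge −2..+2, RotB ≤ 8, heavy atoms 15–50)
plus reactive-group exclusion via boolean `reactive_*` columns. All
boundaries are inclusive on the passing side. Descriptors are consumed, not
computed: the rules are the testable logic; computing logP or TPSA would
drag in a full chemistry stack for no gain here, and an adapter can populate
the descriptor table from any source. Similarity "higher than 0.8" is
implemented as ≥ 0.8 by default with a strictness flag, since sphere
exclusion conventionally includes the boundary; fingerprints are opaque bit
sets (stored sparsely as on-bit indices) because the originating fingerprint
chemistry is not part of the method.

### Interaction geometry

No geometric cutoffs are canonical in the source protocol (interactions
there are read from modeling-suite reports), so the detectors use the
conventional values, all configurable: H-bond donor–acceptor ≤ 3.5 Å with
D–H⋯A ≥ 120° (the angle gate is skipped with a warning when no hydrogen
position is available, as with crystallographic receptors), hydrophobic
C(ligand)–C(side-chain) ≤ 4.5 Å aggregated to the per-residue minimum, ionic
group-center distance ≤ 4.0 Å. The default hot-residue profile
(`pi3kg_hot_residues()`: hinge Val882 plus Lys833, Tyr867, Asp964, Asp836,
Thr886, Thr887, Met953, Ile963) is an inference from the recurrent
crucial-interaction residues of the PI3Kγ ATP pocket and is fully
user-overridable. Ligand RMSF is `sqrt(mean_t ||x_i(t) − x̄_i||²)` over ≥ 2
frames, with optional per-frame receptor-CA alignment; occupancy is the
fraction of frames a (residue, type) contact is detected, capped at one
count per frame. Water bridges need explicit solvent and are provided only
as an optional detector, excluded from defaults. Trajectory snapshots are
consumed as multi-model PDB or SDF — binary MD formats are out of scope.

## What the generators emulate — and what they do not

`gen_score_table()` draws class-conditional Gaussian scores with an
equicorrelation factor: compound aptitude `z ~ N(0,1)`, and
`score_j = μ_class,j + σ(√ρ·z + √(1−ρ)·ε_j)`. This is the minimal structure
that dials single-feature AUC (`pnorm(Δ/(σ√2))` in closed form at ρ = 0) and
the ensemble-consensus gain independently; the default sizes are the
validation design the method targets, 800 actives against 16,000 decoys
(1:20) over 10 conformations. Real docking scores are unimodal and shifted —
which this matches — but also heavy-tailed, engine-correlated and
pose-failure-censored in ways a Gaussian factor model is not; a passing test
therefore certifies the statistics and the pipeline logic, not the behavior
of any docking engine. Likewise `gen_descriptor_table()` calibrates marginal
rule pass rates with independent properties (real descriptors correlate;
MW with heavy atoms, logP with TPSA), `gen_fingerprints()` plants
near-disjoint template clusters with a flip rate inverted from the target
within-cluster Tanimoto `E[sim] = (1−f)²/(2−(1−f)²)`, and
`gen_toy_complex()` builds a helical-spacing residue chain with
H-bond-satisfying or deliberately distant ligand geometry. None attempt
realistic 3D chemistry.

## Numerical choices

- Equal-frequency edges use type-7 quantiles (midpoint convention); fully
  tied features collapse to one bin with a warning.
- Kabsch refuses < 3 points and collinear sets (no unique rotation), and
  the returned rotation is always proper (det +1).
- Rank AUC is computed so that it is *bitwise* equal to exhaustive pairwise
  counting (the numerator is a dyadic rational; the orientation flip negates
  scores rather than subtracting the AUC from 1).
- Deterministic tie-breaks everywhere randomness is not wanted: UPGMA merges
  by smallest id pair, Butina centroids by neighbor count then id, cascade
  boundary ties by compound id, mode choice by listing order.
- Problem sizes in tests and the acceptance script (2,000/class for the
  closed form, 800:16,000 × 10 for the consensus gain, 20,000 compounds for
  the cascade) were chosen as the smallest sizes at which the statistical
  assertions have comfortable margins.

## Known limitations

Docking, MD, and free-energy calculation are out of scope by design; the
package consumes their tabular and structural outputs. PDB parsing covers
the fixed-column ATOM/HETATM dialect with REMARK 2 resolution (alternate
locations and insertion codes are not modeled). The hot-residue default is a
profile, not a ground truth. Resubstitution AUC is the protocol-faithful
headline number but is optimistically biased; use `nbc_cv_auc()` when an
unbiased estimate matters.
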