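---
title: "Separating native from mirror-image backbone models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating native from mirror-image backbone models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MirrorSort)
```

## The problem and the model

A Cα contact map records which residue pairs lie within a distance cutoff;
it is invariant under reflection, so a backbone and its mirror image are
indistinguishable at the map level. Ensembles reconstructed from contact
maps therefore mix natively oriented models with mirror-image ones.
`MirrorSort` separates the two groups with a pipeline of four stages:

1. **Score** every model with a small set of energy terms, two of which
   (the Ramachandran preference `rama` and the amino-acid-conditional
   torsion probability `p_aa_pp`) are sensitive to backbone chirality
   because torsion distributions of real proteins are strongly
   asymmetric, while the distance-based terms (`hack_elec`, `fa_atr`,
   `fa_rep`) are reflection-invariant on exact mirrors and carry signal
   only to the degree that reconstructed mirrors are *not* exact
   reflections.
2. **Test** each term per domain between the known (or
   superposition-derived) orientation groups, and summarize usability
   across domains as the fraction of domains where the term
   differentiates significantly.
3. **Select** features by one of six strategies (`all`, `sig60`, `top2`,
   `top1`, `common3`, `total_only`).
4. **Cluster** each domain's models into two groups by k-means and call
   the cluster with the lower mean (standardized) energy *native* —
   natively oriented structures are the more stable ones.

The method's ground truth, where a reference structure exists, is the
double superposition rule: a model is *native* if its proper-rotation
(Kabsch) RMSD to the reference is lower than to the reference's mirror
image. Restricting superposition to proper rotations is what makes RMSD a
chirality detector: the optimal orthogonal alignment of a chiral trace
onto its reflection would require determinant −1, and with that forbidden
a residual RMSD on the order of the fold's size remains.

Assumptions: models are backbone-only (N, CA, C, O), single-chain,
length-matched to their reference, with standard amino acids. Residues
are renumbered sequentially because every downstream quantity (torsions,
contact separation, bonded exclusions) depends only on sequence
separation.

## Parameters that matter

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| contact cutoff | 8 | Å | standard Cα contact-map convention; boundary inclusive (d ≤ cutoff) |
| contact min. separation | 1 | residues | all off-diagonal pairs, including sequence neighbours |
| favored threshold | 0.02 | per-bin mass | Ramachandran convention (inclusive) |
| allowed threshold | 0.0005 | per-bin mass | idem |
| grid bin width (surrogate) | 10 | degrees | see "Density semantics" below |
| mode sd (surrogate) | 15 | degrees | realistic width of torsion basins |
| Coulomb constant | 322.0637 | kcal·Å/(mol·e²) | electrostatic prefactor |
| dielectric | ε(r) = r | — | distance-dependent screening, so pair energy ∝ 1/r² |
| Coulomb cutoff / min. distance | 5.5 / 1.45 | Å | short-range screened electrostatics; pair terms shifted to 0 at cutoff |
| LJ radii / ε | N 1.75, CA 2.00, C 2.00, O 1.55 / 0.10 | Å / kcal·mol⁻¹ | generic heavy-atom values (backbone models carry no hydrogens) |
| LJ cutoff | 6.0 | Å | nonbonded truncation |
| min. bond separation | 4 | bonds | excludes 1-2, 1-3 and 1-4 bonded interactions |
| charges | N −0.47, CA +0.07, C +0.51, O −0.51 | e | CHARMM-like backbone charges, net ≈ 0 per residue |
| α (significance) | 0.05 | — | per-domain two-group tests, two-sided |
| k-means restarts | 10 | — | k-means++ seeding from one seeded generator |

The energy terms are documented analogs, not numerical reproductions of
any full atomic score function: absolute values are on their own scale,
and only ordinal and statistical behaviour (which group scores lower,
which terms differentiate) is claimed or tested.

## Density semantics and the surrogate grid

Ramachandran densities are stored as **probability mass per grid bin**,
normalized to sum to 1 per residue class, and the favored/allowed/outlier
thresholds act directly on those masses. This convention forces a choice
of bin width: with very fine bins no single bin can reach the favored
threshold (a basin of width ~15° spread over 2° bins puts at most ~0.003
in any one bin), which would make the favored region empty. The surrogate
grid therefore defaults to 10° bins, at which an ideal α-helical residue
falls in a bin of mass ≈ 0.03 (favored), its mirror at (+57, +47) in a
bin of mass ≈ 0.003 (allowed, matching the empirical status of the
left-handed helix region), and mirrored β-strand torsions in essentially
empty bins (outlier). A consequence of mass-per-bin semantics is that
classification is *not* invariant under bin refinement; users loading an
empirical grid should supply it at the bin width its thresholds were
calibrated for. The loader accepts any bin width dividing 360° and
renormalizes after zero-filling missing bins.

The surrogate mixture itself: general class = right-handed helix
(−63, −43) w 0.50, sheet (−120, 130) w 0.40, left-handed helix (57, 47)
w 0.05, polyproline-II (−75, 150) w 0.05, common sd 15°; glycine adds a
mirror-symmetric copy of every mode; proline is confined near φ = −63;
pre-proline is the general mixture with an extra (−130, 75) mode. It is a
deterministic stand-in with the qualitative asymmetry of empirical grids,
not a fit to any dataset.

## Statistical design

The per-domain comparison gates between test families: each group is
screened with Shapiro–Wilk at 0.05; only if both pass is a two-sided
Welch t-test used (summary = mean), otherwise a two-sided Mann–Whitney U
(summary = median). The gate is a declared design choice — reproducible
and conservative — not the only defensible one; the branch taken is
recorded per comparison. Constant groups are treated as non-normal; two
identical constant groups yield p = 1 and RET = 1. No multiple-testing
correction is applied across terms by default, because the
differentiating fraction is reported per term; a Benjamini–Hochberg
option exists (`adjust = "BH"`).

RET is the raw ratio of group summaries; energies can be negative, so a
near-zero mirror summary makes RET undefined (reported `NA`) and
opposite-sign summaries are flagged rather than hidden.

## Clustering design

k-means uses squared-Euclidean distance with k = 2. Determinism and
permutation-stability come from canonically ordering rows before the
seeded k-means++ initialization, running 10 restarts from one generator,
and keeping the restart with the lowest within-cluster sum of squares.
With two or more selected terms, each feature column is z-scored within
the domain first — unscaled mixed-magnitude terms would reduce
multi-term clustering to whichever term has the largest variance; with a
single term raw values are used (monotone-equivalent). The labeling
statistic is the cluster mean of each model's summed standardized
selected terms, which reduces to "the cluster with the lower mean energy
is native" in the single-term case. An exact tie labels cluster 0 native
with a warning.

Evaluation uses the standard conventions: sensitivity = TP/(TP+FN) with
native as the positive class, specificity = TN/(TN+FP); some published
tables transpose the two labels, and `asPrinted = TRUE` reproduces that
swap without changing ACC, MCC or F1. Empty denominators yield 0 (MCC: 0
when any marginal is empty).

## What the synthetic generator emulates — and what it does not

`makeEnsemble` builds a reference from ideal internal coordinates,
reflects it with probability `mirrorFraction` per model, then adds iid
Gaussian coordinate noise (`noiseSd`, Å). Noise is applied *after*
reflection so mirror models are not exact reflections of native ones,
matching the reconstruction setting in which distance-based terms can in
principle carry signal. The single noise knob reproduces the three
regimes of native/mirror RMSD histograms — well-separated bimodal,
overlapping bimodal, effectively unimodal — as the noise scale passes
through the fold's intrinsic mirror RMSD (≈ 2.4 Å for a 40-residue mixed
α/β domain, so regimes at ≈ 0.3, 2.5 and 4 Å noise).

The generator does **not** emulate real reconstruction error modes:
noise is isotropic and residue-independent, bond geometry degrades with
noise instead of staying ideal, there is no compactness or
self-avoidance constraint, and coil torsions come from a fixed 12-entry
table of allowed values rather than a continuous distribution (chosen so
generated coils never start in outlier bins). Passing tests on these
ensembles therefore demonstrates the machinery and the direction of every
effect — torsion terms discriminate exact-mirror-plus-noise ensembles,
total energy fails when clash noise dominates it — but not quantitative
performance on real reconstruction ensembles, where mirrors are partially
refolded and distance terms genuinely differentiate some domains.

## Numerical choices and degenerate inputs

- Reflection plane is x = 0; any other plane differs by a proper
  rotation, which superposition absorbs (asserted in tests).
- Angles are degrees in (−180, 180]; grid lookup is nearest-bin with
  wrap at ±180°, no interpolation.
- Coulomb pair terms are shifted to vanish at the cutoff. The LJ pair
  terms are left unshifted so that the split at r_min keeps its exact
  interpretation (fa_atr = −ε_pair, fa_rep = 0 at the minimum); the
  resulting truncation step at 6 Å is ≲ 0.02 ε and identical across
  models of an ensemble.
- An RMSD tie between reference and mirrored reference (achiral traces)
  labels the model native with a warning, keeping output deterministic.
- Collinear point sets are rejected by the superposition (the rotation is
  underdetermined); models with fewer than 3 residues are rejected by
  construction.
- Contact-map difference divides the upper-triangle disagreement count by
  the reference map's contact count; the normalization is
  reference-based and therefore asymmetric, which is asserted rather than
  hidden. A contact-free reference with any disagreement yields Inf with
  a warning.
- Domains with fewer than 3 native or 3 mirror models, or with constant
  feature columns, are skipped with a machine-readable reason and never
  abort a corpus run.

## Problem sizes

The test suite and the acceptance script run entirely on generated data:
ensembles of 20–100 models of 10–44 residues, corpora of up to 50
domains, 100-domain simulated-feature benchmarks, 200-replicate null
calibrations, and 1000-table metric-oracle sweeps. These sizes give
binomial confidence intervals tight enough for every directional claim
while keeping the whole suite in a few minutes of CPU time.

## Known limitations

- Energy values are not comparable to any full score function; only
  within-ensemble contrasts are meaningful.
- On *exact* mirror pairs the distance-based terms tie by construction;
  their usability on real data comes entirely from reconstruction
  imperfections that the generator only crudely imitates.
- Helix-only folds are intrinsically hard: the left-handed helix region
  is allowed rather than outlier, so the torsion-energy gap is modest and
  clustering accuracy drops — consistent with α-rich domains being the
  hardest class for energy-based separation.
- Sequence alignment, flexible superposition, multi-chain assemblies and
  side-chain energetics are out of scope.
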