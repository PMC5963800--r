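# MirrorSort

Automatic separation of natively oriented protein backbone models from
their mirror images within per-domain model ensembles.

## The problem

Residue–residue Cα contact maps are a common intermediate representation
in protein structure reconstruction, but they are blind to chirality: a
fold and its geometric mirror image (every helix turned left-handed)
generate *identical* contact maps. Ensembles of models reconstructed from
contact maps therefore contain a mixture of natively oriented and
mirror-image backbones — typically around half of each — and a downstream
user needs an automatic way to tell them apart, ideally without knowing
the reference structure.

`MirrorSort` implements the complete workflow for structural
bioinformaticians working with such ensembles:

* **Geometric chirality analysis.** Proper-rotation Kabsch superposition
  (reflections forbidden, so a mirror image registers as a large RMSD),
  orientation assignment by the lower of RMSD(model, reference) and
  RMSD(model, mirror(reference)), backbone torsions φ/ψ/ω, and the
  positive-φ ratio Φ⁺/Φ (≈0 for native right-handed folds, ≈1 for
  mirrors).
* **Ramachandran analysis.** Density-grid classification of each scored
  residue into favored (p<sub>φψ</sub> ≥ 0.02), allowed
  (0.0005 ≤ p<sub>φψ</sub> < 0.02) and outlier (p<sub>φψ</sub> < 0.0005)
  regions, with the four-class general/Gly/Pro/pre-Pro scheme.
* **Energy terms.** Self-contained analogs of the decisive score-function
  components: Coulomb electrostatics with distance-dependent dielectric
  (`hack_elec`), split Lennard-Jones attractive/repulsive
  (`fa_atr`/`fa_rep`), Ramachandran preference (`rama` = Σ −ln p<sub>φψ</sub>)
  and amino-acid-conditional torsion probability (`p_aa_pp` =
  Σ −ln P(aa | φ, ψ)), plus their weighted total.
* **Per-domain statistics.** For every energy term, a normality-gated
  two-group test (Shapiro–Wilk → Welch t or Mann–Whitney U) between the
  native and mirror groups; the energy ratio
  RET = ET̄<sub>native</sub>/ET̄<sub>mirror</sub> (< 1 when native models
  score lower); and the cross-domain *differentiating fraction* of each
  term used for feature selection.
* **Unsupervised separation.** Two-cluster k-means (squared-Euclidean,
  seeded k-means++ restarts) on selected energy terms; the cluster with
  the lower mean energy is labeled *native*; evaluation via ACC, SPC, SN,
  MCC and F1 from the confusion table with native as the positive class.
* **Synthetic benchmark generator.** Deterministic ideal-geometry backbone
  builder (NeRF internal coordinates), mirror reflection, Gaussian
  coordinate noise as the difficulty axis, and simulated energy-feature
  matrices — everything needed to benchmark the method end to end without
  external data.

## Worked example

```r
library(MirrorSort)

# a seeded 6-domain benchmark: ~50% mirror models, 0.5 A coordinate noise
bench <- makeDemoBenchmark(nDomains = 6, nModels = 50, noiseSd = 0.5,
                           seed = 42)

# orientation of one model against its reference
assignOrientation(models(bench$ensembles[[1]])[[1]],
                  referenceModel(bench$ensembles[[1]]))
#> $label
#> [1] "native"
#> $rmsdToReference
#> [1] 0.9150439
#> $rmsdToMirrorReference
#> [1] 3.416915

phiPlusRatio(referenceModel(bench$ensembles[[1]]))                 # 0
phiPlusRatio(mirrorReflect(referenceModel(bench$ensembles[[1]])))  # 1

# the full pipeline: score -> test -> select -> cluster -> evaluate
res <- runPipeline(bench$ensembles, strategy = "common3", seed = 42,
                   grouping = bench$grouping)
round(res$fractions, 2)
#>    fa_atr    fa_rep hack_elec      rama   p_aa_pp     total
#>      0.00      0.00      0.00      1.00      0.83      0.50
res$summary
#>        group n_domains  acc       spc        sn       mcc        f1
#> 1 helix-rich         2 0.64 0.6983083 0.6480938 0.3558309 0.6326776
#> 2      mixed         2 1.00 1.0000000 1.0000000 1.0000000 1.0000000
#> 3 sheet-rich         2 1.00 1.0000000 1.0000000 1.0000000 1.0000000
```

Reading the output: on these ensembles the mirror models are near-exact
reflections plus noise, so only the torsion-based terms differentiate the
two orientation groups (`rama` in 100% of domains, `p_aa_pp` in 83%,
`hack_elec` in none — pairwise distances are reflection-invariant), and
clustering on the common three terms separates the orientations perfectly
wherever β-strands are present. Helix-only folds are the hard case: the
left-handed helix region is allowed rather than outlier, so the energy
gap is smaller.

A shell entry point wrapping the same functions ships in
`inst/scripts/chiralsort`:

```sh
chiralsort synth --ss HHHHHHHHHH --n-models 10 --mirror-fraction 0.5 \
           --seed 7 --output dir/
chiralsort orient --model dir/synthetic_m001.pdb --reference dir/reference.pdb
chiralsort pipeline --input corpus/ --strategy common3 --seed 1 --output out/
```

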