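# elastoage

Brain age modelling from magnetic resonance elastography (MRE) maps.

MRE reconstructs the brain's complex shear modulus `G* = G' + iG''` per
voxel. Two scalar viscoelastic properties summarize it — stiffness
`μ = 2|G*|² / (G' + |G*|)` (kPa) and damping ratio `ξ = G'' / (2G')`
(dimensionless). Both track aging (whole-brain stiffness falls ≈0.33%
per year, damping ratio rises ≈0.34% per year) and neurodegeneration
alters them regionally, which makes them attractive inputs for brain-age
prediction: learn the normative trajectory of healthy brains, then read
disease as a *brain age gap* (BAG) — bias-corrected predicted age minus
chronological age.

This package is a complete, testable implementation of that analysis
for researchers working with (or planning to work with) viscoelastic
brain maps:

- **Synthetic phantom cohorts** (`buildAtlas()`, `cohortSpec()`,
  `generateCohort()`): 3D modulus + anatomical volumes with a 12-region
  atlas, configurable aging rates, regional heterogeneity, disease
  signatures (MCI: damping elevation in hippocampus/brain stem; AD:
  stiffness loss in thalamus/pallidum), written as NIfTI + TSV when a
  directory is given. Every downstream stage is testable without any
  clinical data.
- **Property computation and normalization** (`computeProperties()`,
  `invertProperties()`, `normalizeVolumes()`, `applyCoverageMask()`):
  exact μ/ξ formulas, dataset-level or image-level z-scoring, reusable
  normalization state for held-out subjects.
- **Three model families** behind one fit/`predictAge()` contract:
  PCA + Gaussian-process regression with a linear kernel
  (`fitPcaGp()`), a supervised 3D residual CNN (`fitSupervisedCnn()`),
  and a self-supervised contrastive-regression encoder with adaptive
  age neighbourhoods and a closed-form ridge readout (`fitSsl()`,
  `lossYaware()`, `lossExponential()`, `lossAdaptive()`,
  `selectNeighbours()`). The adaptive loss is

  ```
  L = -Σ_i Σ_{k≠i} (w_ik / Σ_t w_it) ·
      log[ exp(s_ik) / Σ_{t ∈ NN(x_i)\{k}} exp(s_it (1 - w_it)) ]
  ```

  with Gaussian age-kernel weights `w_ik = exp(-(y_i-y_k)²/2σ²)`,
  cosine similarities `s_ik`, and per-anchor neighbourhoods whose size
  shrinks over training.
- **Occlusion saliency** (`occlusionOrigins()`, `deltaMaeGrid()`,
  `postprocessSaliency()`, `saliencyByAgeBin()`): per-age-bin ΔMAE
  occlusion grids (7³ blocks, 13³ = 2197 origins at full scale), cubic
  upsampling, min-max scaling.
- **Cohort analysis** (`fitBias()`, `computeBag()`, `cohortBag()`,
  `regionalProfiles()`, `cohortProfile()`, `flagAtRisk()`,
  `compareGroups()`): leave-cohort-out retraining, Theil-Sen bias
  correction, regional BAG profiles over a fixed 12-region order,
  Pearson-similarity screening of at-risk healthy subjects, and a
  Shapiro-Wilk-gated parametric/non-parametric test dispatch.
- **Pipeline** (`runPipeline()`, `runConfig()`): config-driven
  end-to-end runs with a JSON manifest and deterministic result
  checksums. A thin CLI lives at `inst/scripts/elastoage`.

## Worked example

```r
library(elastoage)

atlas <- buildAtlas(c(24, 24, 24), seed = 0)
atlas
#> PhantomAtlas: 24x24x24 @ 2 mm, 12 regions, 5736 labelled voxels

spec   <- cohortSpec(nHealthy = 40, nAd = 10, seed = 1)
cohort <- generateCohort(spec, atlas)

# healthy-cohort evaluation: fresh 80:20 split and fit per seed
tab <- runProtocol(cohort, families = c("null", "pca_gp"),
                   modalities = "mre", nSeeds = 3)
attr(tab, "summary")
#>   family modality n_seeds   mae_mean mae_mean_sd  mae_median
#> 1   null      mre       3 18.2950229  3.67047383 17.44526485
#> 2 pca_gp      mre       3  0.0873634  0.01610138  0.07976907

# AD brain-age gaps: leave-cohort-out refit on stiffness, Theil-Sen
# correction on matched controls
bag <- cohortBag(cohort, "AD", family = "pca_gp", modality = "stiffness")
aggregate(bag ~ cohort, bag, median)
#>    cohort           bag
#> 1      AD  4.003763e-01
#> 2 control -3.552714e-15
compareGroups(bag$bag[bag$cohort == "AD"], bag$bag[bag$cohort == "control"])
#> StatReport: independent t-test (paired = FALSE), statistic 5.933, p = 1.074e-05
```

Reading the output: the null predictor (training mean age) errs by ~18
years on held-out phantoms while the PCA+GP model tracks the strong
mechanical aging trend almost exactly; the injected AD stiffness lesion
shifts the bias-corrected BAG of patients to a positive median (about
+0.4 yr on this phantom world, where prediction noise is tiny) while
matched controls centre on zero, and the group difference is highly
significant. `regionalProfiles()` + `cohortProfile()` localize the same
effect to the thalamus, and `flagAtRisk()` ranks healthy phantoms by
similarity to the AD profile.

The methods vignette (`vignettes/elastoage-methods.Rmd`) documents the
model assumptions, every tunable parameter with units and defaults, the
generator's fidelity limits, and the numerical design choices.

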