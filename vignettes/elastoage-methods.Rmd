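---
title: "Brain age from viscoelastic maps: models, phantoms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brain age from viscoelastic maps: models, phantoms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

Magnetic resonance elastography (MRE) tracks induced shear waves through
brain tissue and reconstructs the complex shear modulus
$G^* = G' + iG''$ per voxel. Two scalar properties summarize it:

* **stiffness** $\mu = 2|G^*|^2 / (G' + |G^*|)$, in kPa, reflecting
  tissue composition, and
* **damping ratio** $\xi = G'' / (2G')$, dimensionless, reflecting the
  relative viscous energy dissipation.

Both properties change with age — whole-brain stiffness declines at
roughly a third of a percent per year while the damping ratio rises at a
similar rate — and neurodegeneration alters them regionally. `elastoage`
implements a complete brain-age analysis on such maps: phantom cohorts
with controllable aging and disease structure, three model families
behind one train/predict contract, occlusion saliency, Theil–Sen
bias-corrected brain-age gaps (BAGs), regional BAG profiles and
profile-similarity screening. Everything runs CPU-only and is exercised
end-to-end by the test suite on synthetic data.

# The synthetic phantom generator

Clinical MRE collections of this kind are available only under data
sharing agreements, so the package ships a generator whose *statistical
structure* matches what the analysis assumes; it is first-class, tested
code, not a fixture.

**Atlas.** `buildAtlas()` lays out twelve regions — ten subcortical
structures plus grey and white matter — as ellipsoids inside a
brain-shaped ellipsoid, mirrored across the mid-sagittal plane for
paired structures. Region volumes track the relative sizes of
common-space segmentations (cerebellum largest at roughly a tenth of the
brain, thalamus near 1.7%, nucleus accumbens smallest near 0.13%).
Regions are carved large-to-small so small structures survive overlaps.
The default desk grid is $32\times40\times32$ (2 mm voxels); a
$91\times109\times91$ full-geometry option exists for geometry tests.

**Ages.** A two-component uniform mixture, by default
$0.5\,U[18,35] + 0.5\,U[35,90]$, emulates the young-skewed, non-uniform
age profile typical of pooled healthy MRE cohorts. Disease-cohort ages
are drawn from $U[60,85]$, since neurodegenerative cohorts are elderly.

**Mechanics.** Per region $r$,
$\mu_r(a) = \mu_r^0\,(1 + m_r\,\beta_\mu\,(a - a_{\mathrm{ref}}))$ and
analogously for $\xi$, with defaults $\beta_\mu = -0.33\%/yr$,
$\beta_\xi = +0.34\%/yr$, $a_{\mathrm{ref}} = 45$ yr, and per-region
baselines in the 2.3–3.2 kPa (stiffness) and 0.22–0.28 (damping) ranges
— literature-plausible values that remain fully configurable because no
per-region baselines are pinned down by the analysis itself. Disease
signatures are additive fractional offsets: MCI raises damping in the
hippocampus (+10%) and brain stem (+8%), AD lowers stiffness in the
thalamus (−15%) and pallidum (−8%). The hippocampus/brain-stem offsets
are deliberately ordered so the strongest MCI elevation sits in the
hippocampus.

Voxel noise is Gaussian, scaled by the regional baseline (default 5%),
and the *noise field* is smoothed with a 1-voxel Gaussian kernel so maps
have the spatial autocorrelation of reconstructed MRE; smoothing the
noise rather than the signal keeps the regional means exact, which is
what makes the generator's closed forms testable (with zero noise the
whole-brain mean is exactly affine in age, and
`computeProperties(generateSubjectMaps(...))` returns the target fields
to floating-point precision).

Maps are emitted as $(G', G'')$ pairs through the algebraic inverse
$G' = \mu(1+\sqrt{1+4\xi^2})/(2(1+4\xi^2))$, $G'' = 2\xi G'$, so every
phantom exercises the forward property computation.

**Anatomical channel.** A monotone transform of the labels plus noise,
with a weak age-dependent grey/white contrast (default ±0.033%/yr with
opposite signs in GM and WM). The age effect is a *within-image
contrast* on purpose: anatomical images are normalized per image, which
removes any global intensity trend, so a purely global age effect would
leave the channel with no learnable signal at all. What the generator
does **not** emulate: displacement fields and their inversion, scanner
or sequence effects, registration error, cortical folding, atrophy-
driven shape change. Passing tests therefore demonstrate that the
pipeline recovers the signal structure it assumes, not that it matches
clinical effect sizes.

**Matched controls.** The generator labels the oldest healthy subjects
as matched controls for each disease cohort (`control_for` column),
mirroring the leave-cohort-out study structure in which a held-out
healthy subset anchors the bias correction.

# Preprocessing and normalization

`normalizeVolumes()` supports two modes behind one switch:

* **dataset** (default): one location/scale pair per channel pooled over
  the fitting subjects. Global aging trends survive, which is what makes
  whole-brain models so strong on these maps.
* **image**: each volume z-scored independently, removing global levels
  and leaving spatial contrast only — the variant used to study spatial
  aging effects.

The state is fitted on the *training split only* and then applied to
held-out and disease subjects. Literal whole-dataset fitting can be
reproduced by preparing all subjects in one call; the default avoids
leakage. Out-of-mask voxels are set to 0 *after* normalization, so the
occlusion fill value of 0 coincides with background. The anatomical
channel is masked to the mechanical coverage before its per-image
normalization.

# The three model families

All families implement fit + `predictAge()`, are seeded and
deterministic on CPU, and never use disease subjects in training.

**PCA + Gaussian process.** Masked voxels (channels concatenated) are
reduced to $k$ components; an exact GP with linear kernel
$K = \sigma_f^2 S S^\top + \sigma_n^2 I$ is fitted on the scores. The
two variances are optimized by 50 Adam steps on the log marginal
likelihood — the natural reading of "training a GP for epochs" — with
fresh Gaussian augmentation noise per step. The noise is added to the
scores: projecting i.i.d. voxel noise through an orthonormal PCA basis
gives exactly i.i.d. noise of the same variance on the scores, so this
is an exact algebraic shortcut, not an approximation.

**Supervised 3D CNN.** A residual encoder in the ResNet-18 mould:
stride-2 stem convolution, four stages of residual blocks with
projection shortcuts, channels $[16,32,64,128]$ at full scale, ReLU
throughout, global average pooling, a linear latent head (256 at full
scale) and a 256→64→1 regression MLP, trained with the L1 loss, Adam,
stepwise learning-rate decay (×0.9 every 10 epochs), in-mask Gaussian
input augmentation, dropout on pooled features and weight decay. The
network, its backpropagation and Adam are a compact CPU implementation
(Rcpp/Armadillo im2col + GEMM convolutions); there is no batch
normalization, so determinism is exact and the desk-scale nets train
stably with He initialization. Targets are centered on the training
mean age and the final layer starts at zero, so the untrained model
predicts the mean age and learning only ever moves it away from that
baseline.

**Self-supervised contrastive encoder + ridge readout.** The same
encoder produces L2-normalized embeddings trained with the
adaptive-neighbourhood contrastive regression loss (below); after
training, the encoder is frozen and a closed-form ridge readout
($\alpha = 1$ by default) maps embeddings to age. Embeddings are kept
on the unit sphere for the readout — the same space the loss shaped.

## The contrastive losses

With unit embeddings $f_i$, cosine similarities $s_{ik}$ and Gaussian
age-kernel weights $w_{ik} = \exp(-(y_i-y_k)^2/2\sigma^2)$:

* **y-aware**:
  $L = -\sum_i \sum_{k\neq i} w_{ik}\,
  \log \exp(s_{ik}) / \sum_{t\notin\{i,k\}} \exp(s_{it})$.
* **exponential scaling**: denominator terms become
  $\exp(s_{it}(1-w_{it}))$, strengthening repulsion of age-distant
  samples.
* **adaptive neighbourhoods**: weights are normalized per anchor
  ($w_{ik}/\sum_t w_{it}$) and the denominator runs over
  $NN(x_i)\setminus\{k\}$, a per-anchor set of nearest samples in
  embedding space whose size shrinks over training:
  $|NN| = \mathrm{clamp}(start - step\cdot epoch,\; end,\; start)$ with
  $start = n-1$.

Three typographic ambiguities in the printed forms were resolved as
explicit design choices: (i) self-similarity terms $\exp(s_{ii}) = e$
are excluded from every denominator — they are constants that distort
the softmax; (ii) the scaled exponent reads $\exp(s(1-w))$, i.e.
$\exp(s)^{1-w}$, the algebra that matches the exponential-scaling idea;
(iii) the adaptive weight normalization divides by
$\sum_{t\neq i} w_{it}$ per anchor, making the loss invariant to a
common rescaling of the kernel. With full neighbourhoods the adaptive
loss reduces exactly to the anchor-normalized exponential loss, and all
three are verified against scalar-loop brute-force enumeration and
finite-difference gradient checks in the tests. Neighbour sets are
recomputed per batch from the current embeddings; pairs whose effective
denominator empties are skipped with a warning rather than producing
$-\infty$.

The kernel bandwidth $\sigma$ is not fixed by the analysis being
reproduced; the default is 2 years, configurable and stored on the
model. A learning-rate phrase in the source material that ties decay to
"degrees of positiveness" is internally inconsistent and is implemented
as plain stepwise decay.

## Hyperparameter presets

`modalityPreset()` ships the published best configurations per family
and modality (e.g. SSL on two-channel MRE: Manhattan distance, weight
decay $5\times10^{-5}$, noise 0.1, neighbourhood step 5, end count 9).
Hyperparameter search itself is out of scope. The desk-scale profile
(`deskEncoderConfig()`, `deskTrainConfig()`: channels $[4,8,16,32]$,
embedding 32, one block per stage, 30 epochs, batch 16, learning rate
$10^{-3}$) exists so the full pipeline runs in minutes on one CPU; the
learning rate is larger than the full-scale preset because the short
schedule gives few gradient steps.

# Evaluation protocol

`runProtocol()` runs, for every (family, modality, seed): a fresh
deterministic 80:20 split of the healthy cohort, normalization fitted on
the training split, a fresh fit, and test-set errors. Both expansions of
"MAE" — mean and median absolute error — are always reported, because
both appear in the literature this mirrors and the text does not
disambiguate which backs each printed value; neither is asserted against
printed numbers. The `"null"` family (predict the training mean age) is
the reference point for signal-recovery checks. Single fit failures are
recorded in the results table and the protocol continues.

# Occlusion saliency

Test subjects are split into quantile age bins (5 by default). For each
block origin, a $7^3$ block (default) is zeroed in every subject, ages
are re-predicted, and $\Delta$MAE = MAE(occluded) − MAE(original) is
recorded. The printed full-scale geometry (block 7, 9 superior slices
excluded, $13^3 = 2197$ origins on a $91\times109\times91$ grid) is
arithmetically inconsistent on the 109-voxel axis and on the excluded
axis; the resolution here fixes 13 positions per axis with rounded
linear spacing over each admissible extent, which reproduces exact
stride-7 tiling on clean 91-voxel axes while covering the full volume.
Blocks are independent; overlaps are not averaged. Post-processing
clips at the 5th/95th percentiles, upsamples with separable Keys cubic
interpolation ($a=-0.5$, edge clamping), zero-pads the excluded slab
and min-max scales to $[0,1]$. A constant grid has no contrast and maps
to all zeros with a warning. $\Delta$MAE uses the mean-absolute variant.

# Brain-age gaps, regional profiles, screening

For a disease cohort, models are retrained on healthy subjects minus
that cohort's matched controls; the controls anchor a Theil–Sen fit of
predicted on chronological age (slope = median of pairwise slopes over
distinct-age pairs, intercept = median residual — robust to outlying
predictions, verified against a brute-force oracle). Then
$BAG_i = \hat y_i - (\beta_0 + \beta_1 a_i)$ and the corrected
prediction is $a_i + BAG_i$, so any affine prediction rule yields
exactly zero BAGs. Regional profiles repeat the whole procedure with
volumes masked to one region at a time (fixed 12-region order, skipped
regions recorded, never silently dropped), and cohort profiles are
entrywise means.

At-risk screening compares each healthy control's regional profile to a
cohort mean profile by Pearson correlation — the similarity metric is a
declared design choice (the source material shows examples but names no
metric), with a configurable threshold defaulting to 0.7.
Zero-variance profiles have undefined correlation and are excluded with
a warning.

Two-group comparisons gate on Shapiro–Wilk normality (p > 0.05 in both
groups → t-test, paired or independent; otherwise Wilcoxon signed-rank
or Mann–Whitney U). The significance level is fixed at 0.05 and no
multiple-testing correction is applied across regions — a deliberate
mirror of the annotation convention being reproduced, and a limitation
for any confirmatory use.

# Numerical choices and degenerate inputs

* Modulus inversion round-trips to better than $10^{-10}$; tests pin
  this.
* Normalization refuses zero-variance channels by name; a supplied
  state is applied verbatim, never refitted.
* The GP falls back gracefully if a Cholesky step fails during variance
  optimization (the last valid parameters are kept).
* Quantile age bins merge with a warning when ties would empty a bin;
  neighbour selection breaks ties by index order.
* Embedding norms are guarded by $10^{-12}$ before division.
* Clipping keeps generated $\mu > 0$ and $\xi \in (0,1)$ with a warning
  when parameters drive values out of range at extreme ages.

# Problem sizes

Desk-scale defaults throughout the tests and the acceptance script:
$24^3$–$32\times40\times32$ grids, cohorts of 40–60 healthy subjects
plus 10–15 per disease group, compact encoders, 30 epochs, three to ten
seeds per experiment. These sizes were chosen so a complete run of
every stage finishes in minutes on a single CPU while leaving all
qualitative contrasts (model-family ordering, mechanical > anatomical,
disease detection, regional peaks) comfortably resolvable.

# Known limitations

* Phantoms are piecewise-constant ellipsoid worlds; nothing about
  cortical geometry, registration error or scanner variability is
  modelled, so clinical effect sizes and printed errors from real
  cohorts are out of reach by construction.
* The anatomical channel's age information is a single global contrast
  dial; real T1 images carry far richer structure, so
  anatomical-vs-mechanical comparisons here are directional only.
* The CNN implementation is compact and CPU-bound; full-scale
  ($91\times109\times91$, channels $[16,32,64,128]$, 50 epochs)
  training is supported in code but not routinely exercised.
* Whole-brain BAG shifts from a focal stiffness lesion scale with the
  lesioned fraction of the brain; they are intrinsically fractions of a
  year on phantoms, unlike the multi-year gaps seen in clinical
  cohorts, and detection therefore leans on the low prediction noise of
  the phantom world.
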