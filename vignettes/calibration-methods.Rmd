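---
title: "Calibrating grape texture and soluble solids from NIR spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating grape texture and soluble solids from NIR spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirtex)
```

## The problem

Instrumental texture analysis of table grape is destructive and requires a
time-consuming densimetric sorting of the berries beforehand. NIR
diffuse-reflectance spectroscopy offers a fast, non-destructive alternative:
a berry's spectrum over 12,000–4000 cm⁻¹ carries overtone and combination
bands of its water, sugar, organic-acid and pectin content, and those
constituents co-vary with ripeness and mechanical properties. `nirtex`
implements the full calibration workflow that turns a table of berry spectra
plus laboratory reference values (texture-profile parameters and total
soluble solids) into validated regression models:

1. replicate (berry-face) spectra are averaged;
2. the spectra are pre-treated (SNV and/or mean centering; Savitzky–Golay
   smoothing and derivatives are available but are screened against
   design-discrimination, see below);
3. outliers are removed by a Mahalanobis screen on PCA scores and by
   chi-square critical limits on PLS score/orthogonal distances;
4. the data are split 80/20 by the Kennard–Stone maximin algorithm;
5. wavelengths are selected either by Monte Carlo uninformative variable
   elimination (MC-UVE) or by statistically significant peaks/valleys of
   the PLS β-coefficient curve (jack-knife inference);
6. three models are fitted per response — full-spectrum SIMPLS PLS,
   reduced-spectrum PLS, and a small feed-forward neural network on the
   selected (optionally diameter-augmented) predictors;
7. performance is reported as R², RMSE, bias, SEP and RPD on a
   cross-validated training set and an untouched external test set.

Because no public berry dataset accompanies this workflow, the package
ships a synthetic-data module that generates berry populations and spectra
with the statistical structure the analysis assumes; every stage of the
pipeline is exercised and tested against it.

## The synthetic study

`study_design()` encodes the sampling layout: 3 vineyard blocks × 3 bags ×
30 analyzed berries, 3 spectra per berry (different berry faces), i.e. 270
berries and 810 face-level spectra on the 1001-point instrument grid
(12,000–4000 cm⁻¹ at 8 cm⁻¹, stored descending as FT-NIR instruments
report it). Berries are drawn from three densimetric classes (1.02, 1.04,
1.06 g/mL, equal weights) — flotation sorting is emulated only as this
latent label.

The latent link (`link_spec()`) maps a berry's density and equatorial
diameter to its reference values:

* **TSS** (°Brix) is linear in density with Gaussian noise (SD 0.5 °Brix);
  soluble solids are, to first order, what flotation density measures.
  Defaults give a 12–21 °Brix range.
* **Hardness** (BH, N) and **springiness** (BS, mm) decrease with ripeness
  through a saturating logistic in density plus a diameter term;
  springiness additionally carries a diameter × ripeness interaction.
  These links are deliberately *smoothly nonlinear*: a linear model on the
  spectra (which encode density nearly linearly) underfits them, so a
  nonlinear regressor has genuine headroom — the property the network is
  tested against.
* **Cohesiveness** (BCo) is drawn at mean 0.24, SD 0.03, essentially
  decoupled from anything visible in the spectra. Its small variability is
  itself part of the study conditions: no model should be able to predict
  it, and the test suite asserts that failure.
* **Gumminess** and **chewiness** are the exact TPA identities
  BG = BH·BCo and BCh = BH·BCo·BS. Gumminess is generated but never
  modeled (it is mutually exclusive with chewiness for a solid food).

Spectra are Beer–Lambert mixtures: each chemical component contributes
Gaussian bands (`band_library()`, centers at the classic assignments —
10,526, 6896, 6849 and 5128 cm⁻¹ for water; 8333, 5917, 5714, 4424 and
4344 cm⁻¹ for sugars; 10,101 cm⁻¹ for organic acids; broad
combination-region bands for pectins). Concentrations follow the latents:
sugars track TSS, water opposes sugars, acids decline with ripeness,
pectins track hardness, and a mild diameter-dependent path-length gain
scales the whole spectrum. The noise model distorts each face with a
multiplicative gain (SD 0.05), an additive offset (SD 0.02), a linear
baseline (SD 0.01), white noise (SD 0.003), a per-face concentration
jitter (SD 0.01, berry inhomogeneity) and an optional per-block additive
offset (SD 0.004 by default) that emulates a field/batch effect.

What the generator does **not** emulate: real diffuse-reflectance physics
(no radiative transfer, no wavelength-dependent scatter), instrument drift
over measurement days, correlated (pink) noise, or reference-method error
in the texture analyzer itself. Passing tests therefore demonstrate that
the pipeline recovers structure *of the kind it assumes*; they are not
evidence about any particular instrument or cultivar.

## Model and inference details

**SIMPLS.** Single-response SIMPLS computes weight vectors from the
successively deflated covariance vector s = X′y, giving orthonormal scores
without deflating X. Coefficients are nested in the component count, which
makes leave-one-out component selection cheap: the model is refitted n
times at the maximal component count and every smaller count is evaluated
from the same refit. The selected count minimizes RMSECV (first minimum on
ties). If the deflated covariance collapses numerically (norm below
1e-12 relative), the fit truncates with a warning rather than fabricating
components.

**Jack-knife inference.** Delete-one segments by default (configurable to
k segments, split contiguously); the Tukey jack-knife variance across
segment estimates gives per-coefficient SEs, t statistics with
df = segments − 1, and two-sided p-values. A degenerate SE of zero maps to
p = 0 for a nonzero coefficient and p = 1 for a zero one.

**Wavelength selection.** The β-coefficient rule keeps predictors that are
(a) significant at p < 0.05 and (b) on a strict local extremum of the
coefficient curve over the wavenumber grid (plateaus keep their leftmost
index); a top-quantile |β| alternative is available. MC-UVE fits 500
(configurable) subsample models at 80 % of the rows and scores each
predictor by stability = mean/SD of its coefficient across fits; the
cutoff is the 99th percentile of |stability| over appended
negligible-amplitude artificial noise columns, the classical
noise-augmentation rule. If no predictor passes the β rule, the pipeline
logs the condition and continues with the full spectrum so the remaining
models still run — the situation arises precisely for responses (like
cohesiveness) that the spectra cannot explain. Selection can only shrink
the predictor set, and the appended diameter column never participates in
selection.

**Outlier screens.** PCA (SVD, deterministic sign fix) on the pre-treated
spectra; the Mahalanobis screen uses the smallest number of components
reaching 95 % cumulative variance and flags at χ²(k) with α = 0.025. The
PLS residual screen models the score distance h and orthogonal distance q
each as u₀·χ²_N/N. The robust variant matches N by the IQR/median ratio of
a scaled χ² (N searched over 1…200) and sets u₀ = median·N/χ²₀.₅(N); the
data-driven variant uses moments (u₀ = mean, N = round(2·mean²/var)).
Removal is one-shot at the outlier level α = 0.01 (α = 0.05 marks
extremes only); the union of the two screens is removed and logged. After
removal the final model's data-driven limits are reported for reference.

**Kennard–Stone.** Classical greedy maximin on Euclidean distances over
min-max-normalized spectra: the extreme pair first, then the sample
maximizing its minimum distance to the selected set; ties resolve to the
lowest original index, so duplicates are never picked while distinct
geometry remains. The training fraction is 0.8.

**Scaling and leakage.** All modeling constants — pre-treatment constants
(MSC reference, column means), min-max ranges, selection, component counts
— are learned on training rows only and re-applied frozen to the test set;
a test-row perturbation audit in the test suite asserts this. Two stages
necessarily see all samples: the outlier screens (they precede the split,
as in any calibration-transfer workflow) and the distance metric of the
Kennard–Stone split itself. A `scaler_fit = "all"` switch reproduces the
variant that normalizes before splitting, at the cost of leaking test
ranges into the scaler.

**The network.** For n selected predictors the architecture is
n+1 : ⌈(n+1)/2⌉ : 1 with ReLU on the two inner layers and a linear output;
He-normal initialization (SD = √(2/fan_in)); L1 penalty (λ = 1e-4 by
default) on the two inner weight matrices; Adam (lr 1e-3, β₁ 0.9,
β₂ 0.999) on the mean squared error with MAE monitored; batch size 32; a
seeded 0.2 validation split of the training rows; weights of the best
validation-loss epoch are restored after training. The "+1" input unit is
realized as an appended constant-1 column (`plus_one = "constant"`), so
the literal width rule holds; `plus_one = "none"` keeps the n inputs and
applies the rule to the layer widths only. The hidden width rounds up
(⌈·⌉) because n+1 is usually odd. All stochastic stages (initialization,
split, batch order) derive from one seed; training is single-threaded and
bit-reproducible. Dead-ReLU collapse can occur for toy networks with one
or two hidden units; at the widths the pipeline actually uses (n ≥ 100)
it has not been observed across the seed suites.

**Metrics.** bias = mean(pred − ref); RMSE = √mean((pred − ref)²);
SEP = sample SD of the residuals, so RMSE² = SEP²(n−1)/n + bias² exactly;
R² = 1 − SSE/SST (the squared Pearson correlation is reported alongside);
RPD = SD(reference)/SEP, the conventional direction, under which RPD > 2
marks a quantitatively useful calibration. For a constant prediction at
the reference mean, direct evaluation of these definitions gives R² = 0
and RPD = 1. PLS "training with CV" rows report leave-one-out predictions;
the network's training row reports its inner-validation predictions (the
external test set is never touched during training either way), and the
two are labeled identically but are not the same quantity.

## Pre-treatment screening

`select_pretreatment()` ranks candidate chains by the cumulative variance
of the first two PCA components but discards chains whose first two score
dimensions separate the design blocks (mean silhouette of the block
labels > 0.25): a pre-treatment that reconstructs the field layout would
calibrate the design, not the chemistry. On the generator, smoothing-only
chains retain per-block offsets and get flagged once block effects are
switched up, while SNV removes them — the behavior the screening rule
exists to catch. The per-response defaults are pinned: SNV + mean
centering for TSS, springiness, chewiness and cohesiveness; mean centering
alone for hardness.

## Problem sizes and runtimes

The test suite runs the pipeline at two scales, chosen as the package's
own desk-scale conditions: a `tiny` fixture (2 × 2 × 6 berries, 2 faces,
101-point grid) for end-to-end and property tests, and the full
`full_scale` study (270 berries, 810 spectra, 1001 points) for the
acceptance checks. Network suites train 200 epochs — enough for the
best-validation checkpoint to stabilize at these problem sizes — while
1000 epochs remains the interactive default. Seed suites use 10
replicates; statistical acceptance bounds (e.g. the network beating both
PLS models on springiness in ≥ 8/10 seeds) are evaluated at those
conditions.

## Known limitations

* Single-response PLS1 only; multi-response SIMPLS is out of scope.
* No EMSC, detrending, OSC, CARS or genetic-algorithm selection.
* The robust-limit quantile-matching constants are an implementation
  choice within the median/IQR family; other chi-square matchings differ
  in the third decimal of the limits.
* The generator's block effect is a flat spectral offset; real block
  effects can be wavelength-dependent.
* JCAMP-DX import is deferred; wide CSV is the only on-disk format.
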