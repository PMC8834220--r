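# nirtex

Chemometrics pipeline for calibrating NIR diffuse-reflectance spectra of
intact table-grape berries against texture-profile-analysis (TPA)
parameters — hardness (BH, N), springiness (BS, mm), cohesiveness (BCo),
chewiness (BCh, mJ) — and total soluble solids (TSS, °Brix).

Instrumental texture analysis destroys the berry and requires densimetric
sorting beforehand. A calibration on NIR spectra (12,000–4000 cm⁻¹, where
O–H and C–H overtone/combination bands of water, sugars, acids and pectins
absorb) predicts these quality parameters non-destructively from a single
scan. `nirtex` is for spectroscopists and postharvest researchers who want
that workflow as tested, composable R functions rather than a one-off
script.

## What is inside

* **Pre-treatments** — SNV, MSC, Savitzky–Golay smoothing/derivatives,
  mean centering, min–max scaling, as train/apply transforms whose
  constants are learned on training rows only; a screening step ranks
  candidate chains by PCA cumulative variance and discards chains that
  discriminate the experimental-design blocks.
* **Outlier removal** — Mahalanobis distances on PCA scores, and
  chi-square critical limits (robust median/IQR or moment-based
  data-driven) on PLS score distance *h* and orthogonal distance *q*,
  each modeled as u₀·χ²_N/N.
* **SIMPLS PLS1** — weights from the deflated covariance vector s = X′y,
  orthonormal scores, nested coefficients; leave-one-out RMSECV component
  selection; delete-one (or k-segment) jack-knife SEs, t statistics and
  p-values for the β coefficients.
* **Wavelength selection** — MC-UVE (stability = mean/SD of subsample
  coefficients, noise-augmentation cutoff) and significant β-coefficient
  peaks/valleys (p < 0.05 and a strict local extremum of the β curve);
  optional augmentation with the berry's equatorial diameter.
* **A feed-forward network** — n+1 : ⌈(n+1)/2⌉ : 1, ReLU, He-normal
  initialization, L1 on the inner layers, Adam on the MSE with MAE
  monitoring, batch 32, seeded 0.2 validation split with best-epoch
  restore.
* **Evaluation** — Kennard–Stone 80/20 maximin split;
  R² = 1 − SSE/SST, RMSE, bias, SEP and RPD = SD(ref)/SEP per model and
  evaluation set.
* **A synthetic-data module** — generates the full berry study (3 blocks ×
  3 bags × 30 berries × 3 berry faces on the 1001-point instrument grid)
  from a latent density/diameter model with Beer–Lambert band mixing, the
  exact TPA identities BG = BH·BCo and BCh = BH·BCo·BS, and a configurable
  noise model, so every stage is testable without instrument data.

All user-facing functions take and return tibbles (spectra travel as wide
tables: `sample_id`, metadata, one column per wavenumber) and compose with
the pipe; fitted objects have `tidy()`/`glance()` methods and
`autoplot()`s.

## Worked example

```r
library(nirtex)

fx  <- make_fixture("full_scale", seed = 11)   # 270 berries, 810 spectra
run <- run_calibration(fx$spectra, fx$berries,
                       pipeline_config("BS", ann_epochs = 200, seed = 11))
run
#> Calibration run for BS (snv+mean_center)
#> samples: 810 -> 270 -> 247 -> 198 -> 49 (raw_spectra -> after_averaging -> after_outlier_removal -> train -> test)
#> selected predictors: 205
#>         model      set ncomp r.squared   rmse      bias  rpd
#>      pls_full train_cv     3     0.889 0.0773  7.93e-05 3.00
#>      pls_full external     3     0.806 0.0992 -1.69e-02 2.30
#>  pls_selected train_cv     6     0.900 0.0732  1.05e-03 3.17
#>  pls_selected external     6     0.753 0.1118 -2.03e-02 2.05
#>           ann train_cv    NA     0.914 0.0633  1.72e-03 3.40
#>           ann external    NA     0.886 0.0760  2.75e-03 2.96
```

Reading the report: 810 face-level spectra were averaged to 270 berries;
23 berries were removed by the outlier screens; Kennard–Stone put 198 in
training and 49 in the external test set. β-selection kept 205 wavenumbers
(the equatorial diameter is appended afterwards as one more predictor). Springiness in this synthetic population is
a nonlinear function of ripeness and berry size, and the network's
external R² (0.886) and RPD (2.96) beat both PLS models (0.806/0.753) —
an RPD above 2 is the usual bar for a quantitatively useful calibration.
`run$metrics` is a tibble; `run$selection`, `run$outliers`, `run$counts`
and the fitted objects in `run$fits` expose every intermediate.
`autoplot(run)`, `autoplot(run$fits$pls_full, run$selection)` and
`autoplot(run$fits$ann)` plot the summary metrics, the β-coefficient
curve with selected wavenumbers, and the training history.

Single pieces work standalone:

```r
round(nm_to_wn(950))          # 10526 cm^-1, the 950 nm water band
sp   <- read_spectra("spectra.csv") |> average_replicates("berry_id") |> snv()
spl  <- kennard_stone(spectra_matrix(sp), fraction = 0.8)
fit  <- fit_simpls(X, y, ncomp = 7)
jk   <- jackknife_beta(X, y, ncomp = 7)
tidy(fit, jackknife = jk)
```

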