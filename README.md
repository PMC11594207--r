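# hsichemo

Chemometrics for visible/near-infrared hyperspectral imaging of fruit:
predicting internal quality traits (soluble solids content in %, potassium
in mg/100 g) and discriminating geographic origin from 400–1000 nm
reflectance spectra.

The package implements the full analysis chain used in fruit-quality
hyperspectral studies, for people who want a tested, scriptable R
counterpart to the usual ENVI/Unscrambler/MATLAB workflow:

* **ENVI cube handling** — read/write BSQ/BIL/BIP cubes, dark/white
  reflectance calibration `R = (I − I_dark)/(I_white − I_dark)`, ROI mean
  spectra, closed-interval wavelength trimming.
* **Pretreatments** — absorbance conversion `A = log10(1/R)`, MSC, SNV,
  Savitzky–Golay smoothing and 1st/2nd derivatives, mean centering, as
  declarative pipelines with a provenance log.
* **SPXY partitioning** — Kennard–Stone sample selection on the joint
  max-normalized X–y distance, `d_xy = d_x/max(d_x) + d_y/max(d_y)`.
* **Models** — NIPALS PLS1 regression and PLS-DA / random-forest
  classification, latent-variable count chosen by venetian-blind k-fold
  cross-validation; metrics `R² = 1 − SS_res/SS_tot`, RMSE, % accuracy.
* **Wavelength selection** — CARS (Monte-Carlo row sampling, exponential
  forced-deletion schedule `r_i = a·e^(−k·i)`, adaptive reweighted sampling,
  RMSECV minimization) and random frog (stochastic subset walk; a band's
  importance is its containment frequency, threshold 0.1).
* **Synthetic data** — a seeded generator of banana-like spectra with
  planted analyte bands (SSC near 840.3 nm, potassium near 641.51 nm,
  chlorophyll ~680 nm, water ~960 nm), multiplicative scatter, baseline and
  noise, plus ground truth, so selection and regression can be validated
  against known answers.

Everything is tidyverse-native: datasets are wide tibbles, results come
back as tibbles with `tidy()`/`glance()` methods, and traces have
`autoplot()` methods.

## A worked example

Simulate 99 samples on a 60-band grid, take the second derivative, select
bands with CARS on the calibration set only, and fit a PLS model:

```r
library(hsichemo)

sim <- generate_spectra_dataset(scaled_synthetic_config(seed = 1))
cfg <- experiment_config(
  target = "ssc",
  pretreatment = list("to_absorbance",
                      list(fn = "sg_filter", window = 5, polyorder = 3,
                           deriv = 2)),
  selector = "cars",
  selector_config = cars_config(n_runs = 100, cv_folds = 10, max_lv = 5,
                                seed = 201),
  max_lv = 10, cv_folds = 10, seed = 1)
rep <- run_quantitative(sim$dataset, cfg)
rep
#> # Experiment: custom-CARS-PLS
#> # A tibble: 2 × 6
#>   component method          set             n    r2  rmse
#>   <chr>     <chr>           <chr>       <int> <dbl> <dbl>
#> 1 ssc       custom-CARS-PLS calibration    66 0.933 0.568
#> 2 ssc       custom-CARS-PLS prediction     33 0.860 0.740
rep$selection
#> # CARS trace: 100 runs, best run 6, 8 of 60 bands selected (13.33%)
```

Calibration R² 0.93 / prediction R² 0.86 with an RMSE of 0.74 %-SSC from 8
of 60 bands: the selector found the planted 840.3 nm region and discarded
the rest. `autoplot(rep$selection)` shows the kept-count and RMSECV traces;
`make_report()` aligns many such runs into a pretreatment × selector ×
model comparison table. `run_discrimination()` does the same for origin
classification with PLS-DA or a random forest, and
`inst/scripts/run_experiment.R` wraps the pipeline for shell use.

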