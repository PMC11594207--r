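---
title: "Hyperspectral chemometrics for fruit quality: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hyperspectral chemometrics for fruit quality: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsichemo)
```

## The problem

Visible/near-infrared hyperspectral imaging (400–1000 nm) can estimate
internal quality traits of intact fruit — soluble solids content (SSC, in
percent/Brix) and mineral content such as potassium (mg/100 g) — and
discriminate geographic origin, without destroying the sample. The analysis
chain is standard chemometrics:

1. **Reflectance calibration.** Raw counts are corrected with dark and white
   references, $R = (I - I_{dark})/(I_{white} - I_{dark})$, per pixel and band.
2. **ROI mean spectra.** One average spectrum per fruit over a region of
   interest; bands trimmed to the closed 400–1000 nm window.
3. **Pretreatment.** Apparent absorbance $A = \log_{10}(1/R)$, followed by
   one of: multiplicative scatter correction (MSC), standard normal variate
   (SNV), Savitzky–Golay smoothing or first/second derivatives, or mean
   centering.
4. **SPXY partitioning.** Kennard–Stone selection on the joint normalized
   X–y distance splits samples 2:1 into calibration and prediction sets.
5. **Wavelength selection.** Competitive adaptive reweighted sampling (CARS)
   or random frog screens the p bands for the informative few.
6. **Modeling.** NIPALS partial least squares (PLS1) for regression, PLS-DA
   or a random forest for origin classification, with the latent-variable
   (LV) count chosen by venetian-blind cross-validation.
7. **Evaluation.** $R^2 = 1 - SS_{res}/SS_{tot}$ (not a squared
   correlation) and RMSE per set; percent accuracy for classification.

Because real banana spectra of this kind are not publicly deposited, the
package ships a synthetic generator with *known* ground truth, so that every
stage — including the selectors — can be validated quantitatively.

## The synthetic generator

`generate_spectra_dataset()` draws, per sample, SSC uniformly from
15.23–23.23 % and potassium from 80–200 mg/100 g (the descriptive ranges
reported for commercial bananas), an origin class (imported with probability
59/99), and builds a Beer–Lambert-style absorbance

$$A_i(\lambda) = \sum_c a_c\, s_{ic}\, e^{-(\lambda-\mu_c)^2/2w_c^2}
  + b_0 + b_1(\lambda - 400)
  + \delta\,\mathbf 1[800 \le \lambda \le 850]\,\mathbf 1[i\ \text{imported}]$$

with components at 840.3 nm (SSC-linked), 641.51 nm (potassium-linked),
680 nm (chlorophyll) and 960 nm (water). Concentrations are min–max scaled
to $[0,1]$ before multiplying their amplitude, so signal-to-noise is set by
the amplitude and `noise_sd` alone. The observed spectrum is
$m_i A_i(\lambda) + \varepsilon$, with multiplicative scatter
$m_i \sim N(1, 0.05)$ and additive noise
$\varepsilon \sim N(0, 0.002)$ AU per band, stored as reflectance
$R = 10^{-A}$. *This is exactly the distortion family MSC, SNV and
derivatives are designed to remove, which makes every pretreatment
testable.*

Ground truth records the bands within one peak width of each analyte centre
(selection methods recover regions, not single channels); on grids too
coarse for any band to fall inside the peak, the nearest band is used.

**Amplitude calibration.** The default analyte amplitudes (SSC 0.08, K 0.06
AU) against dominant nuisance components (chlorophyll 0.35, water 0.45 AU)
were fixed once so that (i) the absorbance at the band nearest 840.3 nm
correlates with SSC at roughly $r \approx 0.85$ and (ii) full-band PLS
prediction $R^2$ on default data exceeds 0.9 — a realistic fruit-calibration
regime. Early drafts with 0.4 AU analyte peaks gave $R^2_p \approx 0.99$,
which no VIS/NIR fruit calibration achieves and which leaves wavelength
selection nothing to improve.

**What the generator does not emulate:** instrument point-spread functions,
wavelength-correlated (pink) noise, nonlinear detector response, peel/pulp
light-transport effects, and any real covariance between SSC, potassium and
origin. Passing tests therefore demonstrate correctness of the algorithms
under a Beer–Lambert mixture model, not field performance on real fruit.

`generate_cube()` plants one generated spectrum in an elliptical foreground
of a raw-count cube together with consistent dark/white frames, so the ENVI
I/O and calibration path can be tested end to end: with zero noise,
`calibrate()` recovers the planted reflectance to 1e-10.

## The scaled-down benchmark

Method-validation experiments use `scaled_synthetic_config()`: 99 samples on
a 60-band grid with analyte amplitudes halved (SSC 0.04, K 0.03 AU). On this
grid full-band PLS lands at $R^2_p \approx 0.8$–0.93 — the difficulty regime
typical of published banana SSC/K calibrations — leaving measurable headroom
for the selectors. Problem sizes (p = 60, 10 replicate seeds, 1000–1500
selector iterations) keep a full validation run in a few minutes.

Hyperparameters for this grid, fixed once and used everywhere:

* **Second derivative, window 5, polyorder 3.** At 10.2 nm band spacing a
  5-point window spans ~50 nm, about one FWHM of the planted 20 nm-sd
  analyte peaks; the 15-point default matches the same physical width on the
  225-band grid. A wider window smears the derivative signal across
  neighbouring regions and decouples selected bands from the planted ones.
* **CARS: 100 runs, 10-fold CV, `max_lv` 5; frog: `n_lv` 3.** The simulation
  has ~4 latent spectral factors (two analytes, two nuisance components,
  plus scatter); LV caps of this order keep the coefficient ranking inside
  the selectors well-conditioned. The 10/15-LV settings used for real
  225-band fruit data overfit the coefficient vector at p = 60 and n = 66,
  ranking noise bands above planted ones.

## Numerical and algorithmic choices

* **Absorbance conversion** floors reflectance at 1e-6 before
  $\log_{10}(1/R)$.
* **SNV** uses the sample (n−1) standard deviation, the chemometrics
  convention; the population form is available via `population_sd = TRUE`.
* **Savitzky–Golay** edge points are evaluated from the polynomial fitted to
  the terminal window (via `signal::sgolay`), so the band count is
  preserved; derivatives are per band-index step.
* **SPXY** seeds with the pair at maximal joint distance and breaks ties
  toward the lowest sample index; the calibration count is
  `round(n * ratio)` with ratio 2/3 by default (a stated 69/30 split of 99
  samples is arithmetically inconsistent with 2:1; the ratio is the
  contract).
* **PLS** is NIPALS on column-centered data; PLS1 weights are closed-form,
  PLS2 iterates to 1e-10 (500-iteration cap). Coefficients in band space are
  $B = W(P^\top W)^{-1}Q^\top$; scores are orthogonal to 1e-8 by
  construction and the coefficient route equals the latent route.
* **Cross-validation** uses venetian-blind (interleaved) folds over the
  calibration rows in SPXY selection order — deterministic and standard in
  chemometrics. RMSECV ties resolve to the smaller LV count.
* **PLS-DA** one-hot encodes classes, classifies by argmax (ties to the
  lower class index), and selects its LV count by CV accuracy by default
  (`criterion = "rmsecv"` is offered, since either convention appears in the
  applied literature).
* **CARS** per run: Monte-Carlo sampling of 80 % of calibration rows, PLS
  coefficient ranking, forced deletion to the exponential-decline keep count
  $r_i = a e^{-ki}$ with $a = (p/2)^{1/(N-1)}$, $k = \ln(p/2)/(N-1)$ (all
  bands at run 1, two at run N), then adaptive reweighted sampling — *p*
  draws with replacement, probability proportional to |coefficient|, unique
  draws retained. Drawing only the keep count instead (a plausible reading
  of the ARS step) multiplies the pool by ≈0.63 every run and collapses it
  to 2 bands within ~8 runs, which contradicts the gradual decay and
  interior RMSECV minimum this method is known for; the *p*-draw form is the
  canonical construction. Subsets are scored by k-fold RMSECV minimized over
  1..max_lv components, so subsets of very different sizes are compared
  fairly. A `n_monte_carlo` field is accepted for configurations that state
  a Monte-Carlo simulation count separately from the run count, but the
  single run loop does not use it.
* **Random frog** proposes a subset size from
  $N(Q, 0.3\,Q)$, shrinks by dropping the weakest bands or grows by adding
  the strongest candidates from a random pool (ranked by PLS coefficient on
  the temporary superset), and accepts worse subsets with probability
  $0.1 \cdot s_{old}/s_{new}$ (capped at 1). A band's selection probability
  is its containment frequency over iterations; bands strictly above the
  0.1 threshold are selected (a threshold of 1 therefore selects nothing).
  Classification tasks score subsets by 1 − CV accuracy so that score
  minimization covers both tasks.
* **Equivariance caveat.** The frog walk is chaotic in floating point: a
  single accept decision at the rounding limit diverges the trajectory, so
  band-relabeling equivariance holds statistically (same favored bands,
  high rank correlation), not bitwise.
* **Random forest** uses 500 trees and $\lfloor\sqrt p\rfloor$ features per
  split (the field's defaults when none are stated), seeded for
  reproducibility.
* **Leakage discipline.** Selectors are fitted on calibration rows only;
  permuting prediction-set targets provably changes no selected band (this
  is a test).

## Limitations

* ENVI I/O supports BSQ/BIL/BIP with int16/int32/float32/float64/uint16
  payloads; band-sequential metadata beyond wavelengths is ignored.
* ROIs are supplied (rectangle or mask); there is no automatic fruit
  segmentation.
* The generator's class effect is a simple additive offset over 800–850 nm;
  real origin differences involve many correlated traits.
* Stated channel counts for this instrument class vary (231 channels
  acquired vs 225 modeled bands); the generator defaults to 225 equally
  spaced bands and does not attempt to reconcile vendor binning.

## A worked run

```{r example, eval = FALSE}
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
rep$metrics
autoplot(rep$selection)
```
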