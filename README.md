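# nircal

Quantitative near-infrared (NIR) calibration of trace nutritional
analytes — galacto-/fructo-oligosaccharides (GOS, FOS), calcium and
vitamin C — in milk powder, for chemometricians and food-analysis labs
replacing slow wet-chemistry assays (ion chromatography, flame AAS,
fluorometry) with spectroscopic prediction.

Given an absorbance matrix **X** (samples × wavenumbers, 4,000–12,500
cm⁻¹) and reference concentrations **y**, the package runs the standard
calibration chain:

* **Pretreatment** — SNV, MSC, per-row min–max normalization, or
  Savitzky–Golay smoothing (fit state, e.g. the MSC reference spectrum,
  estimated on calibration rows only).
* **Wavelength selection** —
  **CARS** (competitive adaptive reweighted sampling): N Monte Carlo
  runs combining PLSR-coefficient weights *w\_j = |b\_j| / Σ|b|*, an
  exponentially decreasing retention schedule *r\_i = a·e^(−k·i)* with
  *r₁ = 1, r\_N = 2/p*, and weighted resampling; the run minimizing
  RMSECV wins. **Random frog**: a stochastic subset search whose
  per-wavelength selection frequency over N iterations ranks the
  wavelengths; the top 40 are kept.
* **Calibration** — PLSR (NIPALS, latent variables ≤ 10 chosen by k-fold
  RMSECV) or ε-SVR with Gaussian kernel *K(u,v) = exp(−γ‖u−v‖²)* and an
  exhaustive grid search over *(c, g) ∈ [−10, 10]*, step 0.5
  (*C = 2^c, γ = 2^g*; 41 × 41 = 1681 cells).
* **Evaluation** — Rc/RMSEC on the calibration set and Rp/RMSEP on the
  prediction set of a random 7:3 split.

A synthetic milk-powder spectrum generator (Gaussian absorption bands,
per-sample multiplicative scatter, baseline drift, compositional
background variation, noise) with known informative-wavelength ground
truth makes the whole chain testable without instrument data; see the
methods vignette (`vignettes/nircal-methods.Rmd`) for the generative
model and all design choices.

## Worked example

```r
library(nircal)
sim <- simulate_dataset(default_milk_powder_config("GOS", seed = 101))
fit <- nir_calibrate(sim$spectra, sim$reference, preprocess = "snv",
                     selector = "cars", model = "plsr", seed = 101)
summary(fit)
#> NIR calibration of GOS
#>   split: 84 calibration / 36 prediction (ratio 0.7)
#>   preprocessing: snv
#>   selector: CARS, 200 of 1557 wavelengths (reduction 87.15%)
#>   model: PLSR, 10 latent variables
#> GOS | pre: snv | sel: cars (200 wl) | model: plsr
#>   Rc = 0.9926  RMSEC = 0.8822  Rp = 0.9582  RMSEP = 2.3593
```

Reading: of 120 simulated samples, 84 trained the model and 36 were held
out; CARS kept 200 of 1557 wavelengths (an 87.15% reduction); on the
held-out samples the predicted GOS concentrations correlate with the
reference values at Rp = 0.958 with a root mean square error of
2.36 mg/kg over the 5–29 mg/kg range. `predict(fit, new_spectra)`
returns concentrations for new samples; `plot(fit)` draws
predicted-versus-measured; `coef(fit)` exposes the calibration
coefficients; `benchmark_table()` compares pipeline configurations
across analytes and replicate seeds on identical simulated data.

CSV I/O for spectra (`id,<wn1>,<wn2>,...`) and references
(`id,value[,analyte,units]`) is provided by `read_spectra_csv()` /
`write_spectra_csv()` / `read_reference_csv()`; fitted models serialize
to JSON with `save_model_json()` and reload with exact prediction
reproducibility.

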