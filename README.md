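# sifa — surface-induced fluorescence attenuation analysis

`sifa` turns single-molecule fluorescence intensity traces recorded above a
light-absorbing surface into transmembrane insertion depths, identifies the
discrete axial states a membrane-bound molecule visits, and quantifies the
kinetics of its transitions. The target experiment is a dye-labelled
membrane-active peptide (e.g. LL-37) diffusing in a supported lipid bilayer
a few nanometres above a graphene-oxide (GO) monolayer, imaged by TIRF
microscopy: the lateral position comes from spot tracking, and the axial
position comes from how strongly the surface quenches the dye.

## The model

A fluorophore at height *d* above the absorbing plane emits the fraction

I/I₀ = d⁴ / (d⁴ + d₀⁴)

of its unquenched intensity I₀, where d₀ is the characteristic quenching
distance (I/I₀ = 1/2 at d = d₀; for GO, d₀ ≈ 4 nm). Inverting this law maps
a background-subtracted intensity to a height with sub-nanometre
sensitivity inside the 0.5 d₀–1.7 d₀ range. Heights below ~2 nm fall in the
*blind region* where the dye is indistinguishable from camera background.

On top of that ruler the package provides:

* **Calibration** — `calibrate_d0()` solves d₀ from reference layers of
  known thickness with first-order error propagation.
* **Synthetic data** — exact Gillespie state paths over a K-state
  continuous-time Markov model, intensity traces with camera-like noise and
  single-step photobleaching, and rendered TIRF movie stacks with ground
  truth (`go_bsa_model()`, `go_supported_model()`, `simulate_trace()`,
  `simulate_movie()`).
* **Tracking** — spot detection with sub-pixel centroids, greedy
  nearest-neighbour trajectory linking with gap bridging, and 7×7-ROI
  photometry with local background and PSF-aware aperture correction.
* **State inference** — pooled intensity PDFs, seeded Gaussian-mixture EM
  with free component number selected by BIC (optional fixed background
  component for blind-region mass), peak-to-position conversion with
  propagated uncertainties, per-frame state assignment and 3-D trace
  export.
* **Kinetics** — dwell-time extraction with censoring and a
  double-exponential maximum-likelihood fit with truncation, censoring and
  a likelihood-ratio comparison against a single exponential.
* **Pipeline** — `run_pipeline()` drives simulate → calibrate → infer →
  kinetics from one JSON-serialisable config, reproducible from the seed.

## Worked example

```r
library(sifa)

# calibrate the quenching distance from two reference layers
refs <- list(reference_layer("bilayer", 4.1, 0.48, 0.06),
             reference_layer("BSA",     3.3, 0.31, 0.06))
calibrate_d0(refs)
#> Surface quenching model (d^-4 law)
#>   d0: 4.11 +/- 0.19 nm
#>   I0: 1 a.u.
#>   sensitive range: 2.05 - 6.98 nm

# simulate the lifted-bilayer experiment and recover its five states
qm     <- quench_model(d0 = 4.0, i0 = 1000)
traces <- simulate_traces(50, go_bsa_model(), qm, duration = 20, seed = 11)
fit    <- fit_mixture(build_intensity_pdf(traces), n_range = 1:7,
                      restarts = 8, seed = 12)
fit$n
#> [1] 5
round(peaks_to_positions(fit, qm)$position_nm, 2)
#> [1] 3.35 4.19 5.31 6.25 7.73
```

The five recovered heights bracket the generating states at 3.4, 4.2, 5.2,
6.2 and 7.5 nm above the GO layer (bottom surface, lower leaflet, centre,
upper leaflet, top surface of the bilayer); the topmost state sits in the
saturation region and is flagged accordingly. Dwell-time kinetics of the
high-fluorescence states:

```r
set.seed(31)
fit_double_exponential(rdwell(2000, 0.5, 0.060, 0.260), seed = 32)
#> Double-exponential dwell fit (mle), n = 2000 (0 censored)
#>   fast: tau = 57.6 ms (se 5.3), amplitude 0.45
#>   slow: tau = 230.8 ms (se 12.4)
#>   vs single exponential (tau = 153.3 ms): LR = 171.5, p = 5.83e-38 -> 2exp
```

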