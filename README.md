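# portalqa

Quantitative image-quality analysis for radiotherapy **portal imaging**,
aimed at medical physicists evaluating low-atomic-number target imaging
beams against conventional megavoltage beams.

Portal images taken with the 6 MV treatment beam are low-contrast because
megavoltage photons interact almost only by Compton scattering. A thin
low-Z (e.g. aluminium) bremsstrahlung target plus a polystyrene electron
filter enriches the imaging beam in diagnostic-quality photons
(25–150 keV) and visibly improves image quality. `portalqa` implements the
standard analyses used to quantify that improvement, plus a synthetic
phantom-image and beam-model generator that provides reproducible test
images for both beam qualities.

## What it computes

* **Square-wave (bar-pattern) MTF.** For a lamella block of bar width
  *w* (spatial frequency *f* = 1/2*w* lp/mm), the contrast is
  *k* = (max − min)/(max + min) of the grey levels; the MTF at *f* is the
  image/object contrast ratio, normalised to the lowest frequency. The
  **critical frequency f50** and **limiting frequency f10** are where the
  relative MTF first falls to 50 % / 10 %.
* **Contrast-detail analysis.** Each of the QC phantom's 27 low-contrast
  holes (6 diameters × up to 5 depths) is scored by the contrast
  difference |E − E₀|/E₀ = 1 − e^(−Δμ·t) between its measurement disc and
  surrounding background, then classified **green** (≥ 5 %), **yellow**
  (3–5 %) or **red** (< 3 %).
* **1-D gamma analysis.** Measured-vs-modelled depth-dose and lateral
  profiles are compared with γ = min √((Δx/dta)² + (ΔD/δD)²) at 3 %/3 mm
  criteria after 1 mm linear resampling, with percent-of-maximum dose
  normalization.
* **Beam/filter model.** Parametric spectra for the two beam qualities,
  25–150 keV window fractions, Beer–Lambert filtering, and the
  electron-removal sweep of a polystyrene filter (electrons essentially
  gone at 20 mm, photon spectrum nearly untouched).

## Worked example

```r
library(portalqa)

report <- run_comparison(default_run_config(scale = 0.5, seed = 1))
print(report)
#> <comparison_report> seed=1, hash=c040da3d0e0957d0432255374f71c59c
#>   al_target  f50 = 0.759 lp/mm   f10 = 1.590 lp/mm   bars G/Y/R = 14/6/7
#>   6mv        f50 = 0.441 lp/mm   f10 = 0.956 lp/mm   bars G/Y/R = 4/7/16
#>   dose validation: PDD max diff 1.60%, PDD gamma pass 100%, profile gamma pass 100%
```

Reading this: on paired synthetic renders with a shared seed, the
aluminium-target beam resolves to a critical frequency of 0.759 lp/mm
versus 0.441 lp/mm for the 6 MV beam, and 14 of the 27 low-contrast holes
are distinguishable (green) versus 4 — the diagnostic-energy-enriched beam
out-resolves the conventional beam in both sharpness and low-contrast
detectability. The dose-validation arm compares a depth-dose pair agreeing
within 1.6 % of maximum: every point passes 3 %/3 mm gamma.

```r
pair <- make_dose_curve_pair("pdd", perturbation = c(1.6, 0, 0))
gamma_1d(pair$reference, pair$evaluated)
#> <gamma_result> 151 points, criteria 3%/3 mm (1 mm grid): pass 100.0%, max gamma 0.533, max dose diff 1.60%
```

Individual stages are exposed as functions (`make_toy_spectrum()`,
`render_phantom_image()`, `compute_mtf_curve()`,
`contrast_detail_distribution()`, `gamma_1d()`, `filter_sweep()`, …) and as
subcommands of the thin CLI at `inst/scripts/portalqa.R`
(`simulate | mtf | contrast | gamma | report`). The methods vignette
(`vignettes/portal-image-qa.Rmd`) documents the models, default parameters
and their rationale.

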