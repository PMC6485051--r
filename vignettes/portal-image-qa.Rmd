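---
title: "Methods: synthetic portal-image quality analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic portal-image quality analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(portalqa)
```

## The problem

Portal images — images taken with the treatment beam itself to verify
patient positioning — are notoriously poor, because megavoltage photons
interact almost exclusively by Compton scattering and carry little subject
contrast. One route to better portal images is to enrich the imaging beam in
diagnostic-quality photons (25–150 keV) by replacing the thick high-Z
bremsstrahlung target with a thin low-Z one (here: external aluminium on the
accessory tray) and stopping the transmitted primary electrons with a
polystyrene slab. `portalqa` implements the quantitative image-quality
analyses used to evaluate such a beam — bar-pattern MTF, contrast-detail
scoring, and 1-D gamma comparison of dose curves — together with a synthetic
phantom-image and beam-model generator that stands in for measured computed
radiography (CR) images and water-phantom scans, which are not publicly
available for this kind of experiment.

## The beam and filter model

`make_toy_spectrum()` provides two fixed spectral shapes on a 1 keV grid
from 1 keV to a nominal 6 MeV: a thin-target bremsstrahlung-like shape
$w(E) \propto (E_{max}-E)/E \cdot e^{-(E_0/E)^2}$ for the aluminium-target
beam and a hardened $w(E) \propto (E/E_{max})^{1.5}(E_{max}-E)$ shape for
the conventional 6 MV beam. The 1 keV grid makes the 25/150 keV window
arithmetic exact (`low_energy_fraction()` handles straddling bins
pro-rata). The rolloff $E_0 = 20$ keV was calibrated once, by forward
computation, so the aluminium-target beam carries about a third of its
photons in the diagnostic window (the regime a low-Z target beam is designed
to reach); the 6 MV shape carries essentially none:

```{r}
low_energy_fraction(make_toy_spectrum("al_target"))
low_energy_fraction(make_toy_spectrum("6mv"))
```

Attenuation uses a two-component toy curve per material
(`attenuation_coefficient()`): a photoelectric-like $E^{-3}$ term plus a
slowly varying Compton-like term, anchored at 60 keV. The coefficients are a
modelling convenience, calibrated so that (a) brass lamellae are strongly
absorbing at diagnostic energies, (b) the aluminium hole depths 0.5–4.8 mm
span the 3 %/5 % visibility bands under both beams, and (c) polystyrene is
nearly grey. The last point is deliberate: in full transport simulations a
polystyrene electron filter barely changes the *shape* of the photon
spectrum (scattered photons replenish the soft component), so the toy
filter's photon attenuation is made almost energy-independent, which keeps
the low-energy share of the photons nearly constant across the 0–20 mm
thickness sweep while `electron_survival()` — a smooth
$\exp(-(t/0.45R)^2)$ falloff reaching below 1 % at the effective CSDA range
$R = 20$ mm — removes the electrons. The survival curve is a parametric
stand-in for transport physics, chosen for its shape, not derived from it.

```{r}
filter_sweep(make_toy_spectrum("al_target"), seq(0, 20, 4))
```

## The phantom and the imaging geometry

`default_ptw_phantom()` encodes a QC phantom with 11 brass bar-pattern
(lamella) sets from 0.125 to 3.33 lp/mm (bar width $w$ gives frequency
$1/2w$) and an aluminium low-contrast element with 27 holes of 6 diameters
(15–1.1 mm) and 5 depths (0.5–4.8 mm); the two largest diameters omit the
deepest rows. Bar widths, diameters and depths are vendor-published values;
the *layout* (a diameter-column × depth-row grid for the holes, a 4 × 3
block grid for the lamellae) is a documented synthetic arrangement, since
the commercial drawing is not published. All analyses take their regions of
interest from the same specification, so any consistent layout is
equivalent. An `"extended"` variant adds three diagonal duplicates of the
lowest frequencies (14 sets, still 11 distinct frequencies); whether the
vendor's three extra sets are duplicates in orientation is not documented,
so the duplicates are rendered but never analysed, and the `"minimal"`
11-set phantom is the default.

Geometry follows the portal-imaging convention: the phantom plane at
95.2 cm SSD with a 26 × 26 cm² field, the imager at 110 cm SID, so
structures are projected with magnification $M = 110/95.2 \approx 1.156$
and a phantom-plane frequency $f$ appears at $f/M$ on the imager. All
reported frequencies are phantom-referenced. Coordinates are phantom-plane
mm with the origin at the phantom centre; images are row-major with pixel
(1, 1) top-left.

## The synthetic renderer

`render_phantom_image()` computes the ideal transmission of each distinct
material stack (spectrum-weighted Beer–Lambert, no scatter buildup), paints
the projected layout, blurs with a Gaussian PSF, adds scaled-Poisson plus
Gaussian noise, and quantises to 16 bits. The canvas emulates a
2828 × 2320 px CR plate; the pixel spacing (0.125 mm) and the
exposure-to-intensity gain (52 000 counts at unit transmission) are
documented assumptions, since neither is reported for CR portal imaging
setups of this kind. A `scale` parameter coarsens the canvas for desk-scale
work; the analyses below were exercised at scales 0.25–1.

Two deliberate modelling choices:

* **Energy-dependent detector response.** The physical claim that the
  detector's MTF depends on photon energy is folded into a
  beam-mode-dependent PSF width rather than an absorbed-energy model:
  0.33 mm (imager plane) for the aluminium-target beam, 0.56 mm for 6 MV.
  These defaults were chosen so the synthetic critical frequencies fall in
  the regime reported for CR portal imaging of the two beam qualities
  (f50 ≈ 0.75 vs ≈ 0.45 lp/mm). A single Gaussian has a shorter-tailed MTF
  than a real CR chain, so the synthetic limiting frequencies f10 sit closer
  to f50 than measured ones do; conclusions about f10 magnitudes on real
  systems cannot be drawn from the synthetic defaults, only orderings.
* **Hole polarity.** The low-contrast "holes" are modelled as regions of
  *additional* aluminium path equal to the printed depth (the disc signal is
  lower than its background). This makes the measured contrast follow the
  exponential contrast-difference law exactly (see below), which is the
  property the analysis is built on; with the opposite polarity the ratio
  $|E-E_0|/E_0$ would follow $e^{\Delta\mu t}-1$ instead. In the displayed
  (inverted) convention the discs read bright, as hole images do.

Rendering is bit-reproducible: one seeded generator per render, the seed is
recorded in the image metadata, and the session RNG stream is restored
afterwards. Images are stored non-inverted; `invert_for_display()` is a
view, never an analysis step.

## Spatial resolution: square-wave MTF

For each lamella block, `region_contrast()` averages the region transverse
to the bars, splits the profile into bar/gap periods, and averages the
per-period maxima and minima; the contrast is
$k = (\max - \min)/(\max + \min)$. Per-period extrema averaged over several
periods are the robust reading of a max/min contrast under noise — a single
global extremum is biased upward — and the outermost period at each end is
dropped when four or more are available. `compute_mtf_curve()` divides the
image contrast by the object contrast (ideal two-level transmission of the
same block, carried in the render metadata) and normalises to the lowest
frequency; the square-wave contrast ratio is used directly as the MTF, with
no square-to-sine (Coltman-series) conversion, which is the bar-pattern
convention this analysis follows end to end. The critical (f50) and
limiting (f10) frequencies are the first downward crossings of the relative
curve at 0.5 and 0.1, linearly interpolated between bracketing frequencies;
taking the *first* crossing makes the estimate well-defined on noisy,
non-monotone curves. A curve that never falls below the level returns the
highest measured frequency flagged censored. Blocks whose projected period
falls below 2 pixels cannot be sampled and are excluded rather than
extrapolated.

The estimator is validated against an independent direct-convolution
oracle: the continuous blurred profile of a finite bar pattern has a closed
form in the normal CDF, and its per-period extrema give the square-wave
response without touching the renderer. Across PSFs of 0.1–0.6 mm and bar
widths of 0.25–2 mm the two agree within 2 % relative wherever the response
is measurable (≥ 0.05) and within 0.005 absolute in the deeply cut tail,
where the reading is dominated by the envelope of the finite pattern.

## Contrast resolution: contrast-detail scoring

For each hole, `contrast_detail_distribution()` takes `E` as the mean
signal over a concentric disc at 80 % of the projected diameter and `E0`
over a concentric annulus from 120 % to 160 %, and scores
$|E-E_0|/E_0$. The ROI shapes are this package's choice — the method
prescribes only "background areas around the measurement areas" — and
concentric sampling is unbiased under the renderer's symmetric PSF. The
published three-band rule classifies each hole: green (≥ 5 %), yellow
(3–5 %), red (< 3 %), boundaries inclusive from above. Grayscale is used as
the proxy for absorbed energy, as the light output of the detector is
proportional to it.

On a noiseless, PSF-free render the measured contrast of every hole
recovers the spectral forward model $1 - e^{-\Delta\mu_{\text{eff}} t}$
within 1 % relative (quantisation is the only residual), where
$\Delta\mu_{\text{eff}}$ (from `effective_delta_mu()`) is defined so the
exponential law reproduces the polychromatic transmission ratio at that
depth. Under the default degraded renders the small-diameter holes lose
contrast to the PSF, which is what makes the distribution a *detail* test
and not merely a depth ladder.

## Dose-curve comparison: 1-D gamma at 3 %/3 mm

`make_dose_curve_pair()` generates a reference curve — a depth dose with
build-up constant 4 mm and exponential falloff constant 120 mm (maximum
near 15 mm depth), or a lateral profile with a 200 mm flat top and 3 mm
sigmoid penumbrae, both sampled every 2 mm — and an evaluated copy with a
controlled multiplicative dose offset, rigid shift and/or noise.
`gamma_1d()` resamples the evaluated curve at 1 mm by linear interpolation,
then minimises
$\sqrt{(\Delta x/\text{dta})^2 + (\Delta D/\delta D)^2}$ exhaustively
within ±3 dta of each reference point. $\delta D$ is *global*: the dose
tolerance as a percentage of the reference curve's normalization dose
(its maximum; 100 on percent-scaled curves). Global normalization is the
common convention when none is stated, and matches percent-of-maximum
agreement reporting. No sub-grid refinement is applied — the discretization
penalty is bounded by half the resample spacing and is quantified in the
test suite against a 0.01 mm brute-force oracle. A `roi` window restricts
scoring to, e.g., the open-beam region of a profile. "Agreement within
x %" is reported as the maximum absolute pointwise difference of
max-normalized curves; the mean is reported alongside, since published
agreement figures rarely state which was used.

## Problem sizes and determinism

The default test and acceptance runs use canvas scales 0.35–0.5
(≈ 990 × 812 to 1414 × 1160 px) for degraded-image analyses, where the
frequencies that decide f50 are well sampled, and full scale
(2828 × 2320 px) for the noiseless exactness checks. Every stochastic step
takes an explicit seed; identical inputs and seed give bit-identical
images and reports, and `run_comparison()` embeds the seed and a config
hash in its report.

## Known limitations

* No scatter, no CR plate physics (phosphor response, reader optics), no
  EPID chain: the detector is a PSF + gain + noise abstraction.
* The Gaussian PSF understates the long tails of real CR systems (see
  above); the electron-survival curve and attenuation coefficients are
  parametric stand-ins, not transport results or reference data.
* Quantitative agreement with measured f50/f10/contrast-bar values on real
  CR images is out of scope; the synthetic conditions reproduce the
  *structure* of the analysis and the beam-quality orderings.
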