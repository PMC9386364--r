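---
title: "Spectral–texture fusion for rice LAI estimation: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral–texture fusion for rice LAI estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wtvi)
```

## The estimation problem

Leaf area index (LAI) regression on vegetation indices (VIs) works well in
open canopies and fails in two characteristic ways over a full rice season:
normalized indices saturate once the canopy closes, and panicle emergence
after heading perturbs canopy spectra so that one whole-season linear model
straddles two separated point clouds.  `wtvi` implements a fusion approach:
multiply the plot-level VI by a plot-level wavelet texture energy that keeps
responding to canopy structure after the spectral signal has flattened.

## The model chain

1. **Radiometric calibration.** Per band, reflectance is regressed on raw
   digital number (DN) over gray calibration tarps of known reflectance
   (defaults: 0.03, 0.06, 0.12, 0.24, 0.36, 0.48, 0.56, 0.80) by ordinary
   least squares; imagery is mapped through `gain * DN + offset` and clipped
   to [0, 1].  The transform is affine before clipping; the clip exists only
   so index algebra stays defined.  One line is fitted per band per
   invocation — grouping across flights is the caller's decision.
2. **Vegetation indices.** Twelve indices over the 550/670/720/800 nm bands,
   evaluated per pixel.  Pixels with |denominator| < 1e-12, masked pixels,
   and non-finite results are flagged invalid and excluded from plot means
   instead of being clamped.  WDRVI's weight `alpha` defaults to 0.2.
3. **Wavelet texture.** The 800 nm band (configurable; any NIR band is
   reasonable) is decomposed one level with the 2D Haar discrete wavelet
   transform; the texture feature is the 3×3 windowed mean of squared LL
   coefficients (`Ene`), then averaged over the plot ROI at LL (half)
   resolution.
4. **Fusion and evaluation.** `WT-VI = VI × Ene` at plot level; simple
   linear models `LAI = a·x + b` for every VI and WT-VI are compared by
   seeded k-fold cross-validation (default k = 10).

## Numerical and interpretive choices

* **Haar normalization.** The mother-wavelet definition fixes the filter
  shapes but not the discrete scaling.  We use the orthonormal convention
  (`(1, 1)/√2`, `(1, -1)/√2`), so a 2×2 block `(a, b; c, d)` gives
  `LL = (a+b+c+d)/2`: perfect reconstruction holds to machine precision and
  the sum of squared coefficients equals the image energy (Parseval), which
  makes the name "energy texture" literal.  A unit-sum averaging convention
  (`LL` = block mean) is exposed for sensitivity checks only.
* **The energy window.** The energy formula is a 3×3 sum of squared LL
  values with no explicit window anchoring.  We read it as a *sliding* 3×3
  mean producing an energy image at LL resolution (the per-pixel energy maps
  shown in texture figures require exactly this), followed by ROI averaging
  for the plot-level scalar.  The alternative — one fixed 3×3 window per
  plot — was rejected because it discards almost all of the plot and cannot
  produce an energy image.
* **Borders and odd sizes.** A trailing odd row/column is cropped before the
  transform (deterministic; padding would bias LL statistics at the edge).
  The 3×3 window uses reflect padding (mirror about the edge pixel), keeping
  the output shape equal to LL with no zero-bias at borders.
* **Coordinates.** ROIs are 0-based, half-open `[min, max)` — the convention
  of the on-disk files — because it makes the LL-resolution mapping an exact
  integer halving: `[r0, r1) → [⌊r0/2⌋, ⌊r1/2⌋)`.  Any ROI of width ≥ 2
  survives the halving, so the degenerate-ROI error can only trigger on
  hand-built ROI objects.
* **Plot-level VI.** The plot statistic is the mean of the VI image over
  valid ROI pixels, not the VI of mean reflectances.  The two differ for
  ratio indices (Jensen's inequality); the mean-of-image reading matches the
  band-mathematics-then-average processing order described for the UAV
  workflow.  The VI-of-means variant is trivially available via `vi_value()`
  on band means.
* **OSAVI and RVI band choice.** Both are registered with the red-edge
  (720 nm) band as printed in the source VI table, although their classical
  definitions use the red (670 nm) band.  Whether the 720 nm forms are
  deliberate or transcription artifacts cannot be decided from the text, so
  the printed forms are the default and `variant = "classical"` switches to
  the textbook forms.  Nothing downstream depends on the choice.
* **Fit metrics.** `R² = 1 − SS_res/SS_tot`; `RMSE = √(SS_res/n)` (the 1/n
  population form, conventional for held-out evaluation in remote sensing);
  `rRMSE = 100·RMSE/mean(observed LAI)` — rRMSE is not defined in the source
  and this is the most common convention.  Cross-validation reports both the
  fold-mean of squared slopes (`Coef²`, faithful to the stated aggregation)
  and the full-data refit `(slope, intercept)`, which is what published
  final equations of the form `LAI = a·(WT-VI) + b` appear to be; held-out
  `R²` on a fold of size 1 is undefined and reported as `NA` rather than
  guessed.
* **Fold assignment.** One seeded uniform shuffle, k contiguous chunks,
  remainder distributed one per fold from the first; the same seed is shared
  across all features so every feature is judged on identical folds.

## What the synthetic scene emulates

Field data behind the reference results was never deposited, so validation
runs on a generator whose defaults *are* the stated world of the emulated
campaign, chosen once and not revisited:

* 24 plots × 4 growth stages (tillering, jointing, booting/heading,
  ripening) = 96 plot-dates; 32×32-pixel plots; planting density 22.5
  bundles/m² (so ground truth satisfies `LAI = (LA/3)·ρ` exactly).
* Per-stage LAI ranges 0.5–3, 2.5–5.5, 4–7.5 and 2–8 — increasing early,
  plateauing, then wide at ripening (the ripening range 2–8 is as reported
  for the emulated campaign).
* Canopy cover follows the Beer–Lambert gap fraction `f = 1 − exp(−k·LAI)`
  with extinction coefficient `k = 0.5` (a standard mid-range value for
  rice canopies) — the simplest mechanism that produces VI saturation.
* The canopy indicator is a thresholded Gaussian random field whose
  correlation length grows with LAI (`1.5 + 0.35·LAI` pixels: leaves get
  bigger), plus multiplicative NIR mottling (contrast 0.2).  Vegetation NIR
  reflectance rises slowly with LAI (`×(1 + 0.6·(1 − e^{−0.15·LAI}))`,
  multiple leaf-layer scattering), so the NIR mean — and hence LL energy —
  keeps responding after cover closes while band-ratio indices flatten.
* Background is a 50/50 water/soil blend at tillering (flooded paddies),
  bare soil later; post-heading stages mix bright, low-NIR panicle speckle
  into 8% (booting/heading) and 15% (ripening) of canopy pixels.
* Additive per-pixel reflectance noise σ = 0.01; DN synthesis inverts
  `DN = 1200·ρ + 40` with DN noise σ = 5.
* All randomness flows from one mandatory seed; each plot-date renders
  under a derived substream, so scenes are bit-identical under a config.

What it does **not** emulate: radiative transfer (no PROSAIL-class
directional or biochemical effects), illumination/BRDF geometry, leaf
yellowing spectra at ripening, georeferencing or lens registration, or any
quantitative texture statistics of real paddies — no such statistics are
published to match.  A green structural test therefore establishes that the
implementation reproduces the *direction* of the fusion result under the
stated mechanisms (saturating spectra, non-saturating structure), not that
it reproduces field-measured accuracies; the published whole-season
R² ≈ 0.3–0.5 values live on undeposited data and are deliberately not
asserted anywhere.

One measurement convention worth noting: the saturation diagnostic
(marginal NDVI and Ene responses at LAI 6 vs LAI 1) uses common random
numbers — the ±δ plots of a finite difference share a seed — because
coverage-fraction sampling noise in a 32×32 correlated field would
otherwise dominate the derivative at high LAI.  This is variance reduction
in the measurement, not a change to the generator.

## Interfaces

Imagery travels in a self-describing plain-text `.cube` container
(17-significant-digit values; exact round trip).  A GDAL-backed GeoTIFF
reader is intentionally not bundled — the deployment environments this
package targets do not carry GDAL, and every documented workflow, including
the CLI, operates on the text container plus CSV/JSON tables.  Scenes,
ROIs (CSV, 0-based half-open), ground truth (CSV with the `LAI = (LA/3)·ρ`
consistency check), feature tables (CSV) and CV results (JSON) all embed or
accompany a config hash; reruns with an identical config are byte-identical.

## Known limitations

* Single linear regressors only — no exponential, polynomial or
  machine-learning models, and no growth-stage-specific model switching:
  the point of the fusion is one whole-season linear model.
* Level-1 decomposition of one NIR band only; no LH/HL/HH features, wavelet
  packets, or gray-level co-occurrence textures.
* The generator's qualitative orderings (fusion beats VI; Ene unsaturated)
  are robust across seeds, but effect sizes on synthetic scenes are cleaner
  than field data would give; treat absolute R² values from synthetic runs
  as diagnostics, not forecasts.
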