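# wtvi

Estimating rice leaf area index (LAI) from UAV multispectral imagery by
fusing spectral vegetation indices with a wavelet texture feature.

## The problem

LAI — one-sided green leaf area per unit ground area — is the workhorse
indicator of crop growth, but regression of LAI on vegetation indices
(VIs) degrades over a full rice season: once the canopy closes
(LAI ≳ 3) normalized indices such as NDVI saturate, and after heading
the emerging panicles shift canopy spectra and split the VI–LAI scatter
into separated pre/post-heading clouds.

`wtvi` implements a spectral–texture fusion remedy.  The near-infrared
(800 nm) reflectance image is decomposed with a level-1 2D Haar discrete
wavelet transform into LL/LH/HL/HH sub-bands; the texture feature is the
local energy of the approximation sub-band,

```
Ene = (1/9) * sum_{3x3 window} |f(x, y)|^2,     f = LL coefficients,
```

averaged over each plot.  Because canopy structure keeps changing after
spectral saturation sets in, plot-level `Ene` stays sensitive to LAI when
the VI no longer is.  The fused index is the plain product

```
WT-VI = VI x Ene
```

for each of 12 registered VIs (NDVI, GNDVI, NDRE, SR, CI_red_edge,
CI_green, WDRVI, MTCI, EVI2, OSAVI, RVI, VARI).  Simple linear models
`LAI = a * feature + b` are compared by k-fold cross-validation
(k = 10 by default), reporting fold-averaged `Coef² = mean(Coef_i²)`,
`R² = mean(R_i²)`, `RMSE = mean(RMSE_i)` and `rRMSE = mean(rRMSE_i)`.

Supporting stages: empirical-line radiometric calibration (per-band OLS
of reflectance on DN over gray tarps of known reflectance 0.03–0.80),
plot-ROI statistics, and a seeded synthetic canopy generator (Beer–Lambert
gap fraction, correlated canopy indicator fields, panicle speckle,
flooded-soil background) with known LAI per plot, so the entire pipeline
is testable offline.

## Worked example

```r
library(wtvi)

cfg    <- scene_config(seed = 1)          # 24 plots x 4 growth stages
scene  <- generate_scene(cfg)             # 96 plot-dates, known LAI
feats  <- build_feature_table(scene)      # VI, Ene, WT-VI, LAI per plot-date
ranked <- rank_indices(feats, k = 10, seed = 2)
head(cv_summary(ranked), 3)
subset(cv_summary(ranked), name %in% c("VI_NDVI", "WTVI_NDVI"))
```

On this synthetic season (seed 1) the run prints, for the NDVI family:

```
cv R2 NDVI : VI 0.6457  ->  WT-VI 0.8607
cv R2 GNDVI: VI 0.6769  ->  WT-VI 0.8745
cv R2 WDRVI: VI 0.6648  ->  WT-VI 0.8111
best feature: WTVI_SR (R2 0.8922, RMSE 0.5255 LAI, rRMSE 12.46%)
```

i.e. every fused index outranks its spectral-only counterpart — the
structural result the method is built on.  RMSE is in LAI units; rRMSE is
RMSE as a percent of mean observed LAI.  The saturation diagnostic from
the same run: the marginal NDVI response at LAI = 6 is ~0.12 of its
response at LAI = 1 (saturated), while the LL-energy response ratio is
~0.38 (not saturated).

## Command line

```sh
Rscript inst/cli/wtvi simulate --seed 3 --plots 24 --out scene_dir/
Rscript inst/cli/wtvi run --scene scene_dir/ --k 10 --seed 42 --out results/
Rscript inst/cli/wtvi texture --in plot.cube --band 800 --out ene.cube
```

Subcommands: `simulate`, `calibrate`, `indices`, `texture`, `fit`, `run`.
Exit codes: 0 success, 2 input error, 3 numerical/degenerate-data error.
Imagery travels in a self-describing plain-text `.cube` container (see
`?read_cube`); feature tables and CV results are CSV/JSON stamped with a
config hash, and reruns with the same config are byte-identical.

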