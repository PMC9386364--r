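Package: wtvi
Title: Wavelet-Texture Fused Vegetation Indices for Rice Leaf Area Index
    Estimation from UAV Multispectral Imagery
Version: 0.1.0
Authors@R:
    person("wtvi", "developers", email = "wtvi@example.org", role = c("aut", "cre"))
Description: Tools to estimate rice leaf area index (LAI) from multiband
    unmanned-aerial-vehicle (UAV) reflectance imagery by fusing spectral
    vegetation indices with a wavelet texture feature.  Provides empirical-line
    radiometric calibration (digital number to reflectance), twelve
    vegetation indices computed from band reflectances, level-1 2D Haar
    wavelet decomposition of the near-infrared band with an LL-sub-band
    energy texture (Ene), multiplicative spectral-texture fusion (WT-VI),
    plot-level feature extraction, and linear-model evaluation by k-fold
    cross-validation.  A seeded synthetic canopy-scene generator emulates
    soil/leaf/panicle spectral mixing, vegetation-index saturation at high
    LAI, and LAI-dependent spatial texture across growth stages, so the
    whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    optparse,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
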