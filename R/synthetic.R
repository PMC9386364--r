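# Synthetic rice-canopy scenes.
#
# The generator is a statistical stand-in for UAV imagery of paddy plots,
# not a radiative-transfer model.  It reproduces the structure the
# spectral-texture fusion method exploits:
#   * canopy cover follows a Beer-Lambert gap fraction f = 1 - exp(-k*LAI),
#     so visible-band mixing (and with it NDVI-type indices) saturates once
#     the canopy closes;
#   * vegetation NIR reflectance keeps rising slowly with LAI (multiple
#     leaf-layer scattering), so the NIR mean - and hence the LL wavelet
#     energy - stays sensitive to LAI after closure;
#   * spatial texture is a thresholded smoothed Gaussian random field whose
#     correlation length grows with LAI (bigger leaves, coarser canopy);
#   * post-heading stages mix in bright low-NIR panicle speckle;
#   * the tillering background is a water/soil blend (flooded paddies),
#     bare soil afterwards.

# Default endmember spectra (unitless reflectance) for the 12 Mini-MCA
# bands.  Values are typical of green rice leaves, moist paddy soil,
# turbid water and ripening panicles at these wavelengths.
default_spectra <- function() {
  data.frame(
    wavelength_nm = c(490, 520, 550, 570, 670, 680, 700, 720, 800, 850, 900, 950),
    leaf    = c(0.045, 0.080, 0.120, 0.100, 0.045, 0.045, 0.100, 0.250,
                0.460, 0.470, 0.470, 0.440),
    soil    = c(0.100, 0.120, 0.140, 0.150, 0.200, 0.210, 0.220, 0.230,
                0.260, 0.280, 0.300, 0.310),
    water   = c(0.060, 0.070, 0.080, 0.075, 0.050, 0.050, 0.040, 0.030,
                0.015, 0.010, 0.008, 0.005),
    panicle = c(0.120, 0.160, 0.200, 0.220, 0.240, 0.240, 0.260, 0.300,
                0.380, 0.390, 0.400, 0.380)
  )
}

#' Configuration of a synthetic canopy scene
#'
#' Defaults describe the emulated field campaign: 24 plots observed at four
#' growth stages (96 plot-dates), 32 x 32-pixel plots, planting density
#' 22.5 bundles/m^2, per-stage LAI ranges spanning roughly 0.5-8 with the
#' ripening stage widest (2-8), extinction coefficient 0.5, eight gray
#' calibration tarps of reflectance 0.03-0.80, and an inverse empirical
#' line DN = 1200 * reflectance + 40 with DN noise sigma 5.  See the
#' methods vignette for the rationale behind each default.
#'
#' @param n_plots plots per stage (default 24; 4 stages give 96 plot-dates).
#' @param plot_rows,plot_cols plot size in pixels (default 32 x 32).
#' @param stages ordered growth-stage labels.
#' @param lai_range named list of `c(min, max)` LAI per stage.
#' @param k_ext Beer-Lambert extinction coefficient (> 0, default 0.5).
#' @param nir_gain amplitude of the slow NIR reflectance rise with LAI
#'   (default 0.6); bands >= 720 nm are scaled by
#'   `1 + nir_gain * (1 - exp(-nir_rate * LAI))`.
#' @param nir_rate rate of that rise (default 0.15 per LAI unit).
#' @param texture_contrast multiplicative within-canopy NIR mottling
#'   amplitude (default 0.2).
#' @param corr_length_base,corr_length_per_lai spatial correlation length
#'   of the canopy indicator field, in pixels: `base + per_lai * LAI`
#'   (defaults 1.5 and 0.35).
#' @param panicle_density named fraction of canopy pixels replaced by
#'   panicle spectra per stage (defaults: 0.08 at booting_heading, 0.15 at
#'   ripening, 0 earlier).
#' @param noise_sd additive per-pixel, per-band reflectance noise standard
#'   deviation (default 0.01).
#' @param rho planting density, bundles per m^2 (default 22.5).
#' @param spectra endmember spectra data frame (see `default_spectra`
#'   layout: `wavelength_nm`, `leaf`, `soil`, `water`, `panicle`).
#' @param target_reflectances nominal calibration-tarp reflectances.
#' @param dn_gain,dn_offset inverse empirical line used to synthesize DN
#'   imagery: `DN = dn_gain * reflectance + dn_offset`.
#' @param dn_sigma DN noise standard deviation (default 5).
#' @param seed integer RNG seed; mandatory, all randomness flows from it.
#' @return A `wtvi_scene_config` list.
#' @export
scene_config <- function(n_plots = 24L,
                         plot_rows = 32L, plot_cols = 32L,
                         stages = c("tillering", "jointing",
                                    "booting_heading", "ripening"),
                         lai_range = list(tillering = c(0.5, 3),
                                          jointing = c(2.5, 5.5),
                                          booting_heading = c(4, 7.5),
                                          ripening = c(2, 8)),
                         k_ext = 0.5,
                         nir_gain = 0.6, nir_rate = 0.15,
                         texture_contrast = 0.2,
                         corr_length_base = 1.5, corr_length_per_lai = 0.35,
                         panicle_density = c(booting_heading = 0.08,
                                             ripening = 0.15),
                         noise_sd = 0.01,
                         rho = 22.5,
                         spectra = default_spectra(),
                         target_reflectances = c(0.03, 0.06, 0.12, 0.24,
                                                 0.36, 0.48, 0.56, 0.80),
                         dn_gain = 1200, dn_offset = 40, dn_sigma = 5,
                         seed) {
  if (missing(seed) || !is_number(seed))
    wtvi_abort("scene_config() requires an integer seed")
  if (!is_number(k_ext) || k_ext <= 0) wtvi_abort("k_ext must be > 0")
  if (!all(stages %in% names(lai_range)))
    wtvi_abort("every stage needs an lai_range entry")
  em <- as.matrix(spectra[, c("leaf", "soil", "water", "panicle")])
  if (any(!is.finite(em)) || any(em < 0 | em > 1))
    wtvi_abort("endmember reflectances must lie in [0, 1]")
  if (any(target_reflectances < 0 | target_reflectances > 1))
    wtvi_abort("target reflectances must lie in [0, 1]")
  structure(list(
    n_plots = as.integer(n_plots), plot_rows = as.integer(plot_rows),
    plot_cols = as.integer(plot_cols), stages = stages,
    lai_range = lai_range, k_ext = k_ext,
    nir_gain = nir_gain, nir_rate = nir_rate,
    texture_contrast = texture_contrast,
    corr_length_base = corr_length_base,
    corr_length_per_lai = corr_length_per_lai,
    panicle_density = panicle_density, noise_sd = noise_sd,
    rho = rho, spectra = spectra,
    target_reflectances = target_reflectances,
    dn_gain = dn_gain, dn_offset = dn_offset, dn_sigma = dn_sigma,
    seed = as.integer(seed)
  ), class = "wtvi_scene_config")
}

# Smoothed standardized Gaussian random field: white noise filtered with a
# separable Gaussian kernel of standard deviation `ell` pixels (circular
# boundary), then rescaled to zero mean / unit sd.  Assumes an active RNG
# stream (callers wrap in withr::with_seed).
gaussian_field <- function(h, w, ell) {
  z <- matrix(stats::rnorm(h * w), h, w)
  if (ell > 0.05) {
    half <- max(1L, ceiling(3 * ell))
    k <- stats::dnorm(seq(-half, half), sd = ell)
    k <- k / sum(k)
    z <- apply(z, 2, circ_filter, k = k)
    z <- t(apply(z, 1, circ_filter, k = k))
  }
  s <- stats::sd(as.vector(z))
  if (s == 0) return(matrix(0, h, w))
  (z - mean(z)) / s
}

# Circular 1D convolution of a vector with an odd-length kernel.
circ_filter <- function(x, k) {
  n <- length(x); half <- (length(k) - 1L) %/% 2L
  xx <- x[((seq(-half + 1L, n + half) - 1L) %% n) + 1L]
  out <- stats::filter(xx, k, sides = 2)
  as.numeric(out[(half + 1L):(half + n)])
}

# Render one plot-date given its LAI and stage.  Uses the active RNG
# stream; wrap in withr::with_seed for reproducibility.
render_plot <- function(config, lai, stage) {
  sp <- config$spectra
  bm <- band_map(sp$wavelength_nm,
                 c(10, 10, 10, 10, 10, 10, 10, 10, 10, 10, 20, 40)[seq_len(nrow(sp))])
  h <- config$plot_rows; w <- config$plot_cols
  f <- 1 - exp(-config$k_ext * lai)
  ell <- config$corr_length_base + config$corr_length_per_lai * lai
  canopy <- gaussian_field(h, w, ell) > stats::qnorm(1 - f)   # mean coverage ~ f
  mottle <- gaussian_field(h, w, ell)                          # within-canopy NIR variation
  pden <- if (stage %in% names(config$panicle_density))
    unname(config$panicle_density[[stage]]) else 0
  panicle <- if (pden > 0)
    canopy & (gaussian_field(h, w, 1) > stats::qnorm(1 - pden)) else
    matrix(FALSE, h, w)
  # flooded background early, bare soil later
  bg_mix <- if (stage == "tillering") 0.5 else 0
  nir_scale <- 1 + config$nir_gain * (1 - exp(-config$nir_rate * lai))
  px <- array(0, dim = c(h, w, nrow(sp)))
  for (i in seq_len(nrow(sp))) {
    veg <- sp$leaf[i] * if (sp$wavelength_nm[i] >= 720) nir_scale else 1
    vegpx <- matrix(veg, h, w)
    if (sp$wavelength_nm[i] >= 720)
      vegpx <- vegpx * (1 + config$texture_contrast * mottle)
    bg <- (1 - bg_mix) * sp$soil[i] + bg_mix * sp$water[i]
    band <- ifelse(canopy, vegpx, bg)
    band[panicle] <- sp$panicle[i]
    band <- band + stats::rnorm(h * w, sd = config$noise_sd)
    px[, , i] <- pmin(pmax(band, 0), 1)
  }
  reflectance_cube(px, bm)
}

#' Generate one synthetic plot-date cube
#'
#' Renders a single plot at a given LAI and growth stage under its own
#' seed.  Useful for targeted experiments (e.g. finite-difference
#' saturation checks); [generate_scene()] loops over this.
#'
#' @param config a [scene_config()].
#' @param lai leaf area index of the plot (>= 0).
#' @param stage growth-stage label.
#' @param seed integer seed for this cube.
#' @return A `wtvi_cube`.
#' @export
generate_plot <- function(config, lai, stage = "jointing", seed) {
  stopifnot(inherits(config, "wtvi_scene_config"))
  if (!is_number(lai) || lai < 0) wtvi_abort("lai must be finite and >= 0")
  if (!is_number(seed)) wtvi_abort("an integer seed is required")
  withr::with_seed(as.integer(seed), render_plot(config, lai, stage))
}

#' Generate a full synthetic scene
#'
#' Draws a per-stage LAI for every plot (uniform within the stage's range),
#' renders every plot-date cube under a deterministic per-cube substream of
#' the master seed, and assembles ground truth (with
#' `LA_total = 3 * LAI / rho`, so [lai_from_samples()] round-trips) and
#' full-plot ROIs.  Regeneration with the same config is bit-identical.
#'
#' @param config a [scene_config()].
#' @return A `wtvi_scene`: list with `cubes` (named list of
#'   [reflectance_cube()], keyed `plot<i>_<stage>`), `rois`, `truth` (data
#'   frame: `sample_id`, `plot_id`, `stage`, `LA_total_m2`, `rho`, `LAI`)
#'   and `config`.
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "wtvi_scene_config"))
  grid <- expand.grid(plot = seq_len(config$n_plots), stage = config$stages,
                      stringsAsFactors = FALSE)
  draws <- withr::with_seed(config$seed, {
    lai <- vapply(seq_len(nrow(grid)), function(i) {
      r <- config$lai_range[[grid$stage[i]]]
      stats::runif(1, r[1], r[2])
    }, numeric(1))
    subseeds <- sample.int(.Machine$integer.max - 1L, nrow(grid))
    list(lai = lai, subseeds = subseeds)
  })
  ids <- sprintf("plot%02d_%s", grid$plot, grid$stage)
  cubes <- lapply(seq_len(nrow(grid)), function(i)
    withr::with_seed(draws$subseeds[i],
                     render_plot(config, draws$lai[i], grid$stage[i])))
  names(cubes) <- ids
  roi <- plot_roi("full", 0, 0, config$plot_rows, config$plot_cols)
  rois <- lapply(ids, function(id) { r <- roi; r$plot_id <- id; r })
  names(rois) <- ids
  truth <- data.frame(sample_id = ids,
                      plot_id = sprintf("plot%02d", grid$plot),
                      stage = grid$stage,
                      LA_total_m2 = 3 * draws$lai / config$rho,
                      rho = config$rho,
                      LAI = draws$lai)
  structure(list(cubes = cubes, rois = rois, truth = truth, config = config),
            class = "wtvi_scene")
}

#' Synthesize calibration targets and DN imagery
#'
#' Inverts the configured empirical line to produce tarp mean DN values
#' (`DN = dn_gain * reflectance + dn_offset + N(0, dn_sigma)`) for each of
#' the eight nominal tarp reflectances on every band.  The implied true
#' correction is `gain = 1/dn_gain`, `offset = -dn_offset/dn_gain`.
#'
#' @param config a [scene_config()].
#' @param seed integer seed for the DN noise (defaults to the config seed).
#' @param noise if `FALSE`, DN values are exact (for recovery checks).
#' @return list with `targets` (data frame: `target_id`, `wavelength_nm`,
#'   `reflectance`, `mean_DN`), `true_gain`, `true_offset`.
#' @export
generate_targets <- function(config, seed = config$seed, noise = TRUE) {
  stopifnot(inherits(config, "wtvi_scene_config"))
  wl <- config$spectra$wavelength_nm
  refl <- config$target_reflectances
  df <- expand.grid(target_id = sprintf("tarp%d", seq_along(refl)),
                    wavelength_nm = wl, stringsAsFactors = FALSE)
  df$reflectance <- refl[match(df$target_id, sprintf("tarp%d", seq_along(refl)))]
  dn <- config$dn_gain * df$reflectance + config$dn_offset
  if (noise)
    dn <- dn + withr::with_seed(as.integer(seed),
                                stats::rnorm(length(dn), sd = config$dn_sigma))
  df$mean_DN <- pmax(dn, 0)
  list(targets = df,
       true_gain = 1 / config$dn_gain,
       true_offset = -config$dn_offset / config$dn_gain)
}

#' Convert a reflectance cube to synthetic DN imagery
#'
#' Inverts the configured empirical line per pixel, with optional DN noise
#' — the raw-imagery counterpart of [generate_targets()], used to exercise
#' the calibration stage end-to-end.
#'
#' @param cube a [reflectance_cube()].
#' @param config a [scene_config()].
#' @param seed integer seed for DN noise.
#' @param noise add `N(0, dn_sigma)` DN noise (default `TRUE`).
#' @return a `wtvi_cube` holding DN values.
#' @export
dn_from_reflectance <- function(cube, config, seed = config$seed, noise = TRUE) {
  stopifnot(inherits(cube, "wtvi_cube"), inherits(config, "wtvi_scene_config"))
  dn <- config$dn_gain * cube$pixels + config$dn_offset
  if (noise)
    dn <- dn + withr::with_seed(as.integer(seed),
                                array(stats::rnorm(length(dn), sd = config$dn_sigma),
                                      dim = dim(dn)))
  reflectance_cube(pmax(dn, 0), cube$bandmap, cube$mask)
}

#' Write a scene to disk
#'
#' Emits one plain-text cube per plot-date plus `rois.csv`,
#' `ground_truth.csv` and `manifest.json` (the config echo) — the layout
#' consumed by the `simulate`/`run` command-line workflow.
#'
#' @param scene a [generate_scene()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "wtvi_scene"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(scene$cubes))
    write_cube(scene$cubes[[id]], file.path(dir, paste0(id, ".cube")))
  write_rois(scene$rois, file.path(dir, "rois.csv"))
  gt <- scene$truth
  utils::write.csv(gt, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE, quote = FALSE)
  cfg <- scene$config
  cfg$spectra <- as.list(cfg$spectra)
  jsonlite::write_json(unclass(cfg), file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a scene written by [write_scene()]
#'
#' @param dir scene directory.
#' @return a `wtvi_scene` (without the generating config's class).
#' @export
read_scene <- function(dir) {
  gt_path <- file.path(dir, "ground_truth.csv")
  roi_path <- file.path(dir, "rois.csv")
  if (!file.exists(gt_path))
    wtvi_abort(sprintf("missing ground truth: %s", gt_path), kind = "io")
  truth <- utils::read.csv(gt_path, stringsAsFactors = FALSE)
  rois <- read_rois(roi_path)
  files <- list.files(dir, pattern = "\\.cube$", full.names = TRUE)
  cubes <- lapply(files, read_cube)
  names(cubes) <- sub("\\.cube$", "", basename(files))
  structure(list(cubes = cubes, rois = rois, truth = truth, config = NULL),
            class = "wtvi_scene")
}
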