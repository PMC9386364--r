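# A compact scene is enough for structural checks; the full default scene
# is exercised in test-acceptance.R.
small_config <- function(seed = 5, ...) {
  scene_config(n_plots = 4L, plot_rows = 16L, plot_cols = 16L, seed = seed, ...)
}

test_that("scene generation is bit-identical under the same config", {
  a <- generate_scene(small_config())
  b <- generate_scene(small_config())
  expect_identical(a$cubes, b$cubes)
  expect_identical(a$truth, b$truth)
  c <- generate_scene(small_config(seed = 6))
  expect_false(identical(a$cubes[[1]]$pixels, c$cubes[[1]]$pixels))
})

test_that("every cube has matching ground truth and the LAI law holds", {
  sc <- generate_scene(small_config())
  expect_setequal(names(sc$cubes), sc$truth$sample_id)
  expect_equal(nrow(sc$truth), 16L)  # 4 plots x 4 stages
  expect_equal(lai_from_samples(sc$truth$LA_total_m2, sc$truth$rho),
               sc$truth$LAI, tolerance = 1e-9)
  for (st in names(sc$config$lai_range)) {
    r <- sc$config$lai_range[[st]]
    lai <- sc$truth$LAI[sc$truth$stage == st]
    expect_true(all(lai >= r[1] & lai <= r[2]), label = st)
  }
  expect_true(all(sc$cubes[[1]]$pixels >= 0 & sc$cubes[[1]]$pixels <= 1))
})

test_that("an LAI = 0 plot is pure background plus noise", {
  cfg <- small_config()
  cube <- generate_plot(cfg, lai = 0, stage = "tillering", seed = 77)
  sp <- cfg$spectra
  bg <- function(w) {
    i <- match(w, sp$wavelength_nm)
    0.5 * sp$soil[i] + 0.5 * sp$water[i]   # flooded tillering background
  }
  ndvi_bg <- (bg(800) - bg(670)) / (bg(800) + bg(670))
  got <- plot_vi(compute_vi(cube, "NDVI"))
  expect_lt(abs(got - ndvi_bg), 0.06)
  # later stages sit on bare soil
  cube2 <- generate_plot(cfg, lai = 0, stage = "jointing", seed = 78)
  soil_ndvi <- (sp$soil[sp$wavelength_nm == 800] - sp$soil[sp$wavelength_nm == 670]) /
               (sp$soil[sp$wavelength_nm == 800] + sp$soil[sp$wavelength_nm == 670])
  expect_lt(abs(plot_vi(compute_vi(cube2, "NDVI")) - soil_ndvi), 0.06)
})

test_that("plot-mean NIR and NDVI are non-decreasing in LAI pre-heading", {
  cfg <- small_config()
  lais <- c(0.5, 1.5, 3, 4.5, 6)
  stats <- vapply(seq_along(lais), function(i) {
    nir <- ndvi <- 0
    for (s in 1:4) {   # average a few realizations to tame sampling noise
      cube <- generate_plot(cfg, lais[i], "jointing", seed = 300 + 10 * i + s)
      nir <- nir + mean(cube_band(cube, 800)) / 4
      ndvi <- ndvi + plot_vi(compute_vi(cube, "NDVI")) / 4
    }
    c(nir, ndvi)
  }, numeric(2))
  expect_true(all(diff(stats[1, ]) > -0.01))
  expect_true(all(diff(stats[2, ]) > -0.01))
})

test_that("NDVI saturates between LAI 4 and 8 while the fused index does not", {
  cfg <- small_config()
  feat <- function(lai) {
    v <- e <- 0
    for (s in 1:5) {
      cube <- generate_plot(cfg, lai, "jointing", seed = 900 + round(lai) * 20 + s)
      v <- v + plot_vi(compute_vi(cube, "NDVI")) / 5
      e <- e + plot_energy(energy_texture(haar_decompose(
        cube_band(cube, 800, na_mask = FALSE)))) / 5
    }
    c(vi = v, wt = v * e)
  }
  f4 <- feat(4); f8 <- feat(8)
  rel_vi <- (f8["vi"] - f4["vi"]) / f4["vi"]
  rel_wt <- (f8["wt"] - f4["wt"]) / f4["wt"]
  expect_lt(rel_vi, rel_wt)
})

test_that("calibration targets carry the eight tarp reflectances and invert", {
  cfg <- small_config()
  tg0 <- generate_targets(cfg, noise = FALSE)
  expect_setequal(unique(tg0$targets$reflectance),
                  c(0.03, 0.06, 0.12, 0.24, 0.36, 0.48, 0.56, 0.80))
  fit <- fit_empirical_line(tg0$targets, 800)
  expect_equal(fit$gain, tg0$true_gain, tolerance = 1e-12)
  expect_equal(fit$offset, tg0$true_offset, tolerance = 1e-12)

  tg <- generate_targets(cfg, seed = 31, noise = TRUE)
  fitn <- fit_empirical_line(tg$targets, 800)
  dn <- tg$targets$mean_DN[tg$targets$wavelength_nm == 800]
  se <- sqrt(fitn$rmse^2 * 8 / 6 / sum((dn - mean(dn))^2))
  expect_lt(abs(fitn$gain - tg$true_gain), 3 * se + 1e-15)
})

test_that("the DN round trip through calibration recovers reflectance", {
  cfg <- small_config()
  cube <- generate_plot(cfg, 3, "jointing", seed = 12)
  dn <- dn_from_reflectance(cube, cfg, seed = 13, noise = FALSE)
  corr <- fit_empirical_lines(generate_targets(cfg, noise = FALSE)$targets,
                              cube$bandmap)
  back <- apply_correction(dn, corr)
  expect_equal(back$pixels, cube$pixels, tolerance = 1e-10)
})

test_that("scenes survive a disk round trip", {
  sc <- generate_scene(scene_config(n_plots = 2L, plot_rows = 8L,
                                    plot_cols = 8L, seed = 3))
  dir <- withr::local_tempdir()
  write_scene(sc, dir)
  back <- read_scene(dir)
  expect_setequal(names(back$cubes), names(sc$cubes))
  id <- names(sc$cubes)[1]
  expect_identical(back$cubes[[id]]$pixels, sc$cubes[[id]]$pixels)
  expect_equal(back$truth$LAI[match(sc$truth$sample_id, back$truth$sample_id)],
               sc$truth$LAI)
})
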