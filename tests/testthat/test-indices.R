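test_that("exactly the twelve expected indices are registered", {
  defs <- list_indices()
  expect_length(defs, 12)
  expect_setequal(names(defs),
                  c("NDVI", "GNDVI", "NDRE", "SR", "CI_red_edge", "CI_green",
                    "WDRVI", "MTCI", "EVI2", "OSAVI", "RVI", "VARI"))
  expect_setequal(defs$VARI$wavelengths, c(550, 670))
  expect_equal(defs$WDRVI$parameters$alpha, 0.2)
  for (d in defs)
    expect_true(all(d$wavelengths %in% c(550, 670, 720, 800)))
})

test_that("scalar index algebra matches hand arithmetic", {
  expect_equal(vi_value("NDVI", list("800" = 0.3, "670" = 0.3)), 0)
  expect_equal(vi_value("CI_red_edge", list("800" = 0.8, "720" = 0.4)), 1)
  expect_equal(vi_value("WDRVI", list("800" = 0.5, "670" = 0.1)), 0)
  expect_equal(vi_value("EVI2", list("800" = 0.5, "670" = 0.1)),
               2.5 * 0.4 / 1.74, tolerance = 1e-12)
  expect_error(vi_value("NDVI", list("800" = 0.3)), class = "wtvi_contract_error")
  expect_error(vi_value("NOPE", list()), class = "wtvi_contract_error")
})

test_that("all 12 formulas match the independent scalar reference", {
  tuples <- withr::with_seed(99, matrix(runif(4 * 250, 0.01, 0.99), ncol = 4))
  colnames(tuples) <- c("r550", "r670", "r720", "r800")
  for (nm in names(list_indices())) {
    got <- vi_value(nm, list("550" = tuples[, 1], "670" = tuples[, 2],
                             "720" = tuples[, 3], "800" = tuples[, 4]))
    want <- vi_reference(nm, tuples[, 1], tuples[, 2], tuples[, 3], tuples[, 4])
    expect_equal(got, want, tolerance = 1e-12, label = nm)
  }
})

test_that("normalized-difference indices stay within [-1, 1]", {
  tuples <- withr::with_seed(7, matrix(runif(4 * 500, 1e-3, 1), ncol = 4))
  for (nm in c("NDVI", "GNDVI", "NDRE", "VARI")) {
    v <- vi_value(nm, list("550" = tuples[, 1], "670" = tuples[, 2],
                           "720" = tuples[, 3], "800" = tuples[, 4]))
    expect_true(all(v >= -1 & v <= 1), label = nm)
  }
})

test_that("compute_vi on a constant cube equals the scalar formula everywhere", {
  bands <- c("550" = 0.12, "670" = 0.05, "720" = 0.25, "800" = 0.46)
  px <- array(rep(bands, each = 16), dim = c(4, 4, 4))
  cube <- reflectance_cube(px, band_map(c(550, 670, 720, 800)))
  for (nm in names(list_indices())) {
    img <- compute_vi(cube, nm)
    expect_true(all(img$valid))
    expect_equal(unique(as.vector(img$values)),
                 vi_value(nm, as.list(bands)), tolerance = 1e-12, label = nm)
  }
})

test_that("NDVI is monotone in the R800/R670 ratio", {
  ratio <- withr::with_seed(5, sort(runif(100, 0.2, 20)))
  ndvi <- (ratio - 1) / (ratio + 1)
  got <- vi_value("NDVI", list("800" = ratio, "670" = rep(1, 100)))
  expect_equal(got, ndvi, tolerance = 1e-12)
  expect_true(all(diff(got) > 0))
})

test_that("zero denominators and masked pixels invalidate rather than blow up", {
  px <- array(0.4, dim = c(2, 2, 4))
  px[1, 1, ] <- 0                      # all bands zero: NDVI denominator 0
  cube <- reflectance_cube(px, band_map(c(550, 670, 720, 800)))
  cube$mask[2, 2] <- TRUE
  img <- compute_vi(cube, "NDVI")
  expect_false(img$valid[1, 1])
  expect_false(img$valid[2, 2])
  expect_true(img$valid[1, 2])
  expect_true(all(is.na(img$values[!img$valid])))
  # plot mean uses only valid pixels; all-invalid errors
  expect_equal(plot_vi(img), 0)
  allbad <- compute_vi(reflectance_cube(array(0, dim = c(2, 2, 4)),
                                        band_map(c(550, 670, 720, 800))), "NDVI")
  expect_error(plot_vi(allbad), class = "wtvi_degenerate_error")
})

test_that("plot_vi averages valid pixels over the ROI", {
  px <- array(0.5, dim = c(4, 4, 4))
  px[, 1:2, 1] <- 0.1                  # make VARI differ across halves
  cube <- rand_cube(4, 4, seed = 31)
  img <- structure(list(values = matrix(c(rep(0.2, 8), rep(0.4, 8)), 4, 4),
                        name = "x", valid = matrix(TRUE, 4, 4)),
                   class = "wtvi_vi_image")
  expect_equal(plot_vi(img), 0.3)
  expect_equal(plot_vi(img, plot_roi("p", 0, 0, 4, 2)), 0.2)
})

test_that("the classical OSAVI/RVI variant switches to the red band", {
  b <- list("550" = 0.12, "670" = 0.05, "720" = 0.25, "800" = 0.46)
  expect_equal(vi_value("RVI", b, variant = "classical"), 0.46 / 0.05)
  expect_equal(vi_value("RVI", b, variant = "paper"), 0.46 / 0.25)
  expect_equal(vi_value("OSAVI", b, variant = "classical"),
               1.16 * (0.46 - 0.05) / (0.46 + 0.05 + 0.16), tolerance = 1e-12)
})
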