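# Registry of the twelve vegetation indices.
#
# Each entry gives the band reflectances it needs (by center wavelength,
# nm), a value function and the denominator(s) whose vanishing makes a
# pixel invalid.  `b` is a named list of band matrices/scalars keyed by
# wavelength; `p` carries parameters (currently only alpha for WDRVI).
#
# OSAVI and RVI are registered in their red-edge (720 nm) forms, as used
# in the source tables for this camera; `variant = "classical"` switches
# them to the textbook red-band (670 nm) forms.
.vi_registry <- function(variant = c("paper", "classical")) {
  variant <- match.arg(variant)
  r <- list(
    NDVI = list(
      wavelengths = c(670, 800),
      value = function(b, p) (b$`800` - b$`670`) / (b$`800` + b$`670`),
      den   = function(b, p) b$`800` + b$`670`),
    GNDVI = list(
      wavelengths = c(550, 800),
      value = function(b, p) (b$`800` - b$`550`) / (b$`800` + b$`550`),
      den   = function(b, p) b$`800` + b$`550`),
    NDRE = list(
      wavelengths = c(720, 800),
      value = function(b, p) (b$`800` - b$`720`) / (b$`800` + b$`720`),
      den   = function(b, p) b$`800` + b$`720`),
    SR = list(
      wavelengths = c(550, 800),
      value = function(b, p) b$`800` / b$`550`,
      den   = function(b, p) b$`550`),
    CI_red_edge = list(
      wavelengths = c(720, 800),
      value = function(b, p) b$`800` / b$`720` - 1,
      den   = function(b, p) b$`720`),
    CI_green = list(
      wavelengths = c(550, 800),
      value = function(b, p) b$`800` / b$`550` - 1,
      den   = function(b, p) b$`550`),
    WDRVI = list(
      wavelengths = c(670, 800),
      value = function(b, p) (p$alpha * b$`800` - b$`670`) / (p$alpha * b$`800` + b$`670`),
      den   = function(b, p) p$alpha * b$`800` + b$`670`),
    MTCI = list(
      wavelengths = c(670, 720, 800),
      value = function(b, p) (b$`800` - b$`720`) / (b$`720` - b$`670`),
      den   = function(b, p) b$`720` - b$`670`),
    EVI2 = list(
      wavelengths = c(670, 800),
      value = function(b, p) 2.5 * (b$`800` - b$`670`) / (1 + b$`800` + 2.4 * b$`670`),
      den   = function(b, p) 1 + b$`800` + 2.4 * b$`670`),
    OSAVI = list(
      wavelengths = c(720, 800),
      value = function(b, p) (1 + 0.16) * (b$`800` - b$`720`) / (b$`800` + b$`720` + 0.16),
      den   = function(b, p) b$`800` + b$`720` + 0.16),
    RVI = list(
      wavelengths = c(720, 800),
      value = function(b, p) b$`800` / b$`720`,
      den   = function(b, p) b$`720`),
    VARI = list(
      wavelengths = c(550, 670),
      value = function(b, p) (b$`550` - b$`670`) / (b$`550` + b$`670`),
      den   = function(b, p) b$`550` + b$`670`)
  )
  if (variant == "classical") {
    r$OSAVI <- list(
      wavelengths = c(670, 800),
      value = function(b, p) (1 + 0.16) * (b$`800` - b$`670`) / (b$`800` + b$`670` + 0.16),
      den   = function(b, p) b$`800` + b$`670` + 0.16)
    r$RVI <- list(
      wavelengths = c(670, 800),
      value = function(b, p) b$`800` / b$`670`,
      den   = function(b, p) b$`670`)
  }
  r
}

#' List the available vegetation index definitions
#'
#' Twelve indices are registered: NDVI, GNDVI, NDRE, SR, CI_red_edge,
#' CI_green, WDRVI, MTCI, EVI2, OSAVI, RVI, VARI.  All draw on the 550,
#' 670, 720 and 800 nm bands only.  WDRVI has a weighting parameter
#' `alpha`, default 0.2.
#'
#' @param variant `"paper"` (default) registers OSAVI and RVI in their
#'   red-edge (720 nm) forms; `"classical"` uses the textbook red-band
#'   (670 nm) forms.  See the methods vignette for why both exist.
#' @return named list of `wtvi_vi_definition` objects with elements
#'   `name`, `wavelengths` and `parameters`.
#' @examples
#' names(list_indices())
#' list_indices()$VARI$wavelengths
#' @export
list_indices <- function(variant = c("paper", "classical")) {
  variant <- match.arg(variant)
  reg <- .vi_registry(variant)
  out <- lapply(names(reg), function(nm) {
    structure(list(name = nm,
                   wavelengths = reg[[nm]]$wavelengths,
                   parameters = if (nm == "WDRVI") list(alpha = 0.2) else list(),
                   variant = variant),
              class = "wtvi_vi_definition")
  })
  names(out) <- names(reg)
  out
}

#' Evaluate a vegetation index as scalar algebra
#'
#' Applies the index formula to scalar (or vector) band reflectances,
#' without validity masking.  Used for quick calculations and as the
#' element-wise kernel of [compute_vi()].
#'
#' @param name index name, see [list_indices()].
#' @param bands named list or vector of band reflectances keyed by
#'   wavelength, e.g. `list("670" = 0.05, "800" = 0.45)`.
#' @param alpha WDRVI weighting parameter (default 0.2).
#' @param variant formula variant, see [list_indices()].
#' @return numeric index value(s).
#' @examples
#' vi_value("CI_red_edge", list("800" = 0.8, "720" = 0.4))  # 1
#' @export
vi_value <- function(name, bands, alpha = 0.2, variant = "paper") {
  reg <- .vi_registry(variant)
  if (!name %in% names(reg))
    wtvi_abort(sprintf("unknown vegetation index: %s", name))
  def <- reg[[name]]
  b <- as.list(bands)
  have <- names(b)
  need <- as.character(def$wavelengths)
  if (!all(need %in% have))
    wtvi_abort(sprintf("%s needs bands %s; missing %s", name,
                       paste(need, collapse = ", "),
                       paste(setdiff(need, have), collapse = ", ")))
  def$value(b, list(alpha = alpha))
}

#' Compute a vegetation index image from a reflectance cube
#'
#' Evaluates the index formula per pixel.  Pixels whose denominator has
#' absolute value below `eps`, that fall on the nodata mask, or that
#' evaluate non-finite are flagged invalid rather than propagating
#' infinities; invalid pixels are excluded from plot means.
#'
#' @param cube a [reflectance_cube()].
#' @param index index name or a definition from [list_indices()].
#' @param alpha WDRVI weighting parameter (default 0.2).
#' @param variant formula variant, see [list_indices()].
#' @param eps denominator tolerance (default 1e-12).
#' @return A `wtvi_vi_image`: list with `values` (H x W matrix), `name`,
#'   `valid` (logical H x W).
#' @export
compute_vi <- function(cube, index, alpha = 0.2, variant = "paper", eps = 1e-12) {
  stopifnot(inherits(cube, "wtvi_cube"))
  name <- if (inherits(index, "wtvi_vi_definition")) index$name else as.character(index)
  reg <- .vi_registry(variant)
  if (!name %in% names(reg))
    wtvi_abort(sprintf("unknown vegetation index: %s", name))
  def <- reg[[name]]
  b <- lapply(def$wavelengths, function(w) cube_band(cube, w, na_mask = FALSE))
  names(b) <- as.character(def$wavelengths)
  p <- list(alpha = alpha)
  vals <- def$value(b, p)
  den <- def$den(b, p)
  valid <- !cube$mask & is.finite(vals) & abs(den) >= eps
  vals[!valid] <- NA_real_
  structure(list(values = vals, name = name, valid = valid),
            class = "wtvi_vi_image")
}

#' Plot-level mean of a vegetation index image
#'
#' Mean of the valid pixels inside the ROI — the per-plot statistic used
#' for model fitting.
#'
#' @param vi_image a [compute_vi()] result.
#' @param roi a [plot_roi()]; `NULL` (default) averages the whole image.
#' @return scalar mean VI.
#' @export
plot_vi <- function(vi_image, roi = NULL) {
  stopifnot(inherits(vi_image, "wtvi_vi_image"))
  v <- vi_image$values; ok <- vi_image$valid
  if (!is.null(roi)) {
    stopifnot(inherits(roi, "wtvi_roi"))
    if (roi$row_max > nrow(v) || roi$col_max > ncol(v))
      wtvi_abort("ROI exceeds VI image bounds")
    rows <- (roi$row_min + 1L):roi$row_max
    cols <- (roi$col_min + 1L):roi$col_max
    v <- v[rows, cols]; ok <- ok[rows, cols]
  }
  if (!any(ok))
    wtvi_abort("no valid pixels in ROI", kind = "degenerate")
  mean(v[ok])
}
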