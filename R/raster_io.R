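#' Band map for a multiband cube
#'
#' A band map ties band storage order to band center wavelengths, so that
#' downstream code can address bands by wavelength (e.g. "the 800 nm band")
#' rather than by position.  Wavelengths follow the 12-band Mini-MCA layout
#' by default but any unique set can be supplied.
#'
#' @param wavelengths integer-ish vector of band center wavelengths in nm;
#'   must be unique.
#' @param bandwidths full-width bandwidths in nm, recycled to
#'   `length(wavelengths)`.
#' @return A `wtvi_bandmap`: data frame with columns `wavelength_nm`,
#'   `band_index` (1-based storage position) and `bandwidth_nm`.
#' @examples
#' band_map(c(550, 670, 720, 800))
#' @export
band_map <- function(wavelengths, bandwidths = 10) {
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) < 1L || anyNA(wavelengths))
    wtvi_abort("band map needs at least one finite wavelength")
  if (anyDuplicated(wavelengths))
    wtvi_abort("band wavelengths must be unique")
  bm <- data.frame(
    wavelength_nm = wavelengths,
    band_index    = seq_along(wavelengths),
    bandwidth_nm  = rep_len(as.numeric(bandwidths), length(wavelengths))
  )
  class(bm) <- c("wtvi_bandmap", "data.frame")
  bm
}

#' Default Mini-MCA 12-band map
#'
#' Center wavelengths 490-950 nm; 900 and 950 nm have wider bandwidths
#' (20 and 40 nm).
#' @return A [band_map()] with 12 bands.
#' @export
mca12_bandmap <- function() {
  band_map(
    wavelengths = c(490, 520, 550, 570, 670, 680, 700, 720, 800, 850, 900, 950),
    bandwidths  = c(10, 10, 10, 10, 10, 10, 10, 10, 10, 10, 20, 40)
  )
}

#' Resolve a wavelength to a band storage index
#'
#' @param bandmap a [band_map()].
#' @param wavelength band center wavelength in nm.
#' @return 1-based band index into the cube's third dimension.
#' @export
band_index <- function(bandmap, wavelength) {
  stopifnot(inherits(bandmap, "wtvi_bandmap"))
  i <- match(wavelength, bandmap$wavelength_nm)
  if (is.na(i))
    wtvi_abort(sprintf("wavelength %s nm not present in band map (have: %s)",
                       wavelength, paste(bandmap$wavelength_nm, collapse = ", ")))
  bandmap$band_index[i]
}

#' Construct a reflectance cube
#'
#' The cube is the package's in-memory image container: an H x W x B array
#' of unitless reflectance (or raw DN before calibration) plus a band map
#' and a nodata mask.  nodata is a mask, not a sentinel value, so a
#' reflectance of exactly 0 is a legal observation.
#'
#' @param pixels numeric H x W x B array (H rows, W columns, B bands).
#' @param bandmap a [band_map()] with B entries.
#' @param mask logical H x W matrix; `TRUE` marks nodata pixels excluded
#'   from all statistics.  Defaults to all-`FALSE`.
#' @return A `wtvi_cube` list with elements `pixels`, `bandmap`, `mask`.
#' @export
reflectance_cube <- function(pixels, bandmap, mask = NULL) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L)
    wtvi_abort("pixels must be an H x W x B array")
  d <- dim(pixels)
  stopifnot(inherits(bandmap, "wtvi_bandmap"))
  if (d[3] != nrow(bandmap))
    wtvi_abort(sprintf("cube has %d bands but band map describes %d",
                       d[3], nrow(bandmap)), kind = "io")
  if (is.null(mask)) mask <- matrix(FALSE, d[1], d[2])
  if (!is.logical(mask) || !identical(dim(mask), d[1:2]))
    wtvi_abort("mask must be a logical H x W matrix matching the cube")
  structure(list(pixels = pixels, bandmap = bandmap, mask = mask),
            class = "wtvi_cube")
}

#' @export
dim.wtvi_cube <- function(x) dim(x$pixels)

#' @export
print.wtvi_cube <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<wtvi_cube> %d x %d pixels, %d bands (%s nm), %d masked\n",
              d[1], d[2], d[3],
              paste(x$bandmap$wavelength_nm, collapse = "/"),
              sum(x$mask)))
  invisible(x)
}

#' Extract one band of a cube as a matrix
#'
#' Masked pixels are returned as `NA` so they cannot silently enter
#' statistics.
#'
#' @inheritParams band_index
#' @param cube a [reflectance_cube()].
#' @param na_mask replace masked pixels with `NA` (default `TRUE`).
#' @return numeric H x W matrix.
#' @export
cube_band <- function(cube, wavelength, na_mask = TRUE) {
  stopifnot(inherits(cube, "wtvi_cube"))
  m <- cube$pixels[, , band_index(cube$bandmap, wavelength), drop = TRUE]
  m <- matrix(m, dim(cube$pixels)[1], dim(cube$pixels)[2])
  if (na_mask) m[cube$mask] <- NA_real_
  m
}

#' Rectangular plot region of interest
#'
#' Coordinates are 0-based, half-open `[min, max)`, row-major — the
#' convention of the on-disk ROI files — so a full H x W image is
#' `(0, 0, H, W)`.  This makes the mapping to the half-resolution LL
#' sub-band (integer halving) unambiguous.
#'
#' @param plot_id character plot identifier.
#' @param row_min,col_min,row_max,col_max integer pixel bounds, 0-based
#'   half-open.
#' @return A `wtvi_roi` list.
#' @export
plot_roi <- function(plot_id, row_min, col_min, row_max, col_max) {
  v <- c(row_min, col_min, row_max, col_max)
  if (anyNA(v) || any(v != trunc(v)) || any(v < 0))
    wtvi_abort("ROI bounds must be non-negative integers")
  if (!(row_min < row_max) || !(col_min < col_max))
    wtvi_abort("ROI must satisfy row_min < row_max and col_min < col_max")
  if ((row_max - row_min) < 2 || (col_max - col_min) < 2)
    wtvi_abort("ROI must cover at least 2 x 2 pixels")
  structure(list(plot_id = as.character(plot_id),
                 row_min = as.integer(row_min), col_min = as.integer(col_min),
                 row_max = as.integer(row_max), col_max = as.integer(col_max)),
            class = "wtvi_roi")
}

#' Clip a cube to a plot ROI
#'
#' @param cube a [reflectance_cube()].
#' @param roi a [plot_roi()]; must lie within the cube bounds.
#' @return A `wtvi_cube` of shape `(row_max - row_min) x (col_max - col_min) x B`
#'   whose values equal the corresponding slice of the source.
#' @export
clip_roi <- function(cube, roi) {
  stopifnot(inherits(cube, "wtvi_cube"), inherits(roi, "wtvi_roi"))
  d <- dim(cube$pixels)
  if (roi$row_max > d[1] || roi$col_max > d[2])
    wtvi_abort(sprintf("ROI [%d,%d)x[%d,%d) exceeds cube %d x %d",
                       roi$row_min, roi$row_max, roi$col_min, roi$col_max,
                       d[1], d[2]))
  rows <- (roi$row_min + 1L):roi$row_max
  cols <- (roi$col_min + 1L):roi$col_max
  reflectance_cube(cube$pixels[rows, cols, , drop = FALSE], cube$bandmap,
                   cube$mask[rows, cols, drop = FALSE])
}

#' Leaf area index from destructive plant samples
#'
#' Field protocol: three bundles of plants are dug out per plot and their
#' total one-sided leaf area measured; with planting density `rho`
#' (bundles per square meter), `LAI = (LA_total / 3) * rho`.
#'
#' @param la_total total leaf area of the three sampled bundles, m^2.
#' @param rho planting density, bundles per m^2 (default 22.5, the field
#'   density used throughout).
#' @return LAI, unitless.
#' @examples
#' lai_from_samples(0.4, 22.5)  # 3
#' @export
lai_from_samples <- function(la_total, rho = 22.5) {
  if (!all(is.finite(la_total)) || any(la_total < 0))
    wtvi_abort("la_total must be finite and >= 0")
  if (!all(is.finite(rho)) || any(rho <= 0))
    wtvi_abort("rho must be finite and > 0")
  (la_total / 3) * rho
}

# ---------------------------------------------------------------------------
# Plain-text cube container.
#
# The interchange format is a self-describing whitespace/'#' text file:
# header comment lines carry dims, wavelengths, bandwidths; then H*W 0/1
# mask values and H*W*B pixel values in R column-major order, printed with
# 17 significant digits so the write/read round trip is exact for doubles.
# (A GDAL-backed GeoTIFF reader is deliberately not bundled: the text
# container keeps the package dependency-light and the test suite fully
# offline; see the methods vignette.)
# ---------------------------------------------------------------------------

#' Write a cube to the plain-text container
#'
#' @param cube a [reflectance_cube()].
#' @param path output file path (conventionally `.cube`).
#' @return `path`, invisibly.
#' @seealso [read_cube()]
#' @export
write_cube <- function(cube, path) {
  stopifnot(inherits(cube, "wtvi_cube"))
  d <- dim(cube$pixels)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# wtvi-cube v1",
    sprintf("# dims %d %d %d", d[1], d[2], d[3]),
    paste("# wavelengths", paste(format(cube$bandmap$wavelength_nm, trim = TRUE), collapse = " ")),
    paste("# bandwidths", paste(format(cube$bandmap$bandwidth_nm, trim = TRUE), collapse = " "))
  ), con)
  writeLines(paste(as.integer(cube$mask), collapse = " "), con)
  vals <- sprintf("%.17g", as.vector(cube$pixels))
  writeLines(paste(vals, collapse = " "), con)
  invisible(path)
}

#' Read a cube from the plain-text container
#'
#' @param path file written by [write_cube()].
#' @param bandmap optional [band_map()]; if supplied, its band count must
#'   match the file and it replaces the band map stored in the header.
#' @return A `wtvi_cube`.
#' @export
read_cube <- function(path, bandmap = NULL) {
  if (!file.exists(path))
    wtvi_abort(sprintf("no such cube file: %s", path), kind = "io")
  hdr <- readLines(path, n = 4L)
  if (length(hdr) < 4L || !startsWith(hdr[1], "# wtvi-cube"))
    wtvi_abort(sprintf("not a wtvi cube file: %s", path), kind = "io")
  d <- as.integer(strsplit(sub("^# dims ", "", hdr[2]), " ")[[1]])
  wl <- as.numeric(strsplit(sub("^# wavelengths ", "", hdr[3]), " ")[[1]])
  bw <- as.numeric(strsplit(sub("^# bandwidths ", "", hdr[4]), " ")[[1]])
  if (length(d) != 3L || anyNA(d))
    wtvi_abort(sprintf("corrupt dims header in %s", path), kind = "io")
  if (!is.null(bandmap)) {
    stopifnot(inherits(bandmap, "wtvi_bandmap"))
    if (nrow(bandmap) != d[3])
      wtvi_abort(sprintf("file has %d bands but band map describes %d",
                         d[3], nrow(bandmap)), kind = "io")
  } else {
    bandmap <- band_map(wl, bw)
  }
  vals <- scan(path, what = double(), comment.char = "#", quiet = TRUE)
  npx <- d[1] * d[2]
  if (length(vals) != npx + npx * d[3])
    wtvi_abort(sprintf("corrupt cube payload in %s", path), kind = "io")
  mask <- matrix(vals[seq_len(npx)] != 0, d[1], d[2])
  px <- array(vals[-seq_len(npx)], dim = d)
  reflectance_cube(px, bandmap, mask)
}

#' Read / write ground-truth LAI tables
#'
#' CSV columns: `plot_id, LA_total_m2, rho, LAI`.  If `LAI` is missing it
#' is derived with [lai_from_samples()]; if present it is checked against
#' the derivation to 1e-9.
#'
#' @param path CSV path.
#' @return data frame with the four columns.
#' @export
read_ground_truth <- function(path) {
  if (!file.exists(path))
    wtvi_abort(sprintf("no such ground-truth file: %s", path), kind = "io")
  gt <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plot_id", "LA_total_m2", "rho")
  if (!all(need %in% names(gt)))
    wtvi_abort(paste("ground-truth CSV must have columns:",
                     paste(need, collapse = ", ")), kind = "io")
  derived <- lai_from_samples(gt$LA_total_m2, gt$rho)
  if (!"LAI" %in% names(gt)) {
    gt$LAI <- derived
  } else if (any(abs(gt$LAI - derived) > 1e-9)) {
    wtvi_abort("stored LAI disagrees with (LA_total/3)*rho beyond 1e-9", kind = "io")
  }
  gt
}

#' @rdname read_ground_truth
#' @param gt ground-truth data frame.
#' @export
write_ground_truth <- function(gt, path) {
  utils::write.csv(gt, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write ROI tables
#'
#' CSV columns: `plot_id, row_min, col_min, row_max, col_max` (0-based,
#' half-open).
#'
#' @param path CSV path.
#' @return named list of [plot_roi()] keyed by `plot_id`.
#' @export
read_rois <- function(path) {
  if (!file.exists(path))
    wtvi_abort(sprintf("no such ROI file: %s", path), kind = "io")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plot_id", "row_min", "col_min", "row_max", "col_max")
  if (!all(need %in% names(df)))
    wtvi_abort(paste("ROI CSV must have columns:", paste(need, collapse = ", ")),
               kind = "io")
  rois <- lapply(seq_len(nrow(df)), function(i)
    plot_roi(df$plot_id[i], df$row_min[i], df$col_min[i], df$row_max[i], df$col_max[i]))
  names(rois) <- df$plot_id
  rois
}

#' @rdname read_rois
#' @param rois list of [plot_roi()].
#' @export
write_rois <- function(rois, path) {
  df <- do.call(rbind, lapply(rois, function(r)
    data.frame(plot_id = r$plot_id, row_min = r$row_min, col_min = r$col_min,
               row_max = r$row_max, col_max = r$col_max)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
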