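#' Fit the empirical-line DN-to-reflectance correction for one band
#'
#' Under clear-sky acquisition, reflectance is related to the raw digital
#' number (DN) by a per-band straight line fitted over calibration targets
#' of known reflectance (the "empirical line" method).  The fit is ordinary
#' least squares of reflectance on mean DN.
#'
#' @param targets data frame with columns `target_id`, `wavelength_nm`,
#'   `reflectance` (in `[0, 1]`) and `mean_DN` (>= 0); rows for other
#'   wavelengths are ignored.
#' @param wavelength band center wavelength in nm to fit.
#' @return A `wtvi_correction`: list with `wavelength_nm`, `gain`
#'   (reflectance per DN), `offset` (reflectance), `rmse` (residual RMSE of
#'   the fit) and `n_targets`.
#' @examples
#' tg <- data.frame(target_id = c("a", "b"), wavelength_nm = 800,
#'                  reflectance = c(0.03, 0.80), mean_DN = c(100, 1000))
#' fit_empirical_line(tg, 800)
#' @export
fit_empirical_line <- function(targets, wavelength) {
  need <- c("reflectance", "mean_DN")
  if (!is.data.frame(targets) || !all(need %in% names(targets)))
    wtvi_abort("targets must be a data frame with reflectance and mean_DN columns")
  t <- targets
  if ("wavelength_nm" %in% names(t)) t <- t[t$wavelength_nm == wavelength, , drop = FALSE]
  if (nrow(t) < 2L)
    wtvi_abort(sprintf("need >= 2 calibration targets for %s nm, got %d",
                       wavelength, nrow(t)), kind = "degenerate")
  if (any(t$reflectance < 0 | t$reflectance > 1))
    wtvi_abort("target reflectance must lie in [0, 1]")
  if (any(t$mean_DN < 0))
    wtvi_abort("target mean_DN must be >= 0")
  dn <- t$mean_DN; rf <- t$reflectance
  if (var(dn) == 0)
    wtvi_abort("all target DN values identical: degenerate design", kind = "degenerate")
  gain <- sum((dn - mean(dn)) * (rf - mean(rf))) / sum((dn - mean(dn))^2)
  offset <- mean(rf) - gain * mean(dn)
  resid <- rf - (gain * dn + offset)
  structure(list(wavelength_nm = wavelength, gain = gain, offset = offset,
                 rmse = sqrt(mean(resid^2)), n_targets = nrow(t)),
            class = "wtvi_correction")
}

#' Fit empirical lines for every band of a band map
#'
#' @inheritParams fit_empirical_line
#' @param bandmap a [band_map()].
#' @return named list of `wtvi_correction`, keyed by wavelength.
#' @export
fit_empirical_lines <- function(targets, bandmap) {
  stopifnot(inherits(bandmap, "wtvi_bandmap"))
  cor <- lapply(bandmap$wavelength_nm, function(w) fit_empirical_line(targets, w))
  names(cor) <- as.character(bandmap$wavelength_nm)
  cor
}

#' Convert a raw-DN cube to reflectance
#'
#' Applies `reflectance = gain * DN + offset` per band, then clips to
#' `[0, 1]`.  The nodata mask is propagated unchanged.  The transform is
#' affine before clipping; clipping exists only to keep downstream index
#' algebra defined.
#'
#' @param dn_cube a [reflectance_cube()] holding raw DN values.
#' @param corrections named list from [fit_empirical_lines()] (or a list of
#'   [fit_empirical_line()] results keyed by wavelength); must cover every
#'   band of the cube.
#' @param clip clip the result to `[0, 1]` (default `TRUE`).
#' @return A reflectance `wtvi_cube`.
#' @export
apply_correction <- function(dn_cube, corrections, clip = TRUE) {
  stopifnot(inherits(dn_cube, "wtvi_cube"))
  wl <- dn_cube$bandmap$wavelength_nm
  missing <- setdiff(as.character(wl), names(corrections))
  if (length(missing))
    wtvi_abort(paste("no fitted correction for band(s):",
                     paste(missing, collapse = ", ")))
  px <- dn_cube$pixels
  for (i in seq_along(wl)) {
    co <- corrections[[as.character(wl[i])]]
    px[, , i] <- co$gain * px[, , i] + co$offset
  }
  if (clip) px <- pmin(pmax(px, 0), 1)
  reflectance_cube(px, dn_cube$bandmap, dn_cube$mask)
}

#' Extract target mean DN from imagery over tarp ROIs
#'
#' Convenience for workflows where the calibration tarps are visible in the
#' DN imagery: averages the unmasked DN of each band over each tarp ROI and
#' pairs it with the tarp's nominal reflectance.
#'
#' @param dn_cube DN cube containing the tarps.
#' @param tarp_rois named list of [plot_roi()], one per tarp.
#' @param reflectances numeric vector of nominal tarp reflectances, same
#'   order/length as `tarp_rois` (band-constant gray tarps).
#' @return targets data frame as accepted by [fit_empirical_line()].
#' @export
extract_targets <- function(dn_cube, tarp_rois, reflectances) {
  stopifnot(inherits(dn_cube, "wtvi_cube"),
            length(tarp_rois) == length(reflectances))
  wl <- dn_cube$bandmap$wavelength_nm
  out <- list()
  for (i in seq_along(tarp_rois)) {
    sub <- clip_roi(dn_cube, tarp_rois[[i]])
    for (w in wl) {
      m <- cube_band(sub, w)
      out[[length(out) + 1L]] <- data.frame(
        target_id = tarp_rois[[i]]$plot_id, wavelength_nm = w,
        reflectance = reflectances[i], mean_DN = mean(m, na.rm = TRUE))
    }
  }
  do.call(rbind, out)
}
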