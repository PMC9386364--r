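#' Level-1 2D Haar wavelet decomposition
#'
#' Splits an image into the four level-1 sub-bands LL (approximation), LH,
#' HL and HH (detail), by filtering rows and columns with the Haar filter
#' pair and downsampling by two.  With the default orthonormal convention
#' (low-pass `(1, 1)/sqrt(2)`, high-pass `(1, -1)/sqrt(2)`) each 2 x 2
#' input block `(a, b; c, d)` maps to
#' `LL = (a + b + c + d)/2`, `LH = (a + b - c - d)/2`,
#' `HL = (a - b + c - d)/2`, `HH = (a - b - c + d)/2`,
#' so the transform is orthogonal: it reconstructs perfectly and conserves
#' energy (Parseval), which makes the LL "energy" texture literal.
#' A trailing odd row/column is cropped before the transform.
#'
#' @param x numeric matrix, at least 2 x 2.
#' @param normalization `"orthonormal"` (default) or `"average"`.  The
#'   averaging convention divides by 4/2 instead of 2/2 so LL is the plain
#'   2 x 2 block mean; it does not conserve energy and exists only for
#'   sensitivity checks.
#' @param wavelength optional source band wavelength (nm), carried as
#'   metadata.
#' @return A `wtvi_dwt`: list with matrices `LL`, `LH`, `HL`, `HH` of shape
#'   `floor(H/2) x floor(W/2)`, plus `normalization` and `wavelength`.
#' @examples
#' d <- haar_decompose(matrix(1, 2, 2))
#' d$LL  # 2
#' @export
haar_decompose <- function(x, normalization = c("orthonormal", "average"),
                           wavelength = NULL) {
  normalization <- match.arg(normalization)
  if (!is.matrix(x) || !is.numeric(x))
    wtvi_abort("input must be a numeric matrix")
  h <- nrow(x); w <- ncol(x)
  if (h < 2L || w < 2L)
    wtvi_abort("image must be at least 2 x 2 for a level-1 decomposition")
  h2 <- h %/% 2L; w2 <- w %/% 2L
  x <- x[seq_len(2L * h2), seq_len(2L * w2), drop = FALSE]  # crop to even
  io <- seq(1L, 2L * h2, by = 2L); ie <- io + 1L
  jo <- seq(1L, 2L * w2, by = 2L); je <- jo + 1L
  a <- x[io, jo, drop = FALSE]; b <- x[io, je, drop = FALSE]
  c <- x[ie, jo, drop = FALSE]; d <- x[ie, je, drop = FALSE]
  s <- if (normalization == "orthonormal") c(2, 2) else c(4, 2)
  structure(list(
    LL = (a + b + c + d) / s[1],
    LH = (a + b - c - d) / s[2],
    HL = (a - b + c - d) / s[2],
    HH = (a - b - c + d) / s[2],
    normalization = normalization,
    wavelength = wavelength
  ), class = "wtvi_dwt")
}

#' Inverse of [haar_decompose()]
#'
#' @param decomp a `wtvi_dwt`.
#' @return the reconstructed matrix (even-cropped original, exactly for the
#'   orthonormal convention).
#' @export
haar_reconstruct <- function(decomp) {
  stopifnot(inherits(decomp, "wtvi_dwt"))
  LL <- decomp$LL; LH <- decomp$LH; HL <- decomp$HL; HH <- decomp$HH
  dims <- lapply(list(LL, LH, HL, HH), dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L)
    wtvi_abort("sub-band shapes disagree")
  if (decomp$normalization == "average") {   # undo the unit-sum scaling first
    LL <- LL * 2
  }
  a <- (LL + LH + HL + HH) / 2
  b <- (LL + LH - HL - HH) / 2
  c <- (LL - LH + HL - HH) / 2
  d <- (LL - LH - HL + HH) / 2
  h2 <- nrow(LL); w2 <- ncol(LL)
  out <- matrix(0, 2L * h2, 2L * w2)
  io <- seq(1L, 2L * h2, by = 2L); ie <- io + 1L
  jo <- seq(1L, 2L * w2, by = 2L); je <- jo + 1L
  out[io, jo] <- a; out[io, je] <- b; out[ie, jo] <- c; out[ie, je] <- d
  out
}

# Reflect-pad a matrix by one pixel on every side (mirror about the edge
# pixel, edge not repeated): row order  2, 1..n, n-1.
reflect_pad1 <- function(m) {
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L) wtvi_abort("matrix too small to reflect-pad")
  m2 <- m[c(2L, seq_len(n), n - 1L), , drop = FALSE]
  m2[, c(2L, seq_len(k), k - 1L), drop = FALSE]
}

#' LL-sub-band energy texture (Ene)
#'
#' The texture feature is the local wavelet energy of the approximation
#' sub-band: for each LL pixel, the mean of the squared LL coefficients
#' over its 3 x 3 neighborhood, `Ene = (1/9) * sum |f(x, y)|^2`.  Borders
#' use reflect padding so the output has the same shape as LL.
#'
#' @param decomp a `wtvi_dwt` from [haar_decompose()], or an LL matrix.
#' @return A `wtvi_energy`: list with `values` (same shape as LL, all
#'   >= 0) and `wavelength`.
#' @examples
#' d <- haar_decompose(matrix(0.25, 8, 8))
#' energy_texture(d)$values[1, 1]  # (0.5)^2 = 0.25
#' @export
energy_texture <- function(decomp) {
  if (inherits(decomp, "wtvi_dwt")) {
    LL <- decomp$LL; wl <- decomp$wavelength
  } else if (is.matrix(decomp)) {
    LL <- decomp; wl <- NULL
  } else wtvi_abort("expected a wtvi_dwt or an LL matrix")
  if (nrow(LL) < 3L || ncol(LL) < 3L)
    wtvi_abort("LL sub-band must be at least 3 x 3 for the 3 x 3 energy window")
  p <- reflect_pad1(LL)^2
  n <- nrow(LL); k <- ncol(LL)
  acc <- matrix(0, n, k)
  for (di in 0:2) for (dj in 0:2)
    acc <- acc + p[di + seq_len(n), dj + seq_len(k)]
  structure(list(values = acc / 9, wavelength = wl), class = "wtvi_energy")
}

#' Plot-level energy over an ROI
#'
#' The energy image lives at LL (half) resolution; full-resolution ROI
#' bounds are mapped down by integer halving (`floor(bound / 2)` on both
#' ends of the half-open interval) and the energy is averaged over the
#' resulting window.
#'
#' @param energy a [energy_texture()] result.
#' @param roi a [plot_roi()] in full-resolution coordinates; `NULL`
#'   (default) averages the whole image.
#' @return scalar mean energy.
#' @export
plot_energy <- function(energy, roi = NULL) {
  stopifnot(inherits(energy, "wtvi_energy"))
  v <- energy$values
  if (is.null(roi)) return(mean(v))
  stopifnot(inherits(roi, "wtvi_roi"))
  r0 <- roi$row_min %/% 2L; r1 <- roi$row_max %/% 2L
  c0 <- roi$col_min %/% 2L; c1 <- roi$col_max %/% 2L
  if (r1 <= r0 || c1 <= c0)
    wtvi_abort("ROI collapses to zero pixels at LL resolution", kind = "degenerate")
  if (r1 > nrow(v) || c1 > ncol(v))
    wtvi_abort("ROI exceeds energy image bounds")
  mean(v[(r0 + 1L):r1, (c0 + 1L):c1])
}
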