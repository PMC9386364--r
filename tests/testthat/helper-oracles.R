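# Independent oracles used across the suite.  Everything here is a
# deliberately different route from the production code: matrix-form Haar,
# brute-force windows, normal-equations OLS.

# One-level orthonormal Haar analysis matrix for even n: first n/2 rows are
# pairwise sums / sqrt(2), last n/2 rows pairwise differences / sqrt(2).
haar_matrix <- function(n) {
  stopifnot(n %% 2 == 0)
  T <- matrix(0, n, n)
  for (i in seq_len(n / 2)) {
    T[i, 2 * i - 1] <- T[i, 2 * i] <- 1 / sqrt(2)
    T[n / 2 + i, 2 * i - 1] <- 1 / sqrt(2)
    T[n / 2 + i, 2 * i] <- -1 / sqrt(2)
  }
  T
}

# Full 2D separable transform Y = T_h X T_w'; blocks are the sub-bands.
haar_oracle <- function(x) {
  h2 <- nrow(x) %/% 2; w2 <- ncol(x) %/% 2
  x <- x[seq_len(2 * h2), seq_len(2 * w2), drop = FALSE]
  Y <- haar_matrix(2 * h2) %*% x %*% t(haar_matrix(2 * w2))
  list(LL = Y[seq_len(h2), seq_len(w2), drop = FALSE],
       LH = Y[h2 + seq_len(h2), seq_len(w2), drop = FALSE],
       HL = Y[seq_len(h2), w2 + seq_len(w2), drop = FALSE],
       HH = Y[h2 + seq_len(h2), w2 + seq_len(w2), drop = FALSE])
}

# Brute-force 3x3 windowed mean of squares with reflect padding (mirror
# about the edge pixel, edge not repeated), O(n^2 * 9) double loop.
energy_oracle <- function(LL) {
  n <- nrow(LL); k <- ncol(LL)
  ref <- function(i, m) { if (i < 1) 2 - i else if (i > m) 2 * m - i else i }
  out <- matrix(0, n, k)
  for (i in seq_len(n)) for (j in seq_len(k)) {
    s <- 0
    for (di in -1:1) for (dj in -1:1)
      s <- s + LL[ref(i + di, n), ref(j + dj, k)]^2
    out[i, j] <- s / 9
  }
  out
}

# OLS by explicit normal equations.
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  as.numeric(solve(t(X) %*% X, t(X) %*% y))  # (intercept, slope)
}

# Small random reflectance cube on the four VI wavelengths.
rand_cube <- function(h = 8, w = 8, wavelengths = c(550, 670, 720, 800),
                      seed = 1) {
  withr::with_seed(seed, {
    px <- array(runif(h * w * length(wavelengths), 0.01, 0.99),
                dim = c(h, w, length(wavelengths)))
    reflectance_cube(px, band_map(wavelengths))
  })
}

# Scalar reference formulas for all 12 indices, written independently of
# the package registry (straight from the index definitions).
vi_reference <- function(name, r550, r670, r720, r800, alpha = 0.2) {
  switch(name,
    NDVI        = (r800 - r670) / (r800 + r670),
    GNDVI       = (r800 - r550) / (r800 + r550),
    NDRE        = (r800 - r720) / (r800 + r720),
    SR          = r800 / r550,
    CI_red_edge = r800 / r720 - 1,
    CI_green    = r800 / r550 - 1,
    WDRVI       = (alpha * r800 - r670) / (alpha * r800 + r670),
    MTCI        = (r800 - r720) / (r720 - r670),
    EVI2        = 2.5 * (r800 - r670) / (1 + r800 + 2.4 * r670),
    OSAVI       = 1.16 * (r800 - r720) / (r800 + r720 + 0.16),
    RVI         = r800 / r720,
    VARI        = (r550 - r670) / (r550 + r670),
    stop("unknown index in reference"))
}
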