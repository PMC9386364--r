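#' Fuse a vegetation index with the wavelet energy texture
#'
#' The fused index is the plain product `WT-VI = VI * Ene`, taken at plot
#' level.  The sign of the VI is preserved (VARI can be negative).
#'
#' @param vi plot-level vegetation index value.
#' @param ene plot-level LL energy texture value.
#' @return WT-VI scalar.
#' @export
fuse <- function(vi, ene) {
  if (!all(is.finite(vi)) || !all(is.finite(ene)))
    wtvi_abort("fuse() requires finite inputs")
  vi * ene
}

#' Simple linear LAI model fit
#'
#' Ordinary least squares of `lai` on `feature`:
#' `lai = slope * feature + intercept`, with `R^2 = 1 - SS_res/SS_tot`,
#' `RMSE = sqrt(SS_res / n)` (population form, conventional for held-out
#' evaluation) and `rRMSE = 100 * RMSE / mean(lai)`.
#'
#' @param feature numeric predictor vector.
#' @param lai numeric response vector, same length.
#' @return list with `slope`, `intercept`, `r2`, `rmse`, `rrmse`, `n`.
#' @export
fit_linear <- function(feature, lai) {
  x <- as.numeric(feature); y <- as.numeric(lai)
  if (length(x) != length(y)) wtvi_abort("feature and lai lengths differ")
  if (length(x) < 3L) wtvi_abort("need at least 3 samples", kind = "degenerate")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    wtvi_abort("non-finite values in regression inputs")
  if (var(x) == 0) wtvi_abort("zero-variance feature", kind = "degenerate")
  sstot <- sum((y - mean(y))^2)
  if (sstot == 0) wtvi_abort("constant response: R^2 undefined", kind = "degenerate")
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  intercept <- mean(y) - slope * mean(x)
  res <- y - (slope * x + intercept)
  rmse <- sqrt(mean(res^2))
  list(slope = slope, intercept = intercept,
       r2 = 1 - sum(res^2) / sstot,
       rmse = rmse,
       rrmse = 100 * rmse / mean(y),
       n = length(x))
}

# Deterministic near-equal fold assignment: shuffle once under `seed`,
# then cut into k contiguous chunks; the first (n mod k) folds take one
# extra sample.  Returns a list of index vectors.
make_folds <- function(n, k, seed) {
  if (k < 2L) wtvi_abort("k must be >= 2")
  if (k > n) wtvi_abort("k must not exceed the number of samples")
  ord <- withr::with_seed(seed, sample.int(n))
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, ends[-k] + 1L)
  lapply(seq_len(k), function(i) sort(ord[starts[i]:ends[i]]))
}

#' k-fold cross-validated evaluation of a linear LAI model
#'
#' Samples are shuffled once under `seed` and divided into `k` disjoint,
#' exhaustive, near-equal folds.  For each fold the model is fitted on the
#' other `k - 1` folds and evaluated on the held-out fold: the fitted slope
#' `Coef_i`, held-out `R_i^2` (about the held-out mean), `RMSE_i` and
#' `rRMSE_i` (percent of the held-out mean LAI).  The reported aggregates
#' are the plain means over folds:
#' `Coef^2 = mean(Coef_i^2)`, `R^2 = mean(R_i^2)`, `RMSE = mean(RMSE_i)`,
#' `rRMSE = mean(rRMSE_i)`.  The final coefficients are refit on all data.
#'
#' @inheritParams fit_linear
#' @param k number of folds (default 10).
#' @param seed integer RNG seed for the fold shuffle (required for
#'   reproducibility).
#' @param name optional feature label carried into the result.
#' @return A `wtvi_cv`: list with `name`, `k`, `seed`, aggregate `coef2`,
#'   `r2`, `rmse`, `rrmse`, per-fold data frame `folds`, full-data `slope`
#'   and `intercept`, and `n`.
#' @export
kfold_evaluate <- function(feature, lai, k = 10, seed, name = NA_character_) {
  x <- as.numeric(feature); y <- as.numeric(lai)
  if (length(x) != length(y)) wtvi_abort("feature and lai lengths differ")
  if (!is_number(seed)) wtvi_abort("an integer seed is required")
  n <- length(x)
  folds <- make_folds(n, as.integer(k), as.integer(seed))
  per <- lapply(seq_along(folds), function(i) {
    test <- folds[[i]]; train <- setdiff(seq_len(n), test)
    fit <- fit_linear(x[train], y[train])
    pred <- fit$slope * x[test] + fit$intercept
    res <- y[test] - pred
    rmse <- sqrt(mean(res^2))
    sstot <- sum((y[test] - mean(y[test]))^2)
    data.frame(fold = i, n_test = length(test),
               slope = fit$slope, intercept = fit$intercept,
               r2 = if (sstot > 0) 1 - sum(res^2) / sstot else NA_real_,
               rmse = rmse,
               rrmse = 100 * rmse / mean(y[test]))
  })
  per <- do.call(rbind, per)
  full <- fit_linear(x, y)
  structure(list(
    name = name, k = as.integer(k), seed = as.integer(seed),
    coef2 = mean(per$slope^2),
    r2 = mean(per$r2),
    rmse = mean(per$rmse),
    rrmse = mean(per$rrmse),
    folds = per,
    slope = full$slope, intercept = full$intercept,
    n = n
  ), class = "wtvi_cv")
}

#' @export
print.wtvi_cv <- function(x, ...) {
  cat(sprintf("<wtvi_cv> %s: k=%d  R2=%.4f  RMSE=%.4f  rRMSE=%.2f%%  LAI = %.3f*x + %.3f\n",
              ifelse(is.na(x$name), "<feature>", x$name),
              x$k, x$r2, x$rmse, x$rrmse, x$slope, x$intercept))
  invisible(x)
}

#' Build the plot-level feature table
#'
#' For every plot-date in a scene (or any list of cubes with matching ROIs
#' and ground truth): computes each VI image and its plot mean, the level-1
#' Haar LL energy of the texture band and its plot mean (Ene), and the
#' fused `WT-VI = VI * Ene`.
#'
#' @param scene a `wtvi_scene` from [generate_scene()], or a list with
#'   elements `cubes` (named list of cubes), `rois` (named list of
#'   [plot_roi()] keyed like `cubes`) and `truth` (data frame with
#'   `sample_id`, `LAI`, optionally `stage`).
#' @param indices character vector of index names (default: all 12).
#' @param texture_band wavelength (nm) whose LL energy is the texture
#'   feature; default 800.
#' @param alpha WDRVI parameter.
#' @param variant VI formula variant, see [list_indices()].
#' @return data frame with one row per plot-date: `sample_id`, `stage`,
#'   `LAI`, `Ene`, `VI_<name>` and `WTVI_<name>` columns.
#' @export
build_feature_table <- function(scene, indices = names(list_indices()),
                                texture_band = 800, alpha = 0.2,
                                variant = "paper") {
  cubes <- scene$cubes; rois <- scene$rois; truth <- scene$truth
  if (is.null(cubes) || is.null(truth))
    wtvi_abort("scene must provide cubes and truth")
  ids <- names(cubes)
  rows <- lapply(ids, function(id) {
    cube <- cubes[[id]]
    roi <- rois[[id]]
    tr <- truth[truth$sample_id == id, , drop = FALSE]
    if (nrow(tr) != 1L)
      wtvi_abort(sprintf("no unique ground truth for sample %s", id), kind = "io")
    dec <- haar_decompose(cube_band(cube, texture_band, na_mask = FALSE),
                          wavelength = texture_band)
    ene <- plot_energy(energy_texture(dec), roi)
    vi <- vapply(indices, function(nm)
      plot_vi(compute_vi(cube, nm, alpha = alpha, variant = variant), roi),
      numeric(1))
    row <- data.frame(sample_id = id,
                      stage = if ("stage" %in% names(tr)) tr$stage else NA_character_,
                      LAI = tr$LAI, Ene = ene)
    for (nm in indices) {
      row[[paste0("VI_", nm)]] <- vi[[nm]]
      row[[paste0("WTVI_", nm)]] <- fuse(vi[[nm]], ene)
    }
    row
  })
  do.call(rbind, rows)
}

#' Cross-validate and rank every feature of a feature table
#'
#' Runs [kfold_evaluate()] against measured LAI for every `VI_*` and
#' `WTVI_*` column (and `Ene` if present) and returns the results sorted
#' by mean cross-validated R^2, descending; ties broken by lower mean RMSE,
#' then by name.
#'
#' @param table a [build_feature_table()] result (or CSV read of one).
#' @param k folds (default 10).
#' @param seed RNG seed for the fold shuffle, shared by every feature so
#'   folds are identical across features.
#' @param lai_col response column name (default `"LAI"`).
#' @return list of `wtvi_cv`, sorted; see [cv_summary()].
#' @export
rank_indices <- function(table, k = 10, seed, lai_col = "LAI") {
  stopifnot(is.data.frame(table), lai_col %in% names(table))
  feats <- grep("^(VI|WTVI)_", names(table), value = TRUE)
  if ("Ene" %in% names(table)) feats <- c(feats, "Ene")
  if (!length(feats)) wtvi_abort("no VI_/WTVI_ feature columns found")
  res <- lapply(feats, function(f)
    kfold_evaluate(table[[f]], table[[lai_col]], k = k, seed = seed, name = f))
  ord <- order(-vapply(res, `[[`, numeric(1), "r2"),
               vapply(res, `[[`, numeric(1), "rmse"),
               vapply(res, `[[`, character(1), "name"))
  res[ord]
}

#' Summarize a list of cross-validation results as a data frame
#'
#' @param results list of `wtvi_cv` (e.g. from [rank_indices()]).
#' @return data frame with one row per feature: `name`, `k`, `coef2`,
#'   `r2`, `rmse`, `rrmse`, `slope`, `intercept`, `n`.
#' @export
cv_summary <- function(results) {
  if (inherits(results, "wtvi_cv")) results <- list(results)
  do.call(rbind, lapply(results, function(r)
    data.frame(name = r$name, k = r$k, coef2 = r$coef2, r2 = r$r2,
               rmse = r$rmse, rrmse = r$rrmse,
               slope = r$slope, intercept = r$intercept, n = r$n)))
}
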