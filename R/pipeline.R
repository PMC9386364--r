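#' Pipeline run configuration
#'
#' Collects the knobs of the end-to-end workflow.  Defaults reproduce the
#' reference configuration: 800 nm texture band, all 12 indices, k = 10
#' cross-validation folds.
#'
#' @param scene_dir directory containing a scene written by
#'   [write_scene()]; `NULL` to generate a synthetic scene in memory from
#'   `scene`.
#' @param scene a [scene_config()] used when `scene_dir` is `NULL`.
#' @param out_dir output directory for `features.csv` and `results.json`;
#'   `NULL` keeps results in memory only.
#' @param texture_band texture band wavelength, nm (default 800).
#' @param indices character vector of VI names (default all 12).
#' @param k cross-validation folds (default 10).
#' @param seed integer seed for fold shuffling (and scene generation when
#'   the scene config carries none... the scene config seed always wins for
#'   generation; this seed drives the CV shuffle).
#' @param calibrate if `TRUE`, round-trip the imagery through synthetic DN
#'   and the fitted empirical-line correction before feature extraction,
#'   exercising the calibration stage (default `FALSE`).
#' @param alpha WDRVI parameter (default 0.2).
#' @param variant VI formula variant (default `"paper"`).
#' @return a `wtvi_run_config` list.
#' @export
run_config <- function(scene_dir = NULL, scene = NULL, out_dir = NULL,
                       texture_band = 800, indices = names(list_indices()),
                       k = 10, seed = 42, calibrate = FALSE,
                       alpha = 0.2, variant = "paper") {
  if (is.null(scene_dir) && is.null(scene))
    wtvi_abort("run_config() needs scene_dir or a scene_config", kind = "io")
  structure(list(scene_dir = scene_dir, scene = scene, out_dir = out_dir,
                 texture_band = texture_band, indices = indices,
                 k = as.integer(k), seed = as.integer(seed),
                 calibrate = isTRUE(calibrate), alpha = alpha,
                 variant = variant),
            class = "wtvi_run_config")
}

# Stable md5 of the canonical JSON echo of a config (file-based so only
# base tools:: is needed).  Output destinations are excluded: the hash
# identifies the computation, and reruns into different directories must
# produce identical artifacts.
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  cfg$scene <- if (!is.null(cfg$scene)) {
    s <- unclass(cfg$scene); s$spectra <- as.list(s$spectra); s
  }
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the end-to-end workflow
#'
#' Executes: scene acquisition (load from disk or synthesize) → optional
#' DN round-trip with empirical-line calibration → vegetation indices →
#' level-1 Haar LL energy texture → plot-level extraction and WT-VI fusion
#' → k-fold cross-validated ranking of all 24 features (12 VIs + 12
#' WT-VIs, plus Ene itself).  Identical configs give byte-identical
#' outputs; every written artifact embeds the config hash.
#'
#' @param config a [run_config()].
#' @param quiet suppress stage logging (default `FALSE`).
#' @return list with `features` (the plot feature table), `results`
#'   (sorted list of `wtvi_cv`), `summary` (data frame), `config_hash`,
#'   and `paths` (written files, if `out_dir` was set).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "wtvi_run_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  hash <- config_hash(config)
  say("[scene] %s", if (is.null(config$scene_dir)) "generating synthetic scene"
      else paste("loading", config$scene_dir))
  scene <- if (is.null(config$scene_dir)) generate_scene(config$scene)
           else read_scene(config$scene_dir)

  if (config$calibrate) {
    if (is.null(scene$config))
      wtvi_abort("calibrate=TRUE requires a generated scene (known DN line)", kind = "io")
    say("[calibrate] fitting empirical line on %d targets",
        length(scene$config$target_reflectances))
    tg <- generate_targets(scene$config)
    corr <- fit_empirical_lines(tg$targets, scene$cubes[[1]]$bandmap)
    scene$cubes <- lapply(seq_along(scene$cubes), function(i)
      apply_correction(
        dn_from_reflectance(scene$cubes[[i]], scene$config,
                            seed = scene$config$seed + i), corr))
    names(scene$cubes) <- scene$truth$sample_id
  }

  say("[features] %d plot-dates, %d indices, texture band %d nm",
      length(scene$cubes), length(config$indices), config$texture_band)
  features <- build_feature_table(scene, indices = config$indices,
                                  texture_band = config$texture_band,
                                  alpha = config$alpha,
                                  variant = config$variant)
  say("[cv] k = %d, seed = %d", config$k, config$seed)
  results <- rank_indices(features, k = config$k, seed = config$seed)
  summary <- cv_summary(results)

  paths <- NULL
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    fpath <- file.path(config$out_dir, "features.csv")
    rpath <- file.path(config$out_dir, "results.json")
    ftab <- features
    ftab[] <- lapply(ftab, function(col)
      if (is.numeric(col)) sprintf("%.15g", col) else col)
    con <- file(fpath, "w")
    writeLines(sprintf("# config_hash %s", hash), con)
    utils::write.csv(ftab, con, row.names = FALSE, quote = FALSE)
    close(con)
    jsonlite::write_json(
      list(config_hash = hash, k = config$k, seed = config$seed,
           results = summary),
      rpath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths <- c(features = fpath, results = rpath)
    say("[write] %s, %s", fpath, rpath)
  }
  list(features = features, results = results, summary = summary,
       config_hash = hash, paths = paths)
}

# ---------------------------------------------------------------------------
# Command-line interface.  `wtvi_main()` is the testable entry point used
# by the inst/cli/wtvi wrapper script; it returns an exit status instead
# of quitting: 0 success, 2 input error, 3 numerical/degenerate-data error.
# ---------------------------------------------------------------------------

cli_usage <- "usage: wtvi <simulate|calibrate|indices|texture|fit|run> [options]"

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic scene), `calibrate` (fit an
#' empirical line from a targets CSV and correct a DN cube), `indices`
#' (compute VI images), `texture` (LL energy of one band), `fit` (k-fold CV
#' on a feature table CSV), `run` (full pipeline on a scene directory).
#' Run `wtvi_main(c("run", "--help"))` etc. for per-command options.
#'
#' @param argv character vector of command-line arguments (excluding the
#'   program name).
#' @return integer exit status: 0 success, 2 input error, 3
#'   numerical/degenerate-data error.
#' @export
wtvi_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (length(argv) < 1L) { message(cli_usage); return(2L) }
  cmd <- argv[1]; rest <- argv[-1]
  handler <- switch(cmd,
    simulate = cli_simulate, calibrate = cli_calibrate,
    indices = cli_indices, texture = cli_texture,
    fit = cli_fit, run = cli_run, NULL)
  if (is.null(handler)) { message(cli_usage); return(2L) }
  tryCatch({ handler(rest); 0L },
    wtvi_io_error = function(e) { message("input error: ", conditionMessage(e)); 2L },
    wtvi_degenerate_error = function(e) { message("numerical error: ", conditionMessage(e)); 3L },
    wtvi_error = function(e) { message("error: ", conditionMessage(e)); 2L })
}

cli_simulate <- function(args) {
  opts <- optparse::parse_args(optparse::OptionParser(
    "wtvi simulate --seed INT --out DIR", list(
      optparse::make_option("--seed", type = "integer", default = 1L),
      optparse::make_option("--plots", type = "integer", default = 24L),
      optparse::make_option("--out", type = "character"))), args)
  if (is.null(opts$out)) wtvi_abort("--out is required", kind = "io")
  scene <- generate_scene(scene_config(n_plots = opts$plots, seed = opts$seed))
  write_scene(scene, opts$out)
  message("wrote scene to ", opts$out)
}

cli_calibrate <- function(args) {
  opts <- optparse::parse_args(optparse::OptionParser(
    "wtvi calibrate --targets CSV --in CUBE --out CUBE", list(
      optparse::make_option("--targets", type = "character"),
      optparse::make_option("--in", type = "character", dest = "input"),
      optparse::make_option("--out", type = "character"))), args)
  for (o in c("targets", "input", "out"))
    if (is.null(opts[[o]])) wtvi_abort(paste0("--", o, " is required"), kind = "io")
  if (!file.exists(opts$targets))
    wtvi_abort(paste("no such targets file:", opts$targets), kind = "io")
  targets <- utils::read.csv(opts$targets, stringsAsFactors = FALSE)
  cube <- read_cube(opts$input)
  corr <- fit_empirical_lines(targets, cube$bandmap)
  write_cube(apply_correction(cube, corr), opts$out)
  message("wrote reflectance cube to ", opts$out)
}

cli_indices <- function(args) {
  opts <- optparse::parse_args(optparse::OptionParser(
    "wtvi indices --in CUBE --index NAMES --out DIR", list(
      optparse::make_option("--in", type = "character", dest = "input"),
      optparse::make_option("--index", type = "character",
                            default = paste(names(list_indices()), collapse = ",")),
      optparse::make_option("--out", type = "character"))), args)
  if (is.null(opts$input) || is.null(opts$out))
    wtvi_abort("--in and --out are required", kind = "io")
  cube <- read_cube(opts$input)
  dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
  for (nm in strsplit(opts$index, ",")[[1]]) {
    vi <- compute_vi(cube, nm)
    out <- reflectance_cube(array(ifelse(vi$valid, vi$values, 0),
                                  dim = c(dim(vi$values), 1L)),
                            band_map(0), mask = !vi$valid)
    write_cube(out, file.path(opts$out, paste0(nm, ".cube")))
  }
  message("wrote VI images to ", opts$out)
}

cli_texture <- function(args) {
  opts <- optparse::parse_args(optparse::OptionParser(
    "wtvi texture --in CUBE --band NM --out CUBE", list(
      optparse::make_option("--in", type = "character", dest = "input"),
      optparse::make_option("--band", type = "integer", default = 800L),
      optparse::make_option("--out", type = "character"))), args)
  if (is.null(opts$input) || is.null(opts$out))
    wtvi_abort("--in and --out are required", kind = "io")
  cube <- read_cube(opts$input)
  ene <- energy_texture(haar_decompose(cube_band(cube, opts$band, na_mask = FALSE),
                                       wavelength = opts$band))
  out <- reflectance_cube(array(ene$values, dim = c(dim(ene$values), 1L)),
                          band_map(opts$band))
  write_cube(out, opts$out)
  message("wrote energy image to ", opts$out)
}

cli_fit <- function(args) {
  opts <- optparse::parse_args(optparse::OptionParser(
    "wtvi fit --table CSV --k INT --seed INT --out JSON", list(
      optparse::make_option("--table", type = "character"),
      optparse::make_option("--k", type = "integer", default = 10L),
      optparse::make_option("--seed", type = "integer", default = 42L),
      optparse::make_option("--out", type = "character"))), args)
  if (is.null(opts$table)) wtvi_abort("--table is required", kind = "io")
  if (!file.exists(opts$table))
    wtvi_abort(paste("no such feature table:", opts$table), kind = "io")
  tab <- utils::read.csv(opts$table, comment.char = "#", stringsAsFactors = FALSE)
  res <- rank_indices(tab, k = opts$k, seed = opts$seed)
  out <- cv_summary(res)
  if (!is.null(opts$out))
    jsonlite::write_json(list(k = opts$k, seed = opts$seed, results = out),
                         opts$out, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  print(utils::head(out, 10))
}

cli_run <- function(args) {
  opts <- optparse::parse_args(optparse::OptionParser(
    "wtvi run --scene DIR --k INT --seed INT --out DIR", list(
      optparse::make_option("--scene", type = "character"),
      optparse::make_option("--k", type = "integer", default = 10L),
      optparse::make_option("--seed", type = "integer", default = 42L),
      optparse::make_option("--band", type = "integer", default = 800L),
      optparse::make_option("--out", type = "character"))), args)
  if (is.null(opts$scene)) wtvi_abort("--scene is required", kind = "io")
  if (!dir.exists(opts$scene))
    wtvi_abort(paste("no such scene directory:", opts$scene), kind = "io")
  cfg <- run_config(scene_dir = opts$scene, out_dir = opts$out,
                    k = opts$k, seed = opts$seed, texture_band = opts$band)
  res <- run_pipeline(cfg)
  print(utils::head(res$summary, 10))
}
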