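# Orchestration: cube I/O, run configuration, and the end-to-end pipeline
# (simulate -> CWUE -> trend -> persistence/stability -> attribution) with a
# checksummed output manifest.

#' Write a raster cube to disk
#'
#' Lossless plain-text encoding: a long CSV (`year,row,col,value`, masked
#' cells written as the nodata sentinel) plus a JSON sidecar
#' (`<path>.json`) carrying grid origin/cell size/CRS, the time axis and
#' the sentinel. The encoding round-trips values, mask and time axis
#' bit-exactly through [read_cube()].
#'
#' @param cube a [raster_cube()].
#' @param path output CSV path.
#' @param nodata sentinel written at masked cells (default -9999).
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path, nodata = -9999) {
  stopifnot(inherits(cube, "raster_cube"))
  d <- dim(cube$values)
  # row fastest, then col, per year: matches as.vector() on a (y, x) matrix
  df <- data.frame(
    year = rep(cube$years, each = d[2] * d[3]),
    row = rep(rep(seq_len(d[2]), times = d[3]), times = d[1]),
    col = rep(rep(seq_len(d[3]), each = d[2]), times = d[1])
  )
  df$value <- as.vector(vapply(seq_len(d[1]), function(t) {
    v <- cube$values[t, , , drop = TRUE]
    v <- matrix(v, d[2], d[3])
    v[!cube$mask] <- nodata
    v[!is.finite(v)] <- nodata        # stray gaps become sentinel too
    as.vector(v)
  }, numeric(d[2] * d[3])))
  write.csv(format(df, digits = 17, scientific = FALSE, trim = TRUE),
            path, row.names = FALSE, quote = FALSE)
  meta <- list(origin = cube$grid$origin, cellsize = cube$grid$cellsize,
               crs = cube$grid$crs, years = cube$years, nodata = nodata,
               height = d[2], width = d[3])
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a raster cube written by [write_cube()]
#'
#' @param path CSV path; the `<path>.json` sidecar must sit beside it.
#' @return A [raster_cube()]. A cell is masked if it equals the nodata
#'   sentinel (or is non-finite) in ANY year: downstream stages need
#'   gap-free series.
#' @export
read_cube <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    stop("missing metadata sidecar: ", sidecar, call. = FALSE)
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  df <- read.csv(path)
  years <- as.integer(meta$years)
  h <- meta$height
  w <- meta$width
  if (nrow(df) != length(years) * h * w) {
    stop("file ", path, ": row count ", nrow(df),
         " inconsistent with ", length(years), " years on a ", h, "x", w,
         " grid", call. = FALSE)
  }
  vals <- array(NA_real_, c(length(years), h, w))
  for (t in seq_along(years)) {
    sub <- df[df$year == years[t], ]
    vals[t, , ] <- matrix(sub$value[order(sub$col, sub$row)], h, w)
  }
  bad <- !is.finite(vals) | (is.finite(vals) & vals == meta$nodata)
  mask <- !apply(bad, c(2, 3), any)
  vals[bad] <- NA_real_
  raster_cube(vals, years = years, mask = mask,
              grid = list(origin = as.numeric(meta$origin),
                          cellsize = meta$cellsize, crs = meta$crs))
}

#' Pipeline run configuration
#'
#' Exactly one of `scene` (a [scene_config()] block for synthetic input)
#' or `inputs` (named list of CSV cube paths: `npp`, `gpp`, `et`, and the
#' six driver names) must be given. The run `seed` propagates to every
#' stochastic stage.
#'
#' @param scene a [scene_config()], or `NULL` when reading from files.
#' @param inputs named list of cube paths, or `NULL` when simulating.
#' @param outdir output directory.
#' @param eemd an [eemd_config()].
#' @param alpha trend-significance level.
#' @param min_window R/S minimum window (`NULL` = adaptive).
#' @param search a [booster_search_space()].
#' @param indicator which CWUE indicator drives attribution:
#'   `"wue_npp"`, `"wue_gpp"` or `"cue"`.
#' @param n_background background rows for [shapley_values()].
#' @param seed master seed.
#' @return A `run_config` list.
#' @export
run_config <- function(scene = scene_config(), inputs = NULL,
                       outdir = tempfile("cwuetrend_run_"),
                       eemd = eemd_config(), alpha = 0.05,
                       min_window = NULL,
                       search = booster_search_space(),
                       indicator = c("wue_npp", "wue_gpp", "cue"),
                       n_background = 100L, seed = 1L) {
  indicator <- match.arg(indicator)
  if (is.null(scene) == is.null(inputs)) {
    stop("exactly one of `scene` or `inputs` must be provided",
         call. = FALSE)
  }
  if (!is.null(inputs)) {
    need <- c("npp", "gpp", "et", driver_names())
    miss <- setdiff(need, names(inputs))
    if (length(miss)) {
      stop("`inputs` missing required blocks: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  seed <- as.integer(seed)
  if (!is.null(scene)) scene$seed <- seed
  if (!is.null(eemd)) eemd$seed <- seed
  search$seed <- seed
  structure(list(scene = scene, inputs = inputs, outdir = outdir,
                 eemd = eemd, alpha = alpha, min_window = min_window,
                 search = search, indicator = indicator,
                 n_background = as.integer(n_background), seed = seed),
            class = "run_config")
}

write_table <- function(df, path) {
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) {
    format(v, digits = 15, scientific = FALSE, trim = TRUE)
  })
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes: scene simulation (or cube ingest) -> CWUE indicator cubes ->
#' EEMD trend classification -> Hurst/CV persistence-stability table ->
#' booster tuning and Shapley attribution with a dominant-driver map, and
#' writes every artifact as CSV/JSON under `config$outdir` together with a
#' `manifest.json` listing each file with its MD5 checksum and the stage
#' parameters. Identical config and seed reproduce byte-identical CSVs and
#' manifest checksums.
#'
#' @param config a [run_config()].
#' @return The manifest, invisibly (list with `files`, `parameters`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()["elapsed"]
  log_stage <- function(...) message("[cwuetrend ",
                                     sprintf("%7.1fs", proc.time()["elapsed"] - t0),
                                     "] ", ...)

  # stage 1: inputs
  if (!is.null(config$scene)) {
    log_stage("simulating scene ", config$scene$height, "x",
              config$scene$width, "x", config$scene$n_years)
    scn <- generate_scene(config$scene)
    npp <- scn$npp; gpp <- scn$gpp; et <- scn$et
    drivers <- scn$drivers
  } else {
    log_stage("reading input cubes")
    npp <- read_cube(config$inputs$npp)
    gpp <- read_cube(config$inputs$gpp)
    et <- read_cube(config$inputs$et)
    drivers <- lapply(config$inputs[driver_names()], read_cube)
    scn <- NULL
  }

  # stage 2: CWUE indicators
  log_stage("computing CWUE indicator cubes")
  cue <- compute_cue(npp, gpp)
  wue_npp <- compute_wue(npp, et)
  wue_gpp <- compute_wue(gpp, et)
  indicator_cube <- switch(config$indicator,
                           cue = cue, wue_npp = wue_npp, wue_gpp = wue_gpp)
  files <- character(0)
  add <- function(path) files <<- c(files, path)
  for (nm in c("cue", "wue_npp", "wue_gpp")) {
    cb <- switch(nm, cue = cue, wue_npp = wue_npp, wue_gpp = wue_gpp)
    p <- file.path(outdir, paste0(nm, ".csv"))
    write_cube(cb, p)
    add(p); add(paste0(p, ".json"))
  }
  basin <- purrr::map_dfr(
    list(cue = cue, wue_npp = wue_npp, wue_gpp = wue_gpp),
    function(cb) {
      s <- annual_mean_series(cb)
      tibble::tibble(year = s$years, mean = s$values,
                     rate = linear_rate(s))
    }, .id = "indicator")
  add(write_table(basin, file.path(outdir, "basin_annual_means.csv")))

  # stage 3: trend classification
  log_stage("classifying trend patterns (", sum(indicator_cube$mask),
            " pixels)")
  patterns <- classify_cube(indicator_cube, config$eemd,
                            alpha = config$alpha)
  add(write_table(as_tibble(patterns),
                  file.path(outdir, "pattern_map.csv")))
  add(write_table(patterns$area_fraction,
                  file.path(outdir, "pattern_area_fractions.csv")))

  # stage 4: persistence & stability
  log_stage("computing Hurst / CV grades")
  persist <- persistence_stability_table(indicator_cube, patterns,
                                         min_window = config$min_window)
  add(write_table(persist, file.path(outdir, "persistence_stability.csv")))

  # stage 5: attribution
  log_stage("building driver table")
  tab <- build_sample_table(indicator_cube, drivers)
  log_stage("tuning booster (", config$search$n_iter, " draws x ",
            config$search$k_folds, "-fold CV on ", nrow(tab), " rows)")
  fit <- tune_and_fit(tab, config$search)
  add(write_table(glance(fit$report),
                  file.path(outdir, "fit_metrics.csv")))
  jsonlite::write_json(
    c(fit$report$best_params,
      list(cv_rmse = fit$report$cv_rmse, cv_r2 = fit$report$cv_r2,
           test_rmse = fit$report$test_rmse, test_r2 = fit$report$test_r2)),
    file.path(outdir, "fit_report.json"), auto_unbox = TRUE, digits = NA)
  add(file.path(outdir, "fit_report.json"))

  log_stage("computing Shapley attribution (", nrow(tab), " samples, ",
            config$n_background, " background rows)")
  attr_res <- shapley_values(fit$model, tab,
                             background = config$n_background,
                             seed = config$seed)
  add(write_table(importance_ranking(attr_res),
                  file.path(outdir, "importance_ranking.csv")))
  shap_df <- dplyr::bind_cols(attr_res$keys, tibble::as_tibble(attr_res$shap))
  add(write_table(shap_df, file.path(outdir, "shap_values.csv")))
  dom <- dominant_driver_map(attr_res, grid_dim = attr(tab, "grid_dim"))
  add(write_table(dom$dominant_fraction,
                  file.path(outdir, "dominant_fractions.csv")))
  dom_df <- dom$pixel_importance[c("pixel_id", "row", "col", "dominant")]
  add(write_table(dom_df, file.path(outdir, "dominant_map.csv")))
  if (!is.null(scn)) {
    truth_df <- tibble::tibble(
      row = rep(seq_len(nrow(scn$truth$pattern)), ncol(scn$truth$pattern)),
      col = rep(seq_len(ncol(scn$truth$pattern)),
                each = nrow(scn$truth$pattern)),
      true_pattern = as.vector(scn$truth$pattern),
      true_dominant = as.vector(scn$truth$dominant)
    )
    add(write_table(truth_df, file.path(outdir, "scene_truth.csv")))
  }

  # manifest
  log_stage("writing manifest (", length(files), " files)")
  manifest <- list(
    parameters = list(
      seed = config$seed, alpha = config$alpha,
      indicator = config$indicator,
      eemd = unclass(config$eemd),
      search = unclass(config$search),
      n_background = config$n_background,
      scene = if (!is.null(config$scene)) {
        cf <- unclass(config$scene)
        cf$pattern_field <- NULL
        cf$dominant_field <- NULL
        cf
      }
    ),
    files = lapply(files, function(f) {
      list(name = basename(f), md5 = unname(tools::md5sum(f)))
    })
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
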