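# Five-class trend-pattern classification of secular trends.
#
# Labels: MONO_INC, MONO_DEC (monotone trends), INC_DEC, DEC_INC (one
# dominant interior extremum), NOT_SIGNIFICANT (no detectable tendency).

# Null calibration of the significance floor: (1 - alpha) quantiles of
# range(EEMD residual) / sd(raw - residual) on pure white noise, estimated
# from 1000 replicates per length with the default eemd_config(). Linear
# interpolation in log(n) and in the quantile level; lengths clamp to
# [10, 128] (at n < 10 the residual absorbs nearly the whole series and the
# ratio diverges).
null_range_quantiles <- function() {
  list(
    n = c(10, 12, 14, 16, 19, 24, 28, 32, 37, 48, 64, 96, 128),
    probs = c(0.90, 0.95, 0.99),
    q = matrix(c(
      3.9034, 6.7391, 21.9528,
      3.1583, 3.5850,  5.5250,
      3.0211, 3.4384,  4.4801,
      2.6878, 3.0906,  3.9811,
      2.2888, 2.7039,  3.4248,
      1.9354, 2.2081,  2.8058,
      1.7914, 2.0733,  2.5846,
      1.6351, 1.8390,  2.3340,
      1.4485, 1.6434,  2.0563,
      1.2519, 1.3857,  1.6816,
      1.0389, 1.1903,  1.4289,
      0.8595, 0.9702,  1.1909,
      0.7291, 0.8263,  1.0191
    ), ncol = 3, byrow = TRUE)
  )
}

# calibrated floor multiplier c(n, alpha): trend range below
# c * sd(raw - trend) is indistinguishable from the white-noise null
null_range_floor <- function(n, alpha) {
  tab <- null_range_quantiles()
  n <- min(max(n, min(tab$n)), max(tab$n))
  p <- min(max(1 - alpha, min(tab$probs)), max(tab$probs))
  by_n <- apply(tab$q, 2, function(col) {
    stats::approx(log(tab$n), col, xout = log(n))$y
  })
  stats::approx(tab$probs, by_n, xout = p)$y
}

#' Classify a secular trend into one of five variation patterns
#'
#' A pixel is `NOT_SIGNIFICANT` when the raw annual series shows no
#' significant monotonic tendency (two-sided Mann-Kendall test, i.e.
#' Kendall's tau of value against year, p >= `alpha`) AND the secular
#' trend's total range stays below a noise floor calibrated on the
#' white-noise null: the (1 - alpha) quantile of the residual-range to
#' oscillation-sd ratio that pure noise produces at this series length
#' (EMD residuals of noise are themselves smooth curves with substantial
#' range, so an uncalibrated floor misreads them as trends). Otherwise the
#' label follows the trend's shape: a dominant interior extremum whose
#' deviation from the endpoint chord reaches at least `hump_min_dev` of the
#' trend range gives `INC_DEC` (a maximum) or `DEC_INC` (a minimum) -- for
#' a genuine single-hump trend that deviation is comparable to the range
#' itself, while monotone-plus-wiggle shapes stay well below half -- and
#' otherwise the sign of (last - first) gives `MONO_INC`/`MONO_DEC`.
#'
#' @param trend secular trend [pixel_series()] (e.g. from
#'   [secular_trend()]).
#' @param raw the raw annual series the trend was extracted from.
#' @param alpha significance level of the Mann-Kendall test and of the
#'   null-calibrated amplitude floor (default 0.05).
#' @param noise_floor multiplier of `sd(raw - trend)` below which the trend
#'   range is treated as noise; `NULL` (default) uses the null-calibrated
#'   value for this length and `alpha`.
#' @param hump_min_dev minimum chord deviation of the dominant interior
#'   extremum, as a fraction of the trend range, for a hump call
#'   (default 0.5).
#' @return A length-1 character label, one of [trend_patterns()].
#' @examples
#' tr <- generate_trend_series("INC_DEC", 19, amplitude = 1, noise_sd = 0)
#' classify_pattern(tr, tr)
#' @export
classify_pattern <- function(trend, raw, alpha = 0.05,
                             noise_floor = NULL, hump_min_dev = 0.5) {
  trend <- as_pixel_series(trend)
  raw <- as_pixel_series(raw)
  if (length(trend) != length(raw) || length(trend) < 8) {
    stop("`trend` and `raw` must share length >= 8", call. = FALSE)
  }
  tv <- trend$values
  n <- length(tv)
  rng <- max(tv) - min(tv)
  osc_sd <- sd(raw$values - tv)
  if (is.null(noise_floor)) noise_floor <- null_range_floor(n, alpha)

  mk_p <- mann_kendall_p(raw$values)
  if (mk_p >= alpha && rng < noise_floor * osc_sd) {
    return("NOT_SIGNIFICANT")
  }
  if (rng == 0) return("NOT_SIGNIFICANT")   # constant trend, nothing to grade

  ext <- dominant_interior_extremum(tv, hump_min_dev)
  if (is.null(ext)) {
    if (tv[n] > tv[1]) return("MONO_INC")
    if (tv[n] < tv[1]) return("MONO_DEC")
    return("NOT_SIGNIFICANT")               # flat endpoints, no extremum
  }
  if (ext$type == "max") "INC_DEC" else "DEC_INC"
}

# two-sided Mann-Kendall p-value: Kendall's tau of value against time index
mann_kendall_p <- function(values) {
  if (sd(values) == 0) return(1)
  suppressWarnings(
    cor.test(values, seq_along(values), method = "kendall",
             alternative = "two.sided")$p.value
  )
}

# dominant interior extremum of a trend curve: local extrema whose deviation
# from the endpoint chord is at least `min_dev` of the trend range; among
# those, the one with the largest |deviation|. NULL when none survive.
dominant_interior_extremum <- function(tv, min_dev = 0.5) {
  n <- length(tv)
  rng <- max(tv) - min(tv)
  if (rng == 0 || n < 3) return(NULL)
  i <- 2:(n - 1)
  is_max <- tv[i] > tv[i - 1] & tv[i] > tv[i + 1]
  is_min <- tv[i] < tv[i - 1] & tv[i] < tv[i + 1]
  idx <- i[is_max | is_min]
  if (!length(idx)) return(NULL)
  chord <- tv[1] + (tv[n] - tv[1]) * (idx - 1) / (n - 1)
  dev <- tv[idx] - chord
  keep <- abs(dev) >= min_dev * rng
  if (!any(keep)) return(NULL)
  idx <- idx[keep]
  dev <- dev[keep]
  best <- which.max(abs(dev))
  list(index = idx[best],
       type = if (is_max[match(idx[best], i)]) "max" else "min",
       deviation = dev[best])
}

#' Interannual change rate
#'
#' Ordinary least-squares slope of value on year: the linear rate of change
#' in response units per year.
#'
#' @param series a [pixel_series()] or numeric vector, length >= 3.
#' @return The OLS slope (numeric scalar).
#' @examples
#' linear_rate(pixel_series(c(1, 2, 4), years = 0:2))  # 1.5
#' @export
linear_rate <- function(series) {
  s <- as_pixel_series(series)
  if (length(s) < 3) stop("need at least 3 points for a rate", call. = FALSE)
  yr <- as.numeric(s$years)
  if (var(yr) == 0) stop("zero variance in years", call. = FALSE)
  unname(cov(s$values, yr) / var(yr))
}

#' Classify every pixel of a cube
#'
#' Runs, for each unmasked pixel: [eemd()] -> [secular_trend()] ->
#' [classify_pattern()], plus [linear_rate()] on the raw series, and
#' aggregates area fractions per label over unmasked pixels.
#'
#' @param cube a [raster_cube()] with >= 8 time steps.
#' @param config an [eemd_config()]; each pixel's ensemble noise is seeded
#'   deterministically from `config$seed` and the pixel index.
#' @param alpha Mann-Kendall significance level (default 0.05).
#' @return A `pattern_map`: list with `labels` (`(y, x)` character matrix,
#'   `NA` at masked cells), `rate_map` (`(y, x)` numeric matrix of OLS
#'   slopes), and `area_fraction` (tibble `pattern`, `n_pixels`,
#'   `fraction`; fractions over unmasked pixels sum to 1).
#' @export
classify_cube <- function(cube, config = eemd_config(), alpha = 0.05) {
  stopifnot(inherits(cube, "raster_cube"))
  d <- dim(cube$values)
  if (d[1] < 8) stop("need >= 8 time steps to classify", call. = FALSE)
  labels <- matrix(NA_character_, d[2], d[3])
  rate_map <- matrix(NA_real_, d[2], d[3])
  pix_seeds <- matrix(withr::with_seed(config$seed,
                                       sample.int(.Machine$integer.max - 1L,
                                                  d[2] * d[3])), d[2], d[3])
  for (r in seq_len(d[2])) {
    for (c in seq_len(d[3])) {
      if (!cube$mask[r, c]) next
      s <- pixel_series(cube$values[, r, c], cube$years)
      cfg <- config
      cfg$seed <- pix_seeds[r, c]
      dec <- eemd(s, cfg)
      labels[r, c] <- classify_pattern(secular_trend(dec), s, alpha = alpha)
      rate_map[r, c] <- linear_rate(s)
    }
  }
  lab_valid <- labels[cube$mask]
  counts <- table(factor(lab_valid, levels = trend_patterns()))
  area <- tibble::tibble(
    pattern = trend_patterns(),
    n_pixels = as.integer(counts),
    fraction = as.numeric(counts) / max(1L, length(lab_valid))
  )
  structure(list(labels = labels, rate_map = rate_map,
                 area_fraction = area, mask = cube$mask, grid = cube$grid),
            class = "pattern_map")
}

#' @export
print.pattern_map <- function(x, ...) {
  cat("<pattern_map>\n")
  print(x$area_fraction)
  invisible(x)
}

#' Pattern map as a tibble
#'
#' @param x a `pattern_map` from [classify_cube()].
#' @param ... unused.
#' @return Tibble with `row`, `col`, `pattern`, `rate`.
#' @exportS3Method tibble::as_tibble
as_tibble.pattern_map <- function(x, ...) {
  idx <- which(x$mask, arr.ind = TRUE)
  tibble::tibble(row = idx[, 1], col = idx[, 2],
                 pattern = x$labels[idx],
                 rate = x$rate_map[idx])
}
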