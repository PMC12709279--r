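# Persistence (rescaled-range Hurst exponent) and stability (coefficient of
# variation) grading of pixel series, and the categorical sustainability /
# stability taxonomies combining them with the trend pattern.

#' Hurst exponent by rescaled-range analysis
#'
#' For each window size `w` on a geometric ladder (golden-ratio spacing)
#' from `min_window` to `floor(n/2)`, the series is partitioned into
#' `floor(n/w)` consecutive blocks. Per block, `R` is the range of the
#' cumulative sum of mean-centred values and `S` the population standard
#' deviation; blocks with `S = 0` are skipped. `H` is the slope of
#' `log(mean R/S)` on `log(w)`, clipped to `[0, 1]`.
#'
#' `H > 0.5` indicates persistence (future tendency follows the past),
#' `H < 0.5` anti-persistence, and `H = 0.5` a random walk of increments.
#'
#' @param series a [pixel_series()] or numeric vector with
#'   `length >= 2 * min_window`.
#' @param min_window smallest window size, `>= 4`. The default (`NULL`)
#'   scales with the series: `max(4, min(32, floor(n/32)))`. Small windows
#'   bias the R/S slope toward 0.5 (the finite-sample expectation of R/S
#'   deviates from the asymptotic power law most strongly at small `w`), so
#'   long series exclude them; short annual records keep `w = 4` so at
#'   least three ladder sizes fit.
#' @return List with `H`, `n_windows`, `fit_r2`, and the per-window table
#'   `rs` (tibble `window`, `mean_rs`).
#' @examples
#' hurst_rs(generate_fgn(0.8, 512, seed = 1))$H
#' @export
hurst_rs <- function(series, min_window = NULL) {
  s <- as_pixel_series(series)
  x <- s$values
  n <- length(x)
  if (is.null(min_window)) min_window <- max(4L, min(32L, floor(n / 32)))
  min_window <- as.integer(min_window)
  if (min_window < 4) stop("`min_window` must be >= 4", call. = FALSE)
  if (n < 2 * min_window) {
    stop("series too short: need length >= 2 * min_window = ",
         2 * min_window, call. = FALSE)
  }
  if (sd(x) == 0) stop("constant series has no R/S scaling", call. = FALSE)
  windows <- rs_window_ladder(min_window, floor(n / 2))
  if (length(windows) < 3) {
    stop("window ladder has fewer than 3 sizes; lower `min_window`",
         call. = FALSE)
  }
  mean_rs <- vapply(windows, function(w) {
    nb <- floor(n / w)
    rs <- vapply(seq_len(nb), function(b) {
      blk <- x[((b - 1) * w + 1):(b * w)]
      ctr <- blk - mean(blk)
      spop <- sqrt(mean(ctr^2))
      if (spop == 0) return(NA_real_)
      cs <- cumsum(ctr)
      (max(cs) - min(cs)) / spop
    }, numeric(1))
    mean(rs, na.rm = TRUE)
  }, numeric(1))
  ok <- is.finite(mean_rs) & mean_rs > 0
  lx <- log(windows[ok])
  ly <- log(mean_rs[ok])
  fit <- lm(ly ~ lx)
  h <- unname(coef(fit)[2])
  list(H = min(1, max(0, h)),
       n_windows = sum(ok),
       fit_r2 = summary(fit)$r.squared,
       rs = tibble::tibble(window = windows[ok], mean_rs = mean_rs[ok]))
}

# golden-ratio geometric ladder of window sizes; the largest usable window
# floor(n/2) is always included so even short ladders span the full scale
# range
rs_window_ladder <- function(min_window, max_window) {
  phi <- (1 + sqrt(5)) / 2
  w <- min_window
  out <- integer(0)
  while (round(w) <= max_window) {
    out <- c(out, as.integer(round(w)))
    w <- w * phi
  }
  unique(c(out, as.integer(max_window)))
}

#' Coefficient of variation
#'
#' Sample standard deviation divided by the absolute mean; scale-invariant
#' measure of interannual fluctuation. Pixels with `|mean| < 1e-12` are
#' ungradable (the ratio blows up) and return `NA` with a warning-free
#' labelled outcome.
#'
#' @param series a [pixel_series()] or numeric vector.
#' @return The CV (numeric scalar), or `NA_real_` when the mean is
#'   numerically zero.
#' @export
coefficient_of_variation <- function(series) {
  s <- as_pixel_series(series)
  m <- mean(s$values)
  if (abs(m) < 1e-12) return(NA_real_)
  sd(s$values) / abs(m)
}

# Taxonomies -----------------------------------------------------------------

pattern_phrase <- function(pattern) {
  c(MONO_INC = "monotonically increasing",
    MONO_DEC = "monotonically decreasing",
    INC_DEC = "increase then decrease",
    DEC_INC = "decrease then increase")[[pattern]]
}

#' Sustainability class from Hurst exponent and trend pattern
#'
#' `H > 0.5` means the past tendency persists, so the four trend patterns
#' map to "Sustainability and <pattern>". `H < 0.5` (anti-persistent) and
#' `H = 0.5` exactly (a random series, future unpredictable) both yield
#' "Undetermined future variation trend", as does a `NOT_SIGNIFICANT`
#' pattern regardless of `H`.
#'
#' @param H Hurst exponent in `[0, 1]`.
#' @param pattern a label from [trend_patterns()].
#' @return A length-1 character sustainability label.
#' @examples
#' sustainability_class(0.7, "MONO_INC")
#' @export
sustainability_class <- function(H, pattern) {
  stopifnot(H >= 0, H <= 1)
  pattern <- match.arg(pattern, trend_patterns())
  if (pattern == "NOT_SIGNIFICANT" || H <= 0.5) {
    return("Undetermined future variation trend")
  }
  paste0("Sustainability and ", pattern_phrase(pattern))
}

# fluctuation tier x pattern -> grade code; the roman-numeral codes are kept
# exactly as the taxonomy prints them (including the XLIII/XIII/XXIII
# ordering of the medium tier).
grade_table <- function() {
  tibble::tribble(
    ~fluctuation, ~pattern,    ~grade,
    "HIGH",       "MONO_INC",  "XLI",
    "HIGH",       "MONO_DEC",  "XXXI",
    "HIGH",       "INC_DEC",   "XXI",
    "HIGH",       "DEC_INC",   "XI",
    "MEDIUM",     "MONO_INC",  "XLIII",
    "MEDIUM",     "MONO_DEC",  "XXXIII",
    "MEDIUM",     "INC_DEC",   "XIII",
    "MEDIUM",     "DEC_INC",   "XXIII",
    "LOW",        "MONO_INC",  "XLII",
    "LOW",        "MONO_DEC",  "XXXII",
    "LOW",        "INC_DEC",   "XII",
    "LOW",        "DEC_INC",   "XXII"
  )
}

#' Stability grade from coefficient of variation and trend pattern
#'
#' Fluctuation tiers: `HIGH` for `CV >= 0.3`, `MEDIUM` for
#' `0.1 < CV < 0.3`, `LOW` for `CV <= 0.1`. The (tier, pattern) pair maps
#' to a roman-numeral grade code; `NOT_SIGNIFICANT` pixels carry no grade.
#'
#' @param cv coefficient of variation, `>= 0` (or `NA` for ungradable).
#' @param pattern a label from [trend_patterns()].
#' @return List with `cv`, `fluctuation` (`HIGH`/`MEDIUM`/`LOW` or `NA`),
#'   `grade` (roman-numeral code or `NA`), `sustainability` of class
#'   `stability_grade`.
#' @examples
#' stability_grade(0.05, "MONO_INC")$grade   # "XLII"
#' @export
stability_grade <- function(cv, pattern) {
  pattern <- match.arg(pattern, trend_patterns())
  if (is.na(cv)) {
    return(structure(list(cv = NA_real_, fluctuation = NA_character_,
                          grade = NA_character_), class = "stability_grade"))
  }
  stopifnot(cv >= 0)
  fluct <- if (cv >= 0.3) "HIGH" else if (cv > 0.1) "MEDIUM" else "LOW"
  grade <- if (pattern == "NOT_SIGNIFICANT") {
    NA_character_
  } else {
    tbl <- grade_table()
    tbl$grade[tbl$fluctuation == fluct & tbl$pattern == pattern]
  }
  structure(list(cv = cv, fluctuation = fluct, grade = grade),
            class = "stability_grade")
}

#' @export
print.stability_grade <- function(x, ...) {
  cat(sprintf("<stability_grade> CV = %.3f, %s, grade %s\n",
              x$cv, x$fluctuation, x$grade))
  invisible(x)
}

#' Persistence and stability maps for a cube
#'
#' Per-pixel Hurst exponent, coefficient of variation, fluctuation tier,
#' grade code and sustainability label, combining the cube with an already
#' computed [classify_cube()] pattern map.
#'
#' @param cube a [raster_cube()].
#' @param patterns a `pattern_map` on the same grid.
#' @param min_window R/S minimum window; `NULL` (default) scales with the
#'   series length as in [hurst_rs()].
#' @return Tibble with one row per unmasked pixel: `row`, `col`, `H`,
#'   `cv`, `pattern`, `fluctuation`, `grade`, `sustainability`.
#' @export
persistence_stability_table <- function(cube, patterns, min_window = NULL) {
  stopifnot(inherits(cube, "raster_cube"), inherits(patterns, "pattern_map"))
  idx <- which(cube$mask, arr.ind = TRUE)
  purrr::map_dfr(seq_len(nrow(idx)), function(i) {
    r <- idx[i, 1]
    c <- idx[i, 2]
    s <- pixel_series(cube$values[, r, c], cube$years)
    h <- hurst_rs(s, min_window = min_window)$H
    cv <- coefficient_of_variation(s)
    pat <- patterns$labels[r, c]
    gr <- stability_grade(cv, pat)
    tibble::tibble(row = r, col = c, H = h, cv = cv, pattern = pat,
                   fluctuation = gr$fluctuation, grade = gr$grade,
                   sustainability = sustainability_class(h, pat))
  })
}
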