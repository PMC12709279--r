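#' @useDynLib cwuetrend, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor cor.test fft lm median predict quantile rnorm sd var coef
#' @importFrom utils read.csv write.csv
NULL

# canonical labels -----------------------------------------------------------

#' Trend-pattern and driver vocabularies
#'
#' `trend_patterns()` returns the five variation-pattern labels used
#' throughout: monotonically increasing / decreasing, increasing-then-
#' decreasing, decreasing-then-increasing, and not significant.
#' `driver_names()` returns the six driver features in canonical column
#' order: temperature (degC), precipitation (mm), sunlight (h), radiation
#' (index), LAI (unitless), GDP (density index).
#'
#' @return Character vector of labels.
#' @export
trend_patterns <- function() {
  c("MONO_INC", "MONO_DEC", "INC_DEC", "DEC_INC", "NOT_SIGNIFICANT")
}

#' @rdname trend_patterns
#' @export
driver_names <- function() {
  c("temperature", "precipitation", "sunlight", "radiation", "lai", "gdp")
}

archetypes <- function() c("MONO_INC", "MONO_DEC", "INC_DEC", "DEC_INC", "FLAT")

# trend archetypes ------------------------------------------------------------

#' Generate a pixel series with a planted trend archetype
#'
#' The noise-free component is a linear ramp for the monotone archetypes, a
#' quadratic with its vertex at the series midpoint for the hump archetypes
#' (`INC_DEC` peaks, `DEC_INC` dips), and a constant for `FLAT`; `amplitude`
#' is the full range of the noise-free component. White Gaussian noise of
#' standard deviation `noise_sd` is added on top.
#'
#' @param pattern one of `"MONO_INC"`, `"MONO_DEC"`, `"INC_DEC"`,
#'   `"DEC_INC"`, `"FLAT"`.
#' @param n_years series length, at least 8.
#' @param amplitude range of the noise-free component (response units).
#' @param noise_sd standard deviation of additive white noise.
#' @param seed integer seed; the function is a pure function of its
#'   arguments including the seed.
#' @param baseline constant offset added to the series.
#' @param years integer years for the output series.
#' @return A [pixel_series()].
#' @examples
#' generate_trend_series("MONO_INC", 19, amplitude = 1, noise_sd = 0, seed = 1)
#' @export
generate_trend_series <- function(pattern, n_years, amplitude = 1,
                                  noise_sd = 0, seed = 1L, baseline = 0,
                                  years = seq_len(n_years)) {
  pattern <- match.arg(pattern, archetypes())
  stopifnot(n_years >= 8, amplitude >= 0, noise_sd >= 0)
  shape <- trend_shape(pattern, n_years, amplitude)
  noise <- if (noise_sd > 0) {
    withr::with_seed(as.integer(seed), rnorm(n_years, 0, noise_sd))
  } else {
    numeric(n_years)
  }
  pixel_series(baseline + shape + noise, years = years)
}

# noise-free archetype shape with range == amplitude
trend_shape <- function(pattern, n_years, amplitude) {
  t01 <- seq(0, 1, length.out = n_years)
  switch(pattern,
    MONO_INC = amplitude * t01,
    MONO_DEC = amplitude * (1 - t01),
    # quadratic with vertex at the midpoint: 1 - (2t-1)^2 rises from 0 to 1
    # and back; unique interior extremum when n_years is odd, and for even
    # n_years the two central samples straddle the vertex symmetrically --
    # perturb the parabola by centring on the sample grid midpoint so the
    # discrete maximum is unique for any length.
    INC_DEC = amplitude * (1 - (2 * (t01 - midpoint_offset(n_years)))^2),
    DEC_INC = amplitude * ((2 * (t01 - midpoint_offset(n_years)))^2 - 1) + amplitude,
    FLAT = rep(0, n_years)
  )
}

# vertex position in [0,1]: exactly on a sample for odd lengths, nudged onto
# the left-central sample for even lengths so the discrete extremum is unique
midpoint_offset <- function(n_years) {
  if (n_years %% 2 == 1) 0.5 else (n_years / 2 - 1) / (n_years - 1)
}

# fractional Gaussian noise ---------------------------------------------------

# target autocovariance of fGn with unit variance
fgn_acvf <- function(k, hurst) {
  0.5 * (abs(k + 1)^(2 * hurst) - 2 * abs(k)^(2 * hurst) +
           abs(k - 1)^(2 * hurst))
}

#' Generate fractional Gaussian noise
#'
#' Stationary Gaussian noise with unit marginal variance and autocovariance
#' `gamma(k) = 0.5 * (|k+1|^(2H) - 2|k|^(2H) + |k-1|^(2H))`, the increment
#' process of fractional Brownian motion. At `H = 0.5` this is white noise;
#' `H > 0.5` gives persistent (positively correlated) noise, `H < 0.5`
#' anti-persistent. Synthesis is by circulant (Davies-Harte) embedding of
#' the autocovariance with an exact-covariance Cholesky fallback when the
#' embedding is not non-negative definite at short lengths.
#'
#' @param hurst Hurst exponent, strictly inside (0, 1).
#' @param n series length, at least 2.
#' @param seed integer seed; deterministic given the seed.
#' @return Numeric vector of length `n`.
#' @examples
#' x <- generate_fgn(0.8, 256, seed = 7)
#' @export
generate_fgn <- function(hurst, n, seed = 1L) {
  if (!is.numeric(hurst) || hurst <= 0 || hurst >= 1) {
    stop("`hurst` must lie strictly inside (0, 1)", call. = FALSE)
  }
  stopifnot(n >= 2)
  n <- as.integer(n)
  m <- 2L * n
  g <- fgn_acvf(0:n, hurst)
  circ <- c(g, rev(g[2:n]))           # length 2n, symmetric
  lambda <- Re(fft(circ))
  if (min(lambda) < -1e-8 * max(lambda)) {
    return(fgn_cholesky(hurst, n, seed))
  }
  lambda[lambda < 0] <- 0
  withr::with_seed(as.integer(seed), {
    u <- rnorm(m)
    w <- rnorm(m)
    v <- complex(real = numeric(m), imaginary = numeric(m))
    v[1] <- complex(real = u[1], imaginary = 0)
    v[n + 1] <- complex(real = u[n + 1], imaginary = 0)
    k <- 2:n
    v[k] <- complex(real = u[k], imaginary = w[k]) / sqrt(2)
    v[m + 2 - k] <- Conj(v[k])
    z <- fft(sqrt(lambda) * v) / sqrt(m)
    Re(z)[seq_len(n)]
  })
}

# exact-covariance fallback for short series
fgn_cholesky <- function(hurst, n, seed) {
  k <- abs(outer(seq_len(n), seq_len(n), "-"))
  sigma <- matrix(fgn_acvf(k, hurst), n, n)
  l <- chol(sigma)
  withr::with_seed(as.integer(seed), as.vector(crossprod(l, rnorm(n))))
}

# scene configuration ---------------------------------------------------------

#' Configure a synthetic raster scene
#'
#' Defines the study conditions for a planted-truth scene: grid and series
#' sizes, per-pixel trend archetypes, temporal-noise level and persistence,
#' the driver-to-response model with its spatially planted dominant driver,
#' and the nodata mask fraction. Defaults emulate an annual 2000-2018 record
#' on a 30 x 30 grid of 0.05 degree cells: the four trend archetypes planted
#' in quadrants, fGn temporal noise with Hurst 0.7, and LAI dominant on the
#' left half of the scene with temperature dominant on the right.
#'
#' @param n_years number of annual steps (default 19, years 2000-2018).
#' @param height,width grid size in pixels.
#' @param pattern_field `(height, width)` character matrix of archetype
#'   labels (see [generate_trend_series()]); default plants the four
#'   archetypes in quadrants.
#' @param amplitude full range of the planted GPP trend component
#'   (g C m-2 y-1).
#' @param gpp_base baseline GPP (g C m-2 y-1).
#' @param cue_true true carbon use efficiency in (0, 1); NPP is
#'   `cue_true * GPP` by construction so `GPP >= NPP >= 0` holds everywhere.
#' @param noise_sd standard deviation of temporal noise added to GPP
#'   (response units).
#' @param hurst_target Hurst exponent in (0, 1) of the temporal noise.
#' @param driver_model `"additive"` or `"interaction"` response model.
#' @param dominant_field `(height, width)` character matrix of planted
#'   dominant-driver labels drawn from [driver_names()]; default LAI on the
#'   left half, temperature on the right.
#' @param dominant_coef,secondary_coef response-model coefficients (on
#'   globally standardized drivers) for the planted dominant driver and the
#'   rest.
#' @param dominant_sd_boost factor by which the planted dominant driver's
#'   interannual anomaly standard deviation is amplified at its pixels
#'   (default 2.5). A locally dominant driver both carries the largest
#'   response coefficient and varies most strongly at that location; the
#'   variability component is what makes per-pixel dominance visible to a
#'   single basin-wide regression model, which cannot represent spatially
#'   varying coefficients.
#' @param response_noise_sd standard deviation of noise added to the
#'   water-use-efficiency response (g C m-2 mm-1).
#' @param nodata_fraction fraction of cells masked as nodata, in [0, 1).
#' @param start_year first year of the time axis.
#' @param seed integer seed for every random element of the scene.
#' @return A `scene_config` list.
#' @export
scene_config <- function(n_years = 19L, height = 30L, width = 30L,
                         pattern_field = NULL,
                         amplitude = 100, gpp_base = 500, cue_true = 0.5,
                         noise_sd = 10, hurst_target = 0.7,
                         driver_model = c("additive", "interaction"),
                         dominant_field = NULL,
                         dominant_coef = 0.12, secondary_coef = 0.05,
                         dominant_sd_boost = 2.5,
                         response_noise_sd = 0.02,
                         nodata_fraction = 0.05,
                         start_year = 2000L, seed = 1L) {
  driver_model <- match.arg(driver_model)
  n_years <- as.integer(n_years)
  height <- as.integer(height)
  width <- as.integer(width)
  stopifnot(n_years >= 8, height >= 1, width >= 1, noise_sd >= 0,
            hurst_target > 0, hurst_target < 1,
            nodata_fraction >= 0, nodata_fraction < 1,
            cue_true > 0, cue_true < 1, amplitude >= 0,
            dominant_sd_boost >= 1)
  if (is.null(pattern_field)) {
    pattern_field <- quadrant_field(height, width,
                                    c("MONO_INC", "MONO_DEC",
                                      "INC_DEC", "DEC_INC"))
  }
  if (is.null(dominant_field)) {
    dominant_field <- matrix("temperature", height, width)
    dominant_field[, seq_len(floor(width / 2))] <- "lai"
  }
  check_field <- function(field, levels, name) {
    if (!is.matrix(field) ||
        !identical(as.integer(dim(field)), c(height, width))) {
      stop("`", name, "` must be a ", height, " x ", width, " matrix",
           call. = FALSE)
    }
    bad <- setdiff(unique(as.vector(field)), levels)
    if (length(bad)) {
      stop("`", name, "` contains unknown labels: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  check_field(pattern_field, archetypes(), "pattern_field")
  check_field(dominant_field, driver_names(), "dominant_field")
  structure(list(
    n_years = as.integer(n_years), height = as.integer(height),
    width = as.integer(width), pattern_field = pattern_field,
    amplitude = amplitude, gpp_base = gpp_base, cue_true = cue_true,
    noise_sd = noise_sd, hurst_target = hurst_target,
    driver_model = driver_model, dominant_field = dominant_field,
    dominant_coef = dominant_coef, secondary_coef = secondary_coef,
    dominant_sd_boost = dominant_sd_boost,
    response_noise_sd = response_noise_sd,
    nodata_fraction = nodata_fraction,
    start_year = as.integer(start_year), seed = as.integer(seed)
  ), class = "scene_config")
}

quadrant_field <- function(height, width, labels) {
  field <- matrix(labels[1], height, width)
  hy <- floor(height / 2)
  hx <- floor(width / 2)
  field[seq_len(hy), seq_len(hx)] <- labels[1]
  field[seq_len(hy), seq(hx + 1, width)] <- labels[2]
  field[seq(hy + 1, height), seq_len(hx)] <- labels[3]
  field[seq(hy + 1, height), seq(hx + 1, width)] <- labels[4]
  field
}

# driver climatologies: mean and interannual sd on natural scales
driver_climatology <- function() {
  tibble::tribble(
    ~driver,         ~mean,  ~sd,
    "temperature",     8.0,  0.8,
    "precipitation", 450.0, 70.0,
    "sunlight",     2600.0, 120.0,
    "radiation",       0.60, 0.05,
    "lai",             1.50, 0.30,
    "gdp",             2.00, 0.50
  )
}

#' Generate a synthetic scene with planted ground truth
#'
#' Builds NPP, GPP and ET cubes realizing the per-pixel trend archetypes,
#' six driver cubes, and a DEM, wired so that the water-use-efficiency
#' response `WUE_NPP = NPP / ET` is a known function of the standardized
#' drivers with the planted dominant driver carrying the largest
#' coefficient and (see `dominant_sd_boost`) the largest local interannual
#' variability. GPP is generated first as baseline + archetype trend + fGn
#' noise; NPP is `cue_true * GPP` (so `GPP >= NPP >= 0`); ET is derived as
#' `NPP / WUE_true`, which keeps ET positive and makes the response exactly
#' recoverable from the driver cubes. All cubes share one mask with exactly
#' `round(nodata_fraction * height * width)` masked cells.
#'
#' @param config a [scene_config()].
#' @return A `synthetic_scene` list with elements `npp`, `gpp`, `et`
#'   (cubes), `drivers` (named list of six cubes), `dem` (matrix), and
#'   `truth` (list: `pattern` matrix, `dominant` matrix, `hurst_target`,
#'   `wue_true` cube).
#' @examples
#' scn <- generate_scene(scene_config(height = 6, width = 6, seed = 2))
#' scn$npp
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  cf <- config
  ny <- cf$n_years
  h <- cf$height
  w <- cf$width
  years <- seq(cf$start_year, length.out = ny)
  grid <- list(origin = c(0, 0), cellsize = 0.05, crs = "EPSG:4326")

  n_cells <- h * w
  n_masked <- round(cf$nodata_fraction * n_cells)
  mask <- matrix(TRUE, h, w)
  seeds <- withr::with_seed(cf$seed, {
    if (n_masked > 0) {
      masked_cells <- sample.int(n_cells, n_masked)
      mask[masked_cells] <- FALSE
    }
    # independent sub-seeds for each stochastic block
    sample.int(.Machine$integer.max - 1L, 4L)
  })

  # GPP: baseline + planted archetype + fGn temporal noise per pixel
  gpp <- array(NA_real_, c(ny, h, w))
  pix_seed <- matrix(withr::with_seed(seeds[1],
                                      sample.int(.Machine$integer.max - 1L,
                                                 n_cells)), h, w)
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      if (!mask[r, c]) next
      shape <- trend_shape(cf$pattern_field[r, c], ny, cf$amplitude)
      noise <- if (cf$noise_sd > 0) {
        cf$noise_sd * generate_fgn(cf$hurst_target, ny, seed = pix_seed[r, c])
      } else numeric(ny)
      gpp[, r, c] <- pmax(cf$gpp_base + shape + noise, 1)
    }
  }
  npp <- cf$cue_true * gpp

  # drivers: climatological mean + interannual anomalies per pixel; the
  # pixel's planted dominant driver fluctuates dominant_sd_boost times
  # harder there
  clim <- driver_climatology()
  drv_arrays <- list()
  drv_seeds <- withr::with_seed(seeds[2],
                                sample.int(.Machine$integer.max - 1L, 6L))
  for (j in seq_len(6)) {
    nm <- clim$driver[j]
    a <- array(NA_real_, c(ny, h, w))
    z <- withr::with_seed(drv_seeds[j], rnorm(ny * n_cells))
    a[] <- z
    scale_px <- matrix(1, h, w)
    scale_px[cf$dominant_field == nm] <- cf$dominant_sd_boost
    a <- clim$mean[j] + clim$sd[j] * sweep_pixel(a, scale_px)
    for (t in seq_len(ny)) a[t, , ][!mask] <- NA_real_
    drv_arrays[[nm]] <- a
  }

  # response: WUE_true = base + sum_j beta_j(pixel) * z_j (+ interaction)
  z <- lapply(seq_len(6), function(j) {
    (drv_arrays[[clim$driver[j]]] - clim$mean[j]) / clim$sd[j]
  })
  names(z) <- clim$driver
  wue_base <- 1.0
  wue_true <- array(wue_base, c(ny, h, w))
  for (j in seq_len(6)) {
    nm <- clim$driver[j]
    beta <- matrix(cf$secondary_coef, h, w)
    beta[cf$dominant_field == nm] <- cf$dominant_coef
    wue_true <- wue_true + sweep_pixel(z[[nm]], beta)
  }
  if (cf$driver_model == "interaction") {
    # mild precipitation x temperature interaction on top of the main effects
    wue_true <- wue_true +
      0.5 * cf$secondary_coef * z[["temperature"]] * z[["precipitation"]]
  }
  if (cf$response_noise_sd > 0) {
    eps <- withr::with_seed(seeds[3],
                            rnorm(ny * n_cells, 0, cf$response_noise_sd))
    wue_true <- wue_true + array(eps, c(ny, h, w))
  }
  wue_true <- pmax(wue_true, 0.05)   # keep ET finite and positive
  for (t in seq_len(ny)) wue_true[t, , ][!mask] <- NA_real_

  et <- npp / wue_true

  dem <- matrix(withr::with_seed(seeds[4], {
    base <- seq(3500, 500, length.out = w)   # west-high, east-low relief
    rep(base, each = h) + rnorm(n_cells, 0, 50)
  }), h, w)

  mk_cube <- function(a) raster_cube(a, years = years, mask = mask, grid = grid)
  structure(list(
    npp = mk_cube(npp), gpp = mk_cube(gpp), et = mk_cube(et),
    drivers = lapply(drv_arrays, mk_cube),
    dem = dem,
    truth = list(pattern = cf$pattern_field, dominant = cf$dominant_field,
                 hurst_target = cf$hurst_target, wue_true = mk_cube(wue_true)),
    config = cf
  ), class = "synthetic_scene")
}

# multiply each pixel's series by a per-pixel coefficient
sweep_pixel <- function(arr, beta) {
  d <- dim(arr)
  arr * aperm(array(beta, c(d[2], d[3], d[1])), c(3, 1, 2))
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %d x %d pixels, %d years, seed %d\n",
              x$config$height, x$config$width, x$config$n_years,
              x$config$seed))
  invisible(x)
}
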