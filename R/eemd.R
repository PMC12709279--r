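# Ensemble empirical mode decomposition.
#
# EMD peels a series into intrinsic mode functions (IMFs) by envelope-mean
# sifting: at each pass the mean of the cubic-spline envelopes through the
# local maxima and minima is subtracted until the candidate satisfies a
# Cauchy-type SD stopping criterion. The residual left when too few extrema
# remain is the secular (nonlinear) trend. EEMD repeats EMD over an ensemble
# of white-noise-perturbed copies and averages componentwise, which
# suppresses mode mixing on short annual series.

#' EEMD configuration
#'
#' @param ensemble_size number of noise-perturbed EMD runs to average
#'   (default 100, the canonical EEMD setting; 1 with `noise_amplitude = 0`
#'   reduces EEMD to plain EMD).
#' @param noise_amplitude standard deviation of the added white noise as a
#'   multiple of the input series' standard deviation (default 0.2).
#' @param sd_threshold sifting stop value for the Cauchy-type SD criterion
#'   (default 0.2; the canonical sifting range is 0.2-0.3).
#' @param max_sift_iters hard cap on sifting passes per IMF (default 500;
#'   most candidates stop within ten passes, but the joint SD + IMF-property
#'   stop occasionally needs a few hundred on riding-wave cases).
#' @param max_imfs cap on extracted IMFs; `NULL` (default) uses the dyadic
#'   bound `floor(log2(n))`, which prevents over-decomposition of short
#'   series.
#' @param seed integer seed for the ensemble noise.
#' @return An `eemd_config` list.
#' @export
eemd_config <- function(ensemble_size = 100L, noise_amplitude = 0.2,
                        sd_threshold = 0.2, max_sift_iters = 500L,
                        max_imfs = NULL, seed = 1L) {
  stopifnot(ensemble_size >= 1, noise_amplitude >= 0,
            sd_threshold > 0, sd_threshold < 1, max_sift_iters >= 1)
  structure(list(ensemble_size = as.integer(ensemble_size),
                 noise_amplitude = noise_amplitude,
                 sd_threshold = sd_threshold,
                 max_sift_iters = as.integer(max_sift_iters),
                 max_imfs = if (is.null(max_imfs)) NULL else as.integer(max_imfs),
                 seed = as.integer(seed)),
            class = "eemd_config")
}

resolve_max_imfs <- function(config, n) {
  if (is.null(config$max_imfs)) max(1L, floor(log2(n))) else config$max_imfs
}

#' Mean of the upper and lower envelopes
#'
#' Interpolates a cubic spline through the local maxima (upper envelope)
#' and through the local minima (lower envelope), extending each set by
#' mirroring the two nearest extrema beyond the series ends, and returns
#' the pointwise envelope mean. This is the quantity subtracted at each
#' sifting pass.
#'
#' @param series a [pixel_series()] or numeric vector with at least two
#'   local maxima and two local minima.
#' @return Numeric vector of the envelope mean, same length as the input.
#' @export
envelope_mean <- function(series) {
  s <- as_pixel_series(series)
  res <- .envelope_mean_cpp(s$values)
  if (!res$ok) {
    stop("monotone residual: need >= 2 local maxima and >= 2 local minima (",
         "found ", res$n_maxima, " maxima, ", res$n_minima, " minima)",
         call. = FALSE)
  }
  res$mean
}

#' Extract one intrinsic mode function by sifting
#'
#' Repeatedly subtracts the envelope mean until the Cauchy-type SD
#' criterion `sum((h_k - h_(k-1))^2 / h_(k-1)^2)` (terms with a vanishing
#' previous iterate skipped) falls below `sd_threshold`, the candidate runs
#' out of extrema, or `max_sift_iters` passes have been made.
#'
#' @param series a [pixel_series()] or numeric vector.
#' @param config an [eemd_config()].
#' @return List with `imf`, `remainder` (`series - imf`) and `iterations`.
#' @export
sift_imf <- function(series, config = eemd_config()) {
  s <- as_pixel_series(series)
  res <- .sift_imf_cpp(s$values, config$sd_threshold, config$max_sift_iters)
  if (!isTRUE(res$ok)) {
    stop("monotone residual: series has too few extrema to sift",
         call. = FALSE)
  }
  list(imf = res$imf, remainder = res$remainder, iterations = res$iterations)
}

new_decomposition <- function(imfs, residual, input, years) {
  structure(list(imfs = imfs, residual = residual, input = input,
                 years = years),
            class = "imf_decomposition")
}

#' @export
print.imf_decomposition <- function(x, ...) {
  cat(sprintf("<imf_decomposition> %d IMFs + residual, n = %d\n",
              length(x$imfs), length(x$input)))
  invisible(x)
}

#' Empirical mode decomposition
#'
#' Iteratively extracts IMFs from successive residuals until the residual
#' has fewer than two maxima or two minima (monotone-or-single-extremum),
#' or the IMF cap is reached. The decomposition is complete:
#' `input = sum(imfs) + residual` to floating precision. Monotone or
#' constant input yields zero IMFs with the input as residual.
#'
#' @param series a [pixel_series()] or numeric vector, length >= 8.
#' @param config an [eemd_config()]; only the sifting fields are used.
#' @return An `imf_decomposition`: list of `imfs` (each a numeric vector,
#'   possibly empty), `residual`, `input`, `years`.
#' @export
emd <- function(series, config = eemd_config()) {
  s <- as_pixel_series(series)
  n <- length(s$values)
  stopifnot(n >= 8)
  res <- .emd_cpp(s$values, config$sd_threshold, config$max_sift_iters,
                  resolve_max_imfs(config, n))
  imfs <- if (nrow(res$imfs) == 0) list() else
    lapply(seq_len(nrow(res$imfs)), function(i) res$imfs[i, ])
  new_decomposition(imfs, res$residual, s$values, s$years)
}

#' Ensemble empirical mode decomposition
#'
#' Runs [emd()] on `ensemble_size` copies of the input perturbed with white
#' Gaussian noise of standard deviation `noise_amplitude * sd(series)`,
#' pads shorter decompositions with zero IMFs (before the residual) so all
#' members are conformable, and averages componentwise. With
#' `ensemble_size = 1` and `noise_amplitude = 0` this is exactly [emd()].
#' Deterministic given `config$seed`.
#'
#' @inheritParams emd
#' @return An `imf_decomposition` of the componentwise ensemble means.
#' @examples
#' s <- generate_trend_series("MONO_INC", 19, amplitude = 1, noise_sd = 0.1,
#'                            seed = 3)
#' d <- eemd(s, eemd_config(ensemble_size = 25, seed = 3))
#' length(d$imfs)
#' @export
eemd <- function(series, config = eemd_config()) {
  s <- as_pixel_series(series)
  n <- length(s$values)
  stopifnot(n >= 8)
  if (config$ensemble_size == 1 && config$noise_amplitude == 0) {
    return(emd(s, config))
  }
  noise_sd <- config$noise_amplitude * sd(s$values)
  max_imfs <- resolve_max_imfs(config, n)
  members <- withr::with_seed(config$seed, {
    lapply(seq_len(config$ensemble_size), function(e) {
      perturbed <- s$values + rnorm(n, 0, noise_sd)
      .emd_cpp(perturbed, config$sd_threshold, config$max_sift_iters,
               max_imfs)
    })
  })
  n_imfs <- max(vapply(members, function(m) nrow(m$imfs), integer(1)))
  es <- config$ensemble_size
  imfs <- vector("list", n_imfs)
  if (n_imfs > 0) {
    for (k in seq_len(n_imfs)) {
      acc <- numeric(n)
      for (m in members) if (nrow(m$imfs) >= k) acc <- acc + m$imfs[k, ]
      imfs[[k]] <- acc / es
    }
  }
  resid <- Reduce(`+`, lapply(members, `[[`, "residual")) / es
  new_decomposition(imfs, resid, s$values, s$years)
}

#' Secular trend of a decomposition
#'
#' The residual left after all IMFs are removed: the monotone-or-near-
#' monotone component the trend-pattern classifier operates on. (Whether
#' the "trend" should also include the last IMF is a modelling choice; the
#' residual alone is used here, and callers can add `rev(d$imfs)[[1]]` if
#' they want the alternative reading.)
#'
#' @param decomp an `imf_decomposition` from [emd()] or [eemd()].
#' @return A [pixel_series()] of the secular trend.
#' @export
secular_trend <- function(decomp) {
  stopifnot(inherits(decomp, "imf_decomposition"))
  pixel_series(decomp$residual, years = decomp$years)
}

#' Decomposition as a long tibble
#'
#' @param x an `imf_decomposition`.
#' @param ... unused.
#' @return Tibble with columns `component` (`input`, `IMF1`..., `residual`),
#'   `year`, `value`.
#' @exportS3Method tibble::as_tibble
as_tibble.imf_decomposition <- function(x, ...) {
  comps <- c(list(input = x$input),
             stats::setNames(x$imfs, paste0("IMF", seq_along(x$imfs))),
             list(residual = x$residual))
  purrr::imap_dfr(comps, function(v, nm) {
    tibble::tibble(component = nm, year = x$years, value = v)
  })
}

# extrema + zero-crossing counts of a component (IMF structural property)
imf_counts <- function(values) {
  cnt <- .imf_counts_cpp(values)
  list(extrema = cnt[1], zero_crossings = cnt[2])
}
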