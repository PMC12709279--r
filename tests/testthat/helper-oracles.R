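# Independent oracles and small fixtures shared across tests.

# Exact Shapley values by averaging marginal contributions over all k!
# orderings -- an independent route to the same quantity as the package's
# subset enumeration. Only usable for k <= 4.
permutation_shapley <- function(f, x, bg) {
  k <- length(x)
  phi <- numeric(k)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out <- c(out, list(c(v[i], p)))
    }
    out
  }
  vfun <- function(s) {
    hyb <- as.matrix(bg)
    if (length(s)) hyb[, s] <- matrix(x[s], nrow(hyb), length(s), byrow = TRUE)
    mean(f(hyb))
  }
  allp <- perms(seq_len(k))
  for (p in allp) {
    pre <- integer(0)
    for (j in p) {
      phi[j] <- phi[j] + vfun(c(pre, j)) - vfun(pre)
      pre <- c(pre, j)
    }
  }
  phi / length(allp)
}

# mixed tone + ramp random series corpus for decomposition tests
random_test_series <- function(seed, n = NULL) {
  withr::with_seed(seed, {
    if (is.null(n)) n <- sample(16:256, 1)
    t <- seq_len(n)
    n_tones <- sample(1:3, 1)
    x <- 0.05 * runif(1, -1, 1) * t          # ramp
    for (j in seq_len(n_tones)) {
      period <- runif(1, 4, n / 2)
      x <- x + runif(1, 0.5, 2) * sin(2 * pi * t / period + runif(1, 0, 2 * pi))
    }
    x + rnorm(n, 0, 0.2)
  })
}

# small fully valid test cube with prescribed per-pixel series generator
small_cube <- function(fun, h = 3, w = 3, ny = 12, years = 2000 + seq_len(ny) - 1) {
  vals <- array(NA_real_, c(ny, h, w))
  for (r in seq_len(h)) for (c in seq_len(w)) vals[, r, c] <- fun(r, c)
  raster_cube(vals, years = years)
}

# tiny driver table with an additive known response
toy_driver_table <- function(n = 300, seed = 1, noise_sd = 0,
                             coefs = c(temperature = 0.5, precipitation = 0,
                                       sunlight = 0, radiation = 0,
                                       lai = 1, gdp = 0)) {
  withr::with_seed(seed, {
    tab <- tibble::as_tibble(
      stats::setNames(lapply(driver_names(), function(nm) rnorm(n)),
                      driver_names()))
    tab$response <- as.vector(as.matrix(tab) %*% coefs) +
      rnorm(n, 0, noise_sd)
    tab$pixel_id <- seq_len(n)
    tab$row <- rep(1L, n)
    tab$col <- seq_len(n)
    tab
  })
}
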