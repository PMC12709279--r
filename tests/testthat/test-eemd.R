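# EMD / EEMD core: envelopes, sifting, completeness, structural properties.

test_that("envelope mean of a pure sine vanishes away from the boundary", {
  t <- 0:63
  x <- sin(2 * pi * t / 8)            # 8 samples per period, 8 periods
  phi <- envelope_mean(x)
  interior <- 9:(64 - 8)              # exclude one period at each end
  expect_lt(max(abs(phi[interior])), 0.05)
})

test_that("envelope mean is translation-equivariant", {
  x <- random_test_series(5, n = 64)
  expect_equal(envelope_mean(x + 3.7), envelope_mean(x) + 3.7,
               tolerance = 1e-12)
})

test_that("envelope mean of a symmetric triangle wave is ~0 inside", {
  t <- 0:79
  x <- 2 * abs((t / 8) %% 2 - 1) - 1  # period 16, odd-symmetric about midline
  phi <- envelope_mean(x)
  expect_lt(max(abs(phi[17:64])), 0.05)
})

test_that("a pure tone sifts into itself with a near-zero remainder", {
  t <- 0:63
  x <- sin(2 * pi * t / 8)
  s <- sift_imf(x)
  expect_gt(cor(s$imf, x), 0.99)
  expect_lt(max(abs(s$remainder)), 0.05)
  expect_lte(s$iterations, 2)         # SD is already below threshold
  # exact split by definition
  expect_equal(s$imf + s$remainder, x, tolerance = 1e-12)
})

test_that("monotone and constant inputs decompose to residual only", {
  lin <- emd(seq(1, 20))
  expect_length(lin$imfs, 0)
  expect_identical(lin$residual, as.numeric(1:20))
  const <- emd(rep(2.5, 16))
  expect_length(const$imfs, 0)
  expect_error(envelope_mean(rep(1, 20)), "monotone")
  expect_error(sift_imf(seq(1, 20)), "monotone")
})

test_that("a tone plus ramp separates into an IMF and the ramp", {
  n <- 128
  t <- 0:(n - 1)
  x <- sin(2 * pi * t / 8) + 0.05 * t
  d <- emd(x)
  expect_gte(length(d$imfs), 1)
  expect_gt(cor(d$residual, 0.05 * t), 0.95)
  # pure sine alone leaves a near-zero trend
  ds <- emd(sin(2 * pi * t / 8))
  expect_lt(max(abs(ds$residual)), 0.1)
})

test_that("EMD reconstructs its input exactly (completeness)", {
  for (seed in 1:25) {
    x <- random_test_series(seed)
    d <- emd(x)
    recon <- Reduce(`+`, d$imfs, rep(0, length(x))) + d$residual
    expect_lt(max(abs(recon - x)) / max(abs(x)), 1e-10)
  }
})

test_that("every IMF satisfies the extrema/zero-crossing property", {
  for (seed in 26:45) {
    x <- random_test_series(seed)
    d <- emd(x)
    for (imf in d$imfs) {
      cnt <- cwuetrend:::imf_counts(imf)
      expect_lte(abs(cnt$extrema - cnt$zero_crossings), 1)
    }
  }
})

test_that("mean oscillation is non-increasing across IMF order", {
  zc_of <- function(v) cwuetrend:::imf_counts(v)$zero_crossings
  by_order <- list()
  for (seed in 46:75) {
    d <- emd(random_test_series(seed, n = 128))
    zcs <- vapply(d$imfs, zc_of, numeric(1))
    for (k in seq_along(zcs)) {
      cur <- if (k <= length(by_order)) by_order[[k]] else numeric(0)
      by_order[[k]] <- c(cur, zcs[k])
    }
  }
  mean_zc <- vapply(by_order, mean, numeric(1))
  expect_true(all(diff(mean_zc) <= 0))
})

test_that("EEMD degenerates to EMD and is seed-deterministic", {
  x <- random_test_series(70, n = 64)
  d0 <- emd(x)
  d1 <- eemd(x, eemd_config(ensemble_size = 1, noise_amplitude = 0))
  expect_identical(d0$imfs, d1$imfs)
  expect_identical(d0$residual, d1$residual)

  cfg <- eemd_config(ensemble_size = 30, seed = 11)
  a <- eemd(x, cfg)
  b <- eemd(x, cfg)
  expect_identical(a$imfs, b$imfs)
  expect_identical(a$residual, b$residual)
})

test_that("EEMD completeness error shrinks at the white-noise averaging rate", {
  # RMS of (input - sum imfs - residual) <= 3 * amp * sd / sqrt(ensemble)
  errs <- vapply(1:50, function(seed) {
    x <- random_test_series(100 + seed, n = 64)
    cfg <- eemd_config(ensemble_size = 100, noise_amplitude = 0.2,
                       seed = seed)
    d <- eemd(x, cfg)
    recon <- Reduce(`+`, d$imfs, rep(0, 64)) + d$residual
    sqrt(mean((x - recon)^2)) / (0.2 * sd(x) / sqrt(100))
  }, numeric(1))
  expect_lt(max(errs), 3)
})

test_that("the secular trend is the residual and is translation-equivariant", {
  x <- random_test_series(80, n = 96)
  d <- emd(x)
  expect_equal(secular_trend(d)$values, d$residual)
  d_shift <- emd(x + 10)
  expect_equal(secular_trend(d_shift)$values,
               secular_trend(d)$values + 10, tolerance = 1e-8)
})
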