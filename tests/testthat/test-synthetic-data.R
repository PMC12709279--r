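# Synthetic-scene generator: planted archetypes, fGn persistence structure,
# mask coherence, and the driver-response wiring.

test_that("trend archetypes have the advertised noise-free shapes", {
  inc <- generate_trend_series("MONO_INC", 19, amplitude = 1, noise_sd = 0)
  expect_true(all(diff(inc$values) > 0))
  dec <- generate_trend_series("MONO_DEC", 19, amplitude = 1, noise_sd = 0)
  expect_true(all(diff(dec$values) < 0))

  hump <- generate_trend_series("INC_DEC", 19, amplitude = 1, noise_sd = 0)
  peak <- which.max(hump$values)
  expect_gt(peak, 1)
  expect_lt(peak, 19)
  expect_equal(sum(hump$values == max(hump$values)), 1)
  expect_equal(max(hump$values) - min(hump$values), 1)

  dip <- generate_trend_series("DEC_INC", 19, amplitude = 2, noise_sd = 0)
  expect_equal(which.min(dip$values), 10)

  flat <- generate_trend_series("FLAT", 19, amplitude = 1, noise_sd = 0)
  expect_equal(sd(flat$values), 0)

  # even lengths still yield a unique interior extremum
  hump20 <- generate_trend_series("INC_DEC", 20, amplitude = 1, noise_sd = 0)
  expect_equal(sum(hump20$values == max(hump20$values)), 1)

  expect_error(generate_trend_series("SPIRAL", 19), "arg")
})

test_that("trend series are pure functions of the seed", {
  a <- generate_trend_series("FLAT", 19, amplitude = 1, noise_sd = 0.3, seed = 7)
  b <- generate_trend_series("FLAT", 19, amplitude = 1, noise_sd = 0.3, seed = 7)
  c <- generate_trend_series("FLAT", 19, amplitude = 1, noise_sd = 0.3, seed = 8)
  expect_identical(a$values, b$values)
  expect_false(identical(a$values, c$values))
})

test_that("fGn matches its analytic autocovariance at lag 1", {
  # gamma(1) = 2^(2H-1) - 1: zero at H = 0.5, ~0.516 at H = 0.8
  r1 <- function(H) {
    mean(vapply(1:100, function(s) {
      x <- generate_fgn(H, 1024, seed = s)
      cor(x[-1], x[-1024])
    }, numeric(1)))
  }
  expect_lt(abs(r1(0.5)), 0.1)
  expect_lt(abs(r1(0.8) - (2^(2 * 0.8 - 1) - 1)), 0.05)
})

test_that("fGn sample autocovariances converge to the analytic curve", {
  H <- 0.7
  gamma_k <- function(k) 0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) +
                                  abs(k - 1)^(2 * H))
  acfs <- vapply(1:150, function(s) {
    x <- generate_fgn(H, 512, seed = s)
    vapply(1:5, function(k) mean(x[1:(512 - k)] * x[(k + 1):512]), numeric(1))
  }, numeric(5))
  expect_lt(max(abs(rowMeans(acfs) - gamma_k(1:5))), 0.05)
  # unit marginal variance
  vs <- vapply(1:150, function(s) var(generate_fgn(H, 512, seed = s)),
               numeric(1))
  expect_lt(abs(mean(vs) - 1), 0.1)
})

test_that("fGn is deterministic given the seed and rejects bad H", {
  expect_identical(generate_fgn(0.5, 64, seed = 3),
                   generate_fgn(0.5, 64, seed = 3))
  expect_error(generate_fgn(0, 64), "hurst")
  expect_error(generate_fgn(1, 64), "hurst")
})

test_that("scenes honour the mask count, shared mask and flux ordering", {
  cf <- scene_config(height = 30, width = 30, nodata_fraction = 0.1, seed = 4)
  scn <- generate_scene(cf)
  expect_equal(sum(!scn$npp$mask), round(0.1 * 900))
  expect_identical(scn$npp$mask, scn$gpp$mask)
  expect_identical(scn$npp$mask, scn$et$mask)
  for (nm in driver_names()) {
    expect_identical(scn$drivers[[nm]]$mask, scn$npp$mask)
  }
  ok <- as.vector(scn$npp$mask)
  flat <- function(cb) matrix(cb$values, dim(cb$values)[1])[, ok]
  expect_true(all(flat(scn$gpp) >= flat(scn$npp)))
  expect_true(all(flat(scn$npp) >= 0))
  expect_true(all(flat(scn$et) > 0))
})

test_that("scenes are bit-identical under the same config and seed", {
  cf <- scene_config(height = 8, width = 8, seed = 9)
  expect_identical(generate_scene(cf), generate_scene(cf))
  cf2 <- scene_config(height = 8, width = 8, seed = 10)
  expect_false(identical(generate_scene(cf), generate_scene(cf2)))
})

test_that("the planted dominant driver has the largest standardized effect", {
  # response = WUE_NPP = NPP/ET by construction; regress its pixel series
  # on standardized drivers and check the planted driver wins
  cf <- scene_config(height = 6, width = 6, seed = 12, nodata_fraction = 0,
                     response_noise_sd = 0)
  scn <- generate_scene(cf)
  wue <- compute_wue(scn$npp, scn$et)
  for (px in list(c(2, 2), c(2, 5), c(5, 2), c(5, 5))) {
    y <- wue$values[, px[1], px[2]]
    z <- vapply(driver_names(), function(nm) {
      v <- scn$drivers[[nm]]$values[, px[1], px[2]]
      (v - mean(v)) / sd(v)
    }, numeric(length(y)))
    beta <- abs(coef(lm(y ~ z))[-1])
    expect_equal(driver_names()[which.max(beta)],
                 scn$truth$dominant[px[1], px[2]])
  }
})

test_that("scene config rejects malformed fields", {
  expect_error(scene_config(pattern_field = matrix("UP", 30, 30)),
               "unknown labels")
  expect_error(scene_config(dominant_field = matrix("water", 30, 30)),
               "unknown labels")
  expect_error(scene_config(pattern_field = matrix("FLAT", 3, 3)),
               "30 x 30")
  expect_error(scene_config(hurst_target = 1.2))
  expect_error(scene_config(nodata_fraction = 1))
})
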