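# Rescaled-range Hurst estimation, CV, and the categorical taxonomies.

test_that("single-block R/S matches the hand-computed recipe", {
  # block [1,2,3,4]: centred cumsum (-1.5,-2,-1.5,0), R = 2,
  # S = sqrt(1.25) population -> R/S = 1.78885
  x <- c(1, 2, 3, 4)
  ctr <- x - mean(x)
  cs <- cumsum(ctr)
  r_by_hand <- max(cs) - min(cs)
  s_by_hand <- sqrt(mean(ctr^2))
  expect_equal(r_by_hand, 2)
  expect_equal(s_by_hand, sqrt(1.25))
  # the estimator's smallest ladder window on a repeating series reproduces
  # that mean R/S exactly
  series <- rep(c(1, 2, 3, 4), 8)
  h <- hurst_rs(series, min_window = 4)
  expect_equal(h$rs$mean_rs[h$rs$window == 4], 2 / sqrt(1.25),
               tolerance = 1e-12)
})

test_that("Hurst estimates recover white noise and persistent fGn", {
  # reduced-size sanity (full 200-replicate version in the acceptance run)
  est <- function(H) {
    mean(vapply(1:40, function(s) {
      hurst_rs(generate_fgn(H, 1024, seed = 6000 + s))$H
    }, numeric(1)))
  }
  h5 <- est(0.5)
  h8 <- est(0.8)
  expect_lt(abs(h5 - 0.5), 0.1)
  expect_lt(abs(h8 - 0.8), 0.1)
  expect_gt(h8, h5)
})

test_that("hurst_rs validates its inputs", {
  expect_error(hurst_rs(rnorm(10), min_window = 8), "too short")
  expect_error(hurst_rs(rep(1, 64)), "constant")
  expect_error(hurst_rs(rnorm(64), min_window = 3), ">= 4")
  h <- hurst_rs(generate_fgn(0.5, 128, seed = 1))
  expect_gte(h$n_windows, 3)
  expect_gte(h$H, 0)
  expect_lte(h$H, 1)
})

test_that("coefficient of variation is sd/|mean| and scale-invariant", {
  expect_equal(coefficient_of_variation(rep(4, 10)), 0)
  x <- c(0.8, 1.2, 1.0, 0.8, 1.2)
  expect_equal(coefficient_of_variation(x), sd(x) / mean(x))
  expect_equal(coefficient_of_variation(3 * x),
               coefficient_of_variation(x), tolerance = 1e-12)
  expect_true(is.na(coefficient_of_variation(c(-1, 1, -1, 1))))
})

test_that("sustainability classes follow the H threshold and pattern", {
  expect_equal(sustainability_class(0.7, "MONO_INC"),
               "Sustainability and monotonically increasing")
  expect_equal(sustainability_class(0.3, "MONO_DEC"),
               "Undetermined future variation trend")
  expect_equal(sustainability_class(0.3, "INC_DEC"),
               "Undetermined future variation trend")
  # H = 0.5 exactly is a random series: undetermined
  expect_equal(sustainability_class(0.5, "MONO_DEC"),
               "Undetermined future variation trend")
  expect_equal(sustainability_class(0.9, "NOT_SIGNIFICANT"),
               "Undetermined future variation trend")
  expect_equal(sustainability_class(0.51, "INC_DEC"),
               "Sustainability and increase then decrease")
})

test_that("stability grades reproduce the full 12-cell lookup", {
  expected <- list(
    list(0.35, "MONO_INC", "HIGH", "XLI"),
    list(0.30, "MONO_DEC", "HIGH", "XXXI"),
    list(0.55, "INC_DEC",  "HIGH", "XXI"),
    list(0.30, "DEC_INC",  "HIGH", "XI"),
    list(0.20, "MONO_INC", "MEDIUM", "XLIII"),
    list(0.11, "MONO_DEC", "MEDIUM", "XXXIII"),
    list(0.29, "INC_DEC",  "MEDIUM", "XIII"),
    list(0.15, "DEC_INC",  "MEDIUM", "XXIII"),
    list(0.05, "MONO_INC", "LOW", "XLII"),
    list(0.10, "MONO_DEC", "LOW", "XXXII"),
    list(0.10, "INC_DEC",  "LOW", "XII"),
    list(0.00, "DEC_INC",  "LOW", "XXII")
  )
  for (e in expected) {
    g <- stability_grade(e[[1]], e[[2]])
    expect_equal(g$fluctuation, e[[3]])
    expect_equal(g$grade, e[[4]])
  }
})

test_that("CV boundaries resolve per the stated inequalities", {
  # 0.3 is HIGH (cv >= 0.3); 0.1 is LOW (cv <= 0.1)
  expect_equal(stability_grade(0.3, "DEC_INC")$grade, "XI")
  expect_equal(stability_grade(0.1, "INC_DEC")$grade, "XII")
  # every cv >= 0 maps to exactly one tier
  cvs <- c(0, 0.05, 0.1, 0.1 + 1e-12, 0.2, 0.3 - 1e-12, 0.3, 1, 10)
  tiers <- vapply(cvs, function(cv) stability_grade(cv, "MONO_INC")$fluctuation,
                  character(1))
  expect_false(anyNA(tiers))
  expect_equal(tiers[cvs <= 0.1], rep("LOW", sum(cvs <= 0.1)))
  expect_equal(tiers[cvs >= 0.3], rep("HIGH", sum(cvs >= 0.3)))

  # no grade for NOT_SIGNIFICANT, labelled NA for undefined CV
  expect_true(is.na(stability_grade(0.2, "NOT_SIGNIFICANT")$grade))
  expect_true(is.na(stability_grade(NA_real_, "MONO_INC")$grade))
})

test_that("the per-pixel persistence table combines H, CV and grades", {
  cf <- scene_config(height = 4, width = 4, seed = 8, nodata_fraction = 0)
  scn <- generate_scene(cf)
  pm <- classify_cube(scn$gpp, eemd_config(ensemble_size = 20, seed = 3))
  tab <- persistence_stability_table(scn$gpp, pm)
  expect_equal(nrow(tab), 16)
  expect_true(all(tab$H >= 0 & tab$H <= 1))
  expect_true(all(tab$cv > 0))
  graded <- tab$pattern != "NOT_SIGNIFICANT"
  expect_false(anyNA(tab$grade[graded]))
  expect_true(all(is.na(tab$grade[!graded])))
})
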