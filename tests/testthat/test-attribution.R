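# Booster tuning and exact interventional Shapley attribution.

test_that("sample tables have one row per unmasked pixel-year", {
  cf <- scene_config(height = 5, width = 4, n_years = 19, seed = 2,
                     nodata_fraction = 0)
  scn <- generate_scene(cf)
  wue <- compute_wue(scn$npp, scn$et)
  tab <- build_sample_table(wue, scn$drivers)
  expect_equal(nrow(tab), 5 * 4 * 19)
  expect_equal(colnames(tab),
               c("pixel_id", "row", "col", "year", driver_names(),
                 "response"))
  expect_equal(attr(tab, "n_dropped"), 0)

  # masking one pixel removes exactly n_years rows
  cf2 <- scene_config(height = 5, width = 4, n_years = 19, seed = 2,
                      nodata_fraction = 1 / 20)
  tab2 <- with(generate_scene(cf2),
               build_sample_table(compute_wue(npp, et), drivers))
  expect_equal(nrow(tab2), (20 - 1) * 19)

  # canonical column order regardless of input list order
  tab3 <- build_sample_table(wue, rev(scn$drivers))
  expect_identical(tab3, tab)

  expect_error(build_sample_table(wue, scn$drivers[1:3]), "missing driver")
})

test_that("interventional Shapley matches hand and oracle computations", {
  # f = x1 * x2, background (0,0), sample (2,3): v({1}) = v({2}) = 0,
  # v(full) = 6 -> contributions (3, 3)
  f <- function(m) m[, 1] * m[, 2]
  a <- shapley_values(
    f, tibble::tibble(temperature = 2, precipitation = 3),
    background = tibble::tibble(temperature = 0, precipitation = 0),
    features = c("temperature", "precipitation"))
  expect_equal(unname(a$shap[1, ]), c(3, 3))
  expect_equal(a$base, 0)

  # additive model: contribution of j is g_j(x_j) - mean g_j(background)
  withr::with_seed(41, {
    tab <- tibble::tibble(temperature = rnorm(25), precipitation = rnorm(25),
                          sunlight = rnorm(25))
  })
  g <- function(m) sin(m[, 1]) + m[, 2]^2 + 0.5 * m[, 3]
  bg <- tab[1:12, ]
  a2 <- shapley_values(g, tab, background = bg, features = colnames(tab))
  expect_equal(a2$shap[, 1], sin(tab$temperature) - mean(sin(bg$temperature)),
               tolerance = 1e-10)
  expect_equal(a2$shap[, 2], tab$precipitation^2 - mean(bg$precipitation^2),
               tolerance = 1e-10)

  # independent permutation-average oracle, 3 features
  for (i in c(2, 9, 17)) {
    oracle <- permutation_shapley(g, as.numeric(tab[i, ]), bg)
    expect_equal(unname(a2$shap[i, ]), oracle, tolerance = 1e-10)
  }

  # efficiency: base + sum of contributions = prediction
  expect_equal(a2$base + rowSums(a2$shap), g(as.matrix(tab)),
               tolerance = 1e-10)
})

test_that("Shapley symmetry and dummy axioms hold", {
  # symmetric features get equal contributions on symmetric samples
  f <- function(m) m[, 1] + m[, 2]
  a <- shapley_values(
    f, tibble::tibble(temperature = 1.5, precipitation = 1.5),
    background = tibble::tibble(temperature = 0, precipitation = 0),
    features = c("temperature", "precipitation"))
  expect_equal(unname(a$shap[1, 1]), unname(a$shap[1, 2]))

  # a feature the model ignores contributes exactly zero
  g <- function(m) m[, 1]^2
  withr::with_seed(5, {
    tab <- tibble::tibble(temperature = rnorm(10), precipitation = rnorm(10))
  })
  a2 <- shapley_values(g, tab, background = tab,
                       features = colnames(tab))
  expect_equal(unname(a2$shap[, 2]), rep(0, 10))
})

test_that("tuning is deterministic and learns a smooth response", {
  tab <- toy_driver_table(n = 400, seed = 3, noise_sd = 0)
  space <- booster_search_space(n_iter = 4, k_folds = 3, seed = 5)
  f1 <- tune_and_fit(tab, space)
  f2 <- tune_and_fit(tab, space)
  expect_identical(f1$report$best_params, f2$report$best_params)
  expect_identical(glance(f1$report), glance(f2$report))
  expect_gt(f1$report$cv_r2, 0.9)
  expect_gt(f1$report$test_r2, 0.9)

  # broom-style accessors
  td <- tidy(f1$report)
  expect_equal(nrow(td), 7)
  expect_true(all(c("parameter", "value") %in% colnames(td)))

  expect_error(tune_and_fit(tab[1:20, ], space), ">= 50 rows")
  tab0 <- tab
  tab0$response <- 1
  expect_error(tune_and_fit(tab0, space), "zero variance")
})

test_that("fitted boosters satisfy Shapley efficiency", {
  tab <- toy_driver_table(n = 300, seed = 7, noise_sd = 0.05)
  fit <- tune_and_fit(tab, booster_search_space(n_iter = 3, k_folds = 3,
                                                seed = 2))
  a <- shapley_values(fit$model, tab[1:80, ], background = 40, seed = 9)
  pred <- predict(fit$model$booster, as.matrix(tab[1:80, driver_names()]))
  rel <- abs(a$base + rowSums(a$shap) - pred) / pmax(abs(pred), 1e-8)
  expect_lt(max(rel), 1e-6)
})

test_that("importance ranking orders by mean |contribution|", {
  tab <- toy_driver_table(n = 300, seed = 11, noise_sd = 0,
                          coefs = c(temperature = 0, precipitation = 0,
                                    sunlight = 0, radiation = 0,
                                    lai = 2, gdp = 0))
  fit <- tune_and_fit(tab, booster_search_space(n_iter = 3, k_folds = 3,
                                                seed = 4))
  a <- shapley_values(fit$model, tab[1:100, ], background = 30, seed = 1)
  rk <- importance_ranking(a)
  expect_equal(rk$feature[1], "lai")
  expect_true(all(rk$mean_abs_contribution >= 0))
  expect_true(all(diff(rk$mean_abs_contribution) <= 0))

  # all-zero matrix: canonical order preserved
  a0 <- a
  a0$shap[] <- 0
  a0$importance <- tibble::tibble(feature = a$features,
                                  mean_abs_contribution = colMeans(abs(a0$shap)))
  rk0 <- importance_ranking(a0)
  expect_equal(rk0$feature, driver_names())
  expect_equal(unname(rk0$mean_abs_contribution), rep(0, 6))
})

test_that("dominant-driver maps aggregate per pixel with canonical ties", {
  # two pixels x 3 years; feature columns named canonically
  keys <- tibble::tibble(pixel_id = rep(1:2, each = 3),
                         row = rep(1L, 6), col = rep(1:2, each = 3),
                         year = rep(2000:2002, 2))
  shap <- cbind(temperature = c(1, 1, 1, 0.2, 0.2, 0.2),
                precipitation = c(0.5, 0.5, 0.5, 0.2, 0.2, 0.2))
  attr_obj <- structure(list(shap = shap, base = 0,
                             prediction = rep(0, 6),
                             importance = tibble::tibble(
                               feature = colnames(shap),
                               mean_abs_contribution = colMeans(abs(shap))),
                             keys = keys,
                             features = colnames(shap)),
                        class = "shap_attribution")
  dom <- dominant_driver_map(attr_obj, grid_dim = c(1, 2))
  expect_equal(dom$dominant_map[1, 1], "temperature")
  # tie at pixel 2: first feature in canonical order wins
  expect_equal(dom$dominant_map[1, 2], "temperature")
  expect_equal(sum(dom$dominant_fraction$fraction), 1)
})

test_that("a planted single-driver response puts that driver on top", {
  cf <- scene_config(height = 6, width = 6, seed = 14, nodata_fraction = 0,
                     response_noise_sd = 0,
                     dominant_field = matrix("lai", 6, 6),
                     secondary_coef = 0)
  scn <- generate_scene(cf)
  wue <- compute_wue(scn$npp, scn$et)
  tab <- build_sample_table(wue, scn$drivers)
  fit <- tune_and_fit(tab, booster_search_space(n_iter = 5, k_folds = 3,
                                                seed = 6))
  a <- shapley_values(fit$model, tab, background = 40, seed = 3)
  expect_equal(importance_ranking(a)$feature[1], "lai")
  dom <- dominant_driver_map(a, grid_dim = attr(tab, "grid_dim"))
  frac <- dom$dominant_fraction
  expect_equal(frac$fraction[frac$feature == "lai"], 1)
})
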