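#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

# Driver attribution: gradient-boosted regression of a CWUE indicator on six
# drivers, tuned by seeded random search with k-fold cross-validation, and
# exact interventional Shapley values by full subset enumeration (2^6 = 64
# coalitions), yielding importance rankings and per-pixel dominant-driver
# maps.

#' Long sample table of pixel-year driver/response rows
#'
#' One row per (unmasked pixel, year) with the six driver values in
#' canonical order ([driver_names()]) and the response. Rows containing any
#' non-finite value are dropped and counted in `attr(, "n_dropped")`. Grid
#' dimensions and the mask travel along as attributes so per-pixel maps can
#' be rebuilt downstream.
#'
#' @param response a [raster_cube()] of the CWUE indicator.
#' @param drivers named list of six [raster_cube()]s; names must cover
#'   [driver_names()] (order is normalized to canonical).
#' @return A tibble with columns `pixel_id`, `row`, `col`, `year`, the six
#'   drivers, `response`.
#' @export
build_sample_table <- function(response, drivers) {
  stopifnot(inherits(response, "raster_cube"))
  missing_drv <- setdiff(driver_names(), names(drivers))
  if (length(missing_drv)) {
    stop("missing driver cubes: ", paste(missing_drv, collapse = ", "),
         call. = FALSE)
  }
  drivers <- drivers[driver_names()]          # canonical column order
  for (nm in driver_names()) {
    check_same_grid(response, drivers[[nm]], check_mask = FALSE)
  }
  d <- dim(response$values)
  mask <- Reduce(`&`, lapply(drivers, `[[`, "mask"), response$mask)
  idx <- which(mask, arr.ind = TRUE)
  n_pix <- nrow(idx)
  pixel_id <- (idx[, 2] - 1L) * d[2] + idx[, 1]   # column-major cell index

  pull_series <- function(cube) {
    as.vector(vapply(seq_len(n_pix),
                     function(i) cube$values[, idx[i, 1], idx[i, 2]],
                     numeric(d[1])))
  }
  tab <- tibble::tibble(
    pixel_id = rep(pixel_id, each = d[1]),
    row = rep(idx[, 1], each = d[1]),
    col = rep(idx[, 2], each = d[1]),
    year = rep(response$years, times = n_pix)
  )
  for (nm in driver_names()) tab[[nm]] <- pull_series(drivers[[nm]])
  tab$response <- pull_series(response)

  finite <- rowSums(!is.finite(as.matrix(tab[c(driver_names(), "response")]))) == 0
  dropped <- sum(!finite)
  tab <- tab[finite, ]
  attr(tab, "n_dropped") <- dropped
  attr(tab, "grid_dim") <- d[2:3]
  attr(tab, "mask") <- mask
  tab
}

#' Hyperparameter search space for the boosted regression
#'
#' Ranges for the tuned booster hyperparameters, the number of random
#' draws, the cross-validation fold count, and the train share of the
#' train/test split. Defaults bracket the optima typically selected for
#' smooth low-dimensional driver-response surfaces.
#'
#' @param n_estimators,learning_rate,max_depth,subsample,colsample_bytree,reg_lambda,reg_alpha
#'   length-2 numeric ranges (min, max) sampled uniformly (integers for
#'   `n_estimators` and `max_depth`).
#' @param n_iter number of random hyperparameter draws (default 200).
#' @param k_folds cross-validation folds on the training split (default 10).
#' @param split_fraction train share of the initial split (default 0.7).
#' @param seed integer seed controlling the split, the folds, the draws and
#'   the booster itself.
#' @return A `booster_search_space` list.
#' @export
booster_search_space <- function(n_estimators = c(50L, 500L),
                                 learning_rate = c(0.01, 0.3),
                                 max_depth = c(2L, 10L),
                                 subsample = c(0.5, 1),
                                 colsample_bytree = c(0.5, 1),
                                 reg_lambda = c(0, 5),
                                 reg_alpha = c(0, 5),
                                 n_iter = 200L, k_folds = 10L,
                                 split_fraction = 0.7, seed = 1L) {
  chk <- function(r, lo_ok) length(r) == 2 && r[1] <= r[2] && r[1] >= lo_ok
  stopifnot(chk(n_estimators, 1), chk(learning_rate, 1e-6),
            chk(max_depth, 1), chk(subsample, 1e-6), subsample[2] <= 1,
            chk(colsample_bytree, 1e-6), colsample_bytree[2] <= 1,
            chk(reg_lambda, 0), chk(reg_alpha, 0),
            n_iter >= 1, k_folds >= 2, split_fraction > 0, split_fraction < 1)
  structure(list(n_estimators = n_estimators, learning_rate = learning_rate,
                 max_depth = max_depth, subsample = subsample,
                 colsample_bytree = colsample_bytree,
                 reg_lambda = reg_lambda, reg_alpha = reg_alpha,
                 n_iter = as.integer(n_iter), k_folds = as.integer(k_folds),
                 split_fraction = split_fraction, seed = as.integer(seed)),
            class = "booster_search_space")
}

draw_params <- function(space, n_iter) {
  runif_rng <- function(r, n) stats::runif(n, r[1], r[2])
  tibble::tibble(
    n_estimators = as.integer(round(runif_rng(space$n_estimators, n_iter))),
    learning_rate = runif_rng(space$learning_rate, n_iter),
    max_depth = as.integer(round(runif_rng(space$max_depth, n_iter))),
    subsample = runif_rng(space$subsample, n_iter),
    colsample_bytree = runif_rng(space$colsample_bytree, n_iter),
    reg_lambda = runif_rng(space$reg_lambda, n_iter),
    reg_alpha = runif_rng(space$reg_alpha, n_iter)
  )
}

fit_booster <- function(x, y, p, seed) {
  dm <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
  xgboost::xgb.train(
    params = list(
      objective = "reg:squarederror",
      eta = p$learning_rate,
      max_depth = p$max_depth,
      subsample = p$subsample,
      colsample_bytree = p$colsample_bytree,
      lambda = p$reg_lambda,
      alpha = p$reg_alpha,
      nthread = 1,
      seed = seed
    ),
    data = dm, nrounds = p$n_estimators, verbose = 0
  )
}

rmse <- function(obs, pred) sqrt(mean((obs - pred)^2))
r_squared <- function(obs, pred) 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)

#' Tune and fit the boosted driver-response regression
#'
#' Splits the table into train/test by `split_fraction`, draws `n_iter`
#' hyperparameter vectors uniformly from the space, scores each by k-fold
#' cross-validated mean RMSE on the training split, refits the best vector
#' on the full training split, and reports held-out metrics. Fully
#' deterministic given `space$seed` (single-threaded boosting, seeded
#' splits, folds and draws).
#'
#' @param table a [build_sample_table()] tibble (or any tibble with the six
#'   driver columns and `response`), at least 50 rows.
#' @param space a [booster_search_space()].
#' @return List with `model` (a `cwue_booster`) and `report` (a
#'   `booster_fit_report`: best hyperparameters, `cv_rmse`, `cv_r2`,
#'   `test_rmse`, `test_r2`).
#' @export
tune_and_fit <- function(table, space = booster_search_space()) {
  stopifnot(inherits(space, "booster_search_space"))
  n <- nrow(table)
  if (n < 50) stop("need >= 50 rows to tune", call. = FALSE)
  y <- table$response
  if (var(y) == 0) stop("degenerate response: zero variance", call. = FALSE)
  x <- as.matrix(table[driver_names()])

  withr::with_seed(space$seed, {
    n_train <- round(space$split_fraction * n)
    train_idx <- sample.int(n, n_train)
    params <- draw_params(space, space$n_iter)
    fold_of <- sample(rep_len(seq_len(space$k_folds), n_train))
  })
  if (space$k_folds > n_train) {
    stop("k_folds exceeds training rows", call. = FALSE)
  }
  xtr <- x[train_idx, , drop = FALSE]
  ytr <- y[train_idx]
  xte <- x[-train_idx, , drop = FALSE]
  yte <- y[-train_idx]

  scores <- purrr::map_dfr(seq_len(space$n_iter), function(i) {
    p <- params[i, ]
    fold_stats <- vapply(seq_len(space$k_folds), function(k) {
      hold <- fold_of == k
      fit <- fit_booster(xtr[!hold, , drop = FALSE], ytr[!hold], p,
                         seed = space$seed + i)
      pred <- predict(fit, xtr[hold, , drop = FALSE])
      c(rmse(ytr[hold], pred), r_squared(ytr[hold], pred))
    }, numeric(2))
    tibble::tibble(iter = i, cv_rmse = mean(fold_stats[1, ]),
                   cv_r2 = mean(fold_stats[2, ]))
  })
  best_i <- scores$iter[which.min(scores$cv_rmse)]
  best <- params[best_i, ]
  final <- fit_booster(xtr, ytr, best, seed = space$seed + best_i)
  pred_te <- predict(final, xte)

  report <- structure(list(
    best_params = as.list(best),
    cv_rmse = scores$cv_rmse[best_i],
    cv_r2 = scores$cv_r2[best_i],
    test_rmse = rmse(yte, pred_te),
    test_r2 = r_squared(yte, pred_te),
    n_train = n_train, n_test = n - n_train,
    k_folds = space$k_folds, n_iter = space$n_iter
  ), class = "booster_fit_report")
  model <- structure(list(booster = final, features = driver_names(),
                          seed = space$seed),
                     class = "cwue_booster")
  list(model = model, report = report)
}

#' @export
print.booster_fit_report <- function(x, ...) {
  cat(sprintf(
    "<booster_fit_report> cv_rmse %.4f, cv_r2 %.4f | test_rmse %.4f, test_r2 %.4f\n",
    x$cv_rmse, x$cv_r2, x$test_rmse, x$test_r2))
  cat("  best:", paste(names(x$best_params),
                       vapply(x$best_params, format, character(1), digits = 4),
                       sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.cwue_booster <- function(x, ...) {
  cat("<cwue_booster> boosted regression on:",
      paste(x$features, collapse = ", "), "\n")
  invisible(x)
}

#' Tidy the tuned-booster fit report
#'
#' `tidy()` returns one row per tuned hyperparameter; `glance()` returns a
#' one-row tibble of fit metrics.
#'
#' @param x a `booster_fit_report` from [tune_and_fit()].
#' @param ... unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.booster_fit_report <- function(x, ...) {
  tibble::tibble(parameter = names(x$best_params),
                 value = as.numeric(unlist(x$best_params)))
}

#' @rdname tidy.booster_fit_report
#' @exportS3Method generics::glance
glance.booster_fit_report <- function(x, ...) {
  tibble::tibble(cv_rmse = x$cv_rmse, cv_r2 = x$cv_r2,
                 test_rmse = x$test_rmse, test_r2 = x$test_r2,
                 n_train = x$n_train, n_test = x$n_test,
                 k_folds = x$k_folds, n_iter = x$n_iter)
}

model_predict <- function(model, x) {
  if (inherits(model, "cwue_booster")) {
    predict(model$booster, x)
  } else if (is.function(model)) {
    model(x)
  } else {
    stop("`model` must be a cwue_booster or a prediction function",
         call. = FALSE)
  }
}

model_features <- function(model, table) {
  if (inherits(model, "cwue_booster")) model$features
  else intersect(driver_names(), colnames(table))
}

#' Exact interventional Shapley values
#'
#' For every sample and feature, enumerates all feature coalitions (2^k
#' subsets). The value of coalition `s` is the mean model prediction with
#' features in `s` fixed at the sample's values and the remaining features
#' replaced by each background row in turn. Contributions combine the
#' marginal gains `v(s) - v(s \ i)` with the Shapley weights
#' `(k - |s|)! (|s| - 1)! / k!`. The base value is the mean prediction over
#' the background. By construction `base + sum(contributions)` equals the
#' model prediction for every sample (local accuracy).
#'
#' @param model a `cwue_booster` from [tune_and_fit()], or any function
#'   mapping a numeric feature matrix to predictions (used with small toy
#'   models).
#' @param table tibble containing the model's feature columns; one row per
#'   sample to explain. If `pixel_id`/`row`/`col` columns are present they
#'   are carried into the result for mapping.
#' @param background background sample: a tibble/matrix of feature rows, or
#'   an integer count (default 100) of rows drawn from `table` with `seed`.
#' @param features feature column names; defaults to the model's features.
#' @param seed seed for the default background draw.
#' @return A `shap_attribution`: list with `shap` (sample x feature matrix
#'   of contributions, response units), `base` (background mean
#'   prediction), `prediction` (per-sample model output), `importance`
#'   (tibble of mean |contribution| per feature, sorted), and the carried
#'   sample keys.
#' @export
shapley_values <- function(model, table, background = 100L,
                           features = NULL, seed = 1L) {
  if (is.null(features)) features <- model_features(model, table)
  if (!all(features %in% colnames(table))) {
    stop("feature-name mismatch: table lacks ",
         paste(setdiff(features, colnames(table)), collapse = ", "),
         call. = FALSE)
  }
  x <- as.matrix(table[features])
  k <- length(features)
  if (is.numeric(background) && length(background) == 1) {
    n_bg <- min(as.integer(background), nrow(x))
    bg_idx <- withr::with_seed(as.integer(seed),
                               sample.int(nrow(x), n_bg))
    bg <- x[bg_idx, , drop = FALSE]
  } else {
    bg <- as.matrix(as.data.frame(background)[, features, drop = FALSE])
  }
  if (nrow(bg) == 0) stop("background is empty", call. = FALSE)

  n <- nrow(x)
  m <- nrow(bg)
  n_sub <- 2^k
  # subset membership matrix: n_sub x k logicals
  members <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), k)))
  colnames(members) <- features
  sizes <- rowSums(members)
  # v[i, s]: mean prediction with subset s from the sample, rest background
  v <- matrix(0, n, n_sub)
  for (s in seq_len(n_sub)) {
    sel <- members[s, ]
    # hybrid rows: for each (sample, background) pair
    hyb <- bg[rep(seq_len(m), times = n), , drop = FALSE]
    if (any(sel)) {
      samp_part <- x[rep(seq_len(n), each = m), sel, drop = FALSE]
      hyb[, sel] <- samp_part
    }
    pred <- model_predict(model, hyb)
    v[, s] <- colMeans(matrix(pred, m, n))
  }
  # Shapley combination: phi_j = sum over subsets s containing j of
  # w(|s|) * (v(s) - v(s \ j)), with w(q) = (k-q)! (q-1)! / k!
  wts <- exp(lgamma(k - seq_len(k) + 1) + lgamma(seq_len(k)) - lgamma(k + 1))
  phi <- matrix(0, n, k, dimnames = list(NULL, features))
  # index of s \ j: flip bit j
  pow <- 2^(seq_len(k) - 1)
  for (s in seq_len(n_sub)) {
    sel <- members[s, ]
    q <- sizes[s]
    if (q == 0) next
    for (j in which(sel)) {
      s_minus <- s - pow[j]
      phi[, j] <- phi[, j] + wts[q] * (v[, s] - v[, s_minus])
    }
  }
  base <- mean(model_predict(model, bg))
  importance <- tibble::tibble(
    feature = features,
    mean_abs_contribution = colMeans(abs(phi))
  )
  importance <- importance[order(-importance$mean_abs_contribution,
                                 match(importance$feature, features)), ]
  keys <- intersect(c("pixel_id", "row", "col", "year"), colnames(table))
  structure(list(shap = phi, base = base,
                 prediction = v[, n_sub],
                 importance = importance,
                 keys = table[keys],
                 features = features),
            class = "shap_attribution")
}

#' @export
print.shap_attribution <- function(x, ...) {
  cat(sprintf("<shap_attribution> %d samples x %d features, base = %.4f\n",
              nrow(x$shap), ncol(x$shap), x$base))
  print(x$importance)
  invisible(x)
}

#' Global driver importance ranking
#'
#' Features sorted by decreasing mean absolute Shapley contribution over
#' all samples; ties resolve to canonical driver order.
#'
#' @param attr a `shap_attribution` from [shapley_values()].
#' @return Tibble `feature`, `mean_abs_contribution`, `rank`.
#' @export
importance_ranking <- function(attr) {
  stopifnot(inherits(attr, "shap_attribution"))
  out <- attr$importance
  out$rank <- seq_len(nrow(out))
  out
}

#' Per-pixel dominant driver map
#'
#' Averages |contribution| over each pixel's years per feature; the
#' dominant driver is the feature with the largest mean (ties broken by
#' canonical driver order). Fractions are shares of retained pixels and
#' sum to 1.
#'
#' @param attr a `shap_attribution` whose samples carry `pixel_id`, `row`,
#'   `col` keys (as produced from a [build_sample_table()] table).
#' @param grid_dim optional `(y, x)` dimensions for the output matrix;
#'   defaults to the maximum row/col seen.
#' @return List with `dominant_map` (`(y, x)` character matrix, `NA` off
#'   the retained pixels), `dominant_fraction` (tibble `feature`,
#'   `n_pixels`, `fraction` over all six drivers), and `pixel_importance`
#'   (tibble of per-pixel mean |contribution| per feature).
#' @export
dominant_driver_map <- function(attr, grid_dim = NULL) {
  stopifnot(inherits(attr, "shap_attribution"))
  keys <- attr$keys
  if (!all(c("pixel_id", "row", "col") %in% colnames(keys))) {
    stop("attribution lacks pixel keys; build the table with ",
         "build_sample_table()", call. = FALSE)
  }
  df <- dplyr::bind_cols(keys[c("pixel_id", "row", "col")],
                         tibble::as_tibble(abs(attr$shap)))
  per_pixel <- df |>
    dplyr::group_by(.data$pixel_id, .data$row, .data$col) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(attr$features), mean),
                     .groups = "drop")
  imp <- as.matrix(per_pixel[attr$features])
  # argmax with canonical-order tie-break: max.col("first") on the matrix
  # whose columns are already in canonical order
  dom <- attr$features[max.col(imp, ties.method = "first")]
  if (is.null(grid_dim)) grid_dim <- c(max(per_pixel$row), max(per_pixel$col))
  dominant_map <- matrix(NA_character_, grid_dim[1], grid_dim[2])
  dominant_map[cbind(per_pixel$row, per_pixel$col)] <- dom
  counts <- table(factor(dom, levels = attr$features))
  fraction <- tibble::tibble(
    feature = attr$features,
    n_pixels = as.integer(counts),
    fraction = as.numeric(counts) / nrow(per_pixel)
  )
  per_pixel$dominant <- dom
  list(dominant_map = dominant_map, dominant_fraction = fraction,
       pixel_importance = per_pixel)
}
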