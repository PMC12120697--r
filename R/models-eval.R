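#' Regression error metrics
#'
#' The four metrics used to compare droplet-volume models: mean absolute
#' error, mean squared error, its square root, and the coefficient of
#' determination `R2 = 1 - SSres/SStot`. `R2` is `NaN` (with a warning) when
#' the observed values have zero variance, and may be negative for a
#' worse-than-mean predictor.
#'
#' @param truth Observed values.
#' @param estimate Predicted values, same length.
#' @return A one-row tibble: `mae`, `mse`, `rmse`, `r2`.
#' @examples
#' regression_metrics(c(1, 2, 3), c(1, 2, 4))
#' @export
regression_metrics <- function(truth, estimate) {
  stopifnot(length(truth) == length(estimate), length(truth) >= 1)
  res <- truth - estimate
  mse <- mean(res^2)
  sstot <- sum((truth - mean(truth))^2)
  r2 <- if (sstot == 0) {
    warning("zero-variance truth: R-squared is undefined (NaN)")
    NaN
  } else {
    1 - sum(res^2) / sstot
  }
  tibble::tibble(mae = mean(abs(res)), mse = mse, rmse = sqrt(mse), r2 = r2)
}

#' Evaluate a fitted model on held-out records
#'
#' @param model A [fit_droplet_model()] result.
#' @param test_records Data frame with feature columns and `volume_uL`.
#' @return A one-row tibble: `algorithm`, `mae`, `mse`, `rmse`, `r2`,
#'   `train_time_ms`, `test_time_ms`.
#' @export
evaluate_model <- function(model, test_records) {
  stopifnot(inherits(model, "droplet_model"))
  check_records(test_records)
  t0 <- proc.time()[3]
  pred <- stats::predict(model, test_records)
  test_time_ms <- unname((proc.time()[3] - t0) * 1000)
  m <- regression_metrics(test_records$volume_uL, pred)
  dplyr::bind_cols(
    tibble::tibble(algorithm = model$spec$algorithm), m,
    tibble::tibble(train_time_ms = model$train_time_ms,
                   test_time_ms = test_time_ms)
  )
}

#' Split records into training and testing sets
#'
#' Seeded uniform shuffle followed by a split at `floor(fraction * n)`:
#' 1758 records at the default 70% fraction give 1230 training and 528
#' testing records.
#'
#' @param records Data frame (>= 10 rows).
#' @param fraction Training fraction, strictly inside (0, 1).
#' @param seed Integer seed.
#' @return An object of class `dataset_split`: list with `train`, `test`
#'   (disjoint tibbles covering the input), `fraction`, `seed`.
#' @export
split_dataset <- function(records, fraction = 0.7, seed = 1L) {
  stopifnot(is.data.frame(records))
  if (nrow(records) < 10) {
    stop_dropsizer("Need at least 10 records to split.",
                   class = "dropsizer_error_config")
  }
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1) {
    stop_dropsizer("`fraction` must lie strictly between 0 and 1.",
                   class = "dropsizer_error_config")
  }
  n <- nrow(records)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  ord <- sample.int(n)
  n_train <- floor(fraction * n)
  structure(
    list(train = tibble::as_tibble(records[ord[seq_len(n_train)], , drop = FALSE]),
         test = tibble::as_tibble(records[ord[(n_train + 1):n], , drop = FALSE]),
         fraction = fraction, seed = as.integer(seed)),
    class = "dataset_split"
  )
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split> %d train / %d test (fraction %.2f, seed %d)\n",
              nrow(x$train), nrow(x$test), x$fraction, x$seed))
  invisible(x)
}

#' k-fold cross-validation of one model specification
#'
#' Partitions the training records into `k` near-equal seeded folds; each
#' fold serves once as the validation set for a model trained on the
#' remaining `k - 1` folds. Per-fold train and validation MAE, MSE, RMSE and
#' R2 are recorded together with wall-clock fit and validation times, and
#' averaged.
#'
#' @param train_records Data frame with features and `volume_uL`.
#' @param spec A [model_spec()].
#' @param k Number of folds (>= 2, <= number of records).
#' @param seed Seed for the fold partition; defaults to the spec's seed.
#' @return An object of class `droplet_cv`: list with `folds` (per-fold
#'   metric tibble), `summary` (mean and sd per metric), `assignments`
#'   (fold id per record), `spec`, `k`.
#' @export
kfold_cv <- function(train_records, spec, k = 10, seed = spec$seed) {
  stopifnot(inherits(spec, "model_spec"))
  check_records(train_records)
  n <- nrow(train_records)
  if (k < 2 || k > n) {
    stop_dropsizer("`k` must satisfy 2 <= k <= number of records.",
                   class = "dropsizer_error_config")
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  assignments <- integer(n)
  assignments[sample.int(n)] <- rep_len(seq_len(k), n)

  folds <- purrr::map(seq_len(k), function(fold) {
    tr <- train_records[assignments != fold, , drop = FALSE]
    va <- train_records[assignments == fold, , drop = FALSE]
    model <- fit_droplet_model(tr, spec)
    t0 <- proc.time()[3]
    pv <- stats::predict(model, va)
    val_time_ms <- unname((proc.time()[3] - t0) * 1000)
    pt <- stats::predict(model, tr)
    mt <- regression_metrics(tr$volume_uL, pt)
    mv <- regression_metrics(va$volume_uL, pv)
    tibble::tibble(
      fold = fold,
      train_mae = mt$mae, val_mae = mv$mae,
      train_rmse = mt$rmse, val_rmse = mv$rmse,
      train_r2 = mt$r2, val_r2 = mv$r2,
      train_mse = mt$mse, val_mse = mv$mse,
      train_time_ms = model$train_time_ms, val_time_ms = val_time_ms
    )
  })
  folds <- dplyr::bind_rows(folds)
  summary <- folds |>
    tidyr::pivot_longer(-"fold", names_to = "metric") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value),
                     sd = stats::sd(.data$value), .groups = "drop")
  structure(list(folds = folds, summary = summary,
                 assignments = assignments, spec = spec, k = k),
            class = "droplet_cv")
}

#' @export
print.droplet_cv <- function(x, ...) {
  s <- x$summary
  g <- function(m) s$mean[s$metric == m]
  cat(sprintf(
    "<droplet_cv> %s, %d folds: val RMSE %.4g (train %.4g), val R2 %.4f\n",
    x$spec$algorithm, x$k, g("val_rmse"), g("train_rmse"), g("val_r2")))
  invisible(x)
}

#' Exhaustive grid search over hyperparameters
#'
#' Evaluates every combination in `grid` by [kfold_cv()] and selects the
#' one minimizing mean validation RMSE; exact ties go to the simpler model
#' (smaller values of the grid variables, compared in column order). The
#' full trace of mean train/validation metrics per combination supports
#' optimization-curve plots via [ggplot2::autoplot()].
#'
#' @param train_records Data frame with features and `volume_uL`.
#' @param algorithm Algorithm name as in [model_spec()].
#' @param grid Named list of hyperparameter value vectors (crossed), or a
#'   data frame of explicit combinations.
#' @param k Folds per evaluation.
#' @param seed Seed for fold partitions and training.
#' @return An object of class `droplet_grid_search`: list with `best_spec`,
#'   `trace` (one row per combination) and `algorithm`.
#' @export
grid_search <- function(train_records, algorithm, grid, k = 10, seed = 1L) {
  if (is.data.frame(grid)) {
    combos <- grid
  } else {
    if (!is.list(grid) || length(grid) == 0 || is.null(names(grid))) {
      stop_dropsizer("`grid` must be a non-empty named list or data frame.",
                     class = "dropsizer_error_config")
    }
    combos <- do.call(tidyr::expand_grid, grid)
  }
  if (nrow(combos) == 0) {
    stop_dropsizer("Empty hyperparameter grid.", class = "dropsizer_error_config")
  }
  rows <- purrr::map(seq_len(nrow(combos)), function(i) {
    hp <- as.list(combos[i, , drop = FALSE])
    spec <- do.call(model_spec, c(list(algorithm = algorithm), hp,
                                  list(seed = seed)))
    cv <- kfold_cv(train_records, spec, k = k, seed = seed)
    s <- cv$summary
    g <- function(m) s$mean[s$metric == m]
    dplyr::bind_cols(
      combos[i, , drop = FALSE],
      tibble::tibble(
        train_mae = g("train_mae"), val_mae = g("val_mae"),
        train_rmse = g("train_rmse"), val_rmse = g("val_rmse"),
        train_r2 = g("train_r2"), val_r2 = g("val_r2"),
        train_mse = g("train_mse"), val_mse = g("val_mse")
      )
    )
  })
  trace <- dplyr::bind_rows(rows)
  ord <- do.call(order, c(list(trace$val_rmse),
                          lapply(names(combos), function(nm) trace[[nm]])))
  best_row <- ord[1]
  best_spec <- do.call(model_spec,
                       c(list(algorithm = algorithm),
                         as.list(combos[best_row, , drop = FALSE]),
                         list(seed = seed)))
  structure(list(best_spec = best_spec, trace = trace, algorithm = algorithm),
            class = "droplet_grid_search")
}

#' @export
print.droplet_grid_search <- function(x, ...) {
  cat(sprintf("<droplet_grid_search> %s over %d combinations\n",
              x$algorithm, nrow(x$trace)))
  print(x$best_spec)
  invisible(x)
}

#' Normalized impurity-based feature importance
#'
#' Fits a random forest and reports, per print parameter, the total
#' variance (squared-error impurity) reduction accumulated over all split
#' nodes, averaged across trees and normalized so the importances sum to
#' one. A constant response yields all-zero reductions; uniform weights are
#' then reported with a warning.
#'
#' @param records Data frame with features and `volume_uL`.
#' @param spec A random-forest [model_spec()].
#' @return A tibble `feature`, `importance`, sorted decreasing.
#' @export
feature_importance <- function(records, spec = model_spec("random_forest")) {
  stopifnot(inherits(spec, "model_spec"), spec$algorithm == "random_forest")
  check_records(records)
  model <- fit_droplet_model(records, spec)
  imp <- randomForest::importance(model$fit, type = 2)[, 1]
  imp[!is.finite(imp)] <- 0
  if (sum(imp) <= 0) {
    warning("constant response: reporting uniform feature importances")
    imp[] <- 1
  }
  tibble::tibble(feature = feature_names(),
                 importance = unname(imp[feature_names()]) / sum(imp)) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}

#' Compare regression algorithms over repeated seeded runs
#'
#' For each repeat the dataset is re-split 70/30 with a fresh seed, every
#' spec is re-seeded, trained on the training portion and evaluated on the
#' testing portion. Per-algorithm means and standard deviations of MAE,
#' RMSE and R2 plus mean train/test wall-clock times are reported. A
#' failure in one algorithm is recorded and does not abort the others.
#'
#' @param records Data frame with features and `volume_uL`.
#' @param specs List of [model_spec()] objects (>= 1).
#' @param repeats Number of independent train/evaluate iterations.
#' @param seed Base seed; repeat `r` uses `seed + r`.
#' @param fraction Training fraction per repeat.
#' @return An object of class `droplet_comparison`: list with `summary`
#'   (one row per algorithm) and `runs` (one row per algorithm x repeat).
#' @export
compare_algorithms <- function(records, specs, repeats = 10, seed = 1L,
                               fraction = 0.7) {
  stopifnot(length(specs) >= 1, repeats >= 1)
  runs <- purrr::map(seq_len(repeats), function(r) {
    sp <- split_dataset(records, fraction = fraction, seed = seed + r)
    purrr::map(specs, function(spec) {
      spec$seed <- as.integer(seed + r)
      tryCatch({
        model <- fit_droplet_model(sp$train, spec)
        ev <- evaluate_model(model, sp$test)
        dplyr::bind_cols(tibble::tibble(repeat_id = r), ev,
                         tibble::tibble(status = "ok"))
      }, error = function(e) {
        tibble::tibble(repeat_id = r, algorithm = spec$algorithm,
                       mae = NA_real_, mse = NA_real_, rmse = NA_real_,
                       r2 = NA_real_, train_time_ms = NA_real_,
                       test_time_ms = NA_real_,
                       status = paste0("error: ", conditionMessage(e)))
      })
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()

  summary <- runs |>
    dplyr::filter(.data$status == "ok") |>
    dplyr::group_by(.data$algorithm) |>
    dplyr::summarise(
      mae_mean = mean(.data$mae), mae_sd = sd0(.data$mae),
      rmse_mean = mean(.data$rmse), rmse_sd = sd0(.data$rmse),
      r2_mean = mean(.data$r2), r2_sd = sd0(.data$r2),
      train_time_ms = mean(.data$train_time_ms),
      test_time_ms = mean(.data$test_time_ms),
      n_runs = dplyr::n(), .groups = "drop"
    )
  # preserve the input spec order
  order_idx <- match(vapply(specs, function(s) s$algorithm, character(1)),
                     summary$algorithm)
  summary <- summary[order_idx[!is.na(order_idx)], , drop = FALSE]
  structure(list(summary = summary, runs = runs), class = "droplet_comparison")
}

sd0 <- function(x) if (length(x) < 2) 0 else stats::sd(x)

#' @export
print.droplet_comparison <- function(x, ...) {
  cat("<droplet_comparison>\n")
  print(as.data.frame(x$summary), digits = 4, row.names = FALSE)
  invisible(x)
}
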