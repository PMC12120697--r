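#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy per-fold cross-validation metrics
#'
#' @param x A [kfold_cv()] result.
#' @param ... Unused.
#' @return The per-fold metric tibble (one row per fold).
#' @export
tidy.droplet_cv <- function(x, ...) x$folds

#' One-row cross-validation summary
#'
#' @param x A [kfold_cv()] result.
#' @param ... Unused.
#' @return A one-row tibble of the fold-averaged metrics.
#' @export
glance.droplet_cv <- function(x, ...) {
  wide <- stats::setNames(as.list(x$summary$mean), x$summary$metric)
  dplyr::bind_cols(
    tibble::tibble(algorithm = x$spec$algorithm, k = x$k),
    tibble::as_tibble(wide)
  )
}

#' Tidy a grid-search trace
#'
#' @param x A [grid_search()] result.
#' @param ... Unused.
#' @return The trace tibble, one row per hyperparameter combination.
#' @export
tidy.droplet_grid_search <- function(x, ...) x$trace

#' Tidy a model-comparison result
#'
#' @param x A [compare_algorithms()] result.
#' @param ... Unused.
#' @return The per-run tibble (algorithm x repeat).
#' @export
tidy.droplet_comparison <- function(x, ...) x$runs

#' Per-algorithm comparison summary
#'
#' @param x A [compare_algorithms()] result.
#' @param ... Unused.
#' @return The summary tibble, one row per algorithm (mean and sd of MAE,
#'   RMSE, R2 plus mean train/test times).
#' @export
glance.droplet_comparison <- function(x, ...) x$summary

#' Tidy a fitted droplet model
#'
#' Polynomial models report their non-zero monomial coefficients; tree
#' models report per-feature importance; network models report layer sizes.
#'
#' @param x A [fit_droplet_model()] result.
#' @param ... Unused.
#' @return A tibble whose shape depends on the engine.
#' @export
tidy.droplet_model <- function(x, ...) {
  switch(x$spec$algorithm,
    polynomial_regression = {
      expo <- x$fit$exponents
      term <- apply(expo, 1, function(e) {
        if (all(e == 0)) return("(Intercept)")
        paste0(feature_names()[e > 0], "^", e[e > 0], collapse = " * ")
      })
      tibble::tibble(term = term, estimate = unname(x$fit$coefficients)) |>
        dplyr::filter(.data$estimate != 0)
    },
    decision_tree = {
      imp <- x$fit$variable.importance
      tibble::tibble(feature = names(imp), importance = unname(imp) / sum(imp))
    },
    random_forest = {
      imp <- randomForest::importance(x$fit, type = 2)[, 1]
      tibble::tibble(feature = names(imp), importance = unname(imp) / sum(imp))
    },
    mlp = tibble::tibble(layer = seq_along(x$fit$sizes) - 1,
                         units = x$fit$sizes),
    lstm = tibble::tibble(component = c("inputs", "units"),
                          size = c(nrow(x$fit$params$Wi), x$fit$units))
  )
}

#' One-row fitted-model summary
#'
#' @param x A [fit_droplet_model()] result.
#' @param ... Unused.
#' @return A one-row tibble: algorithm, training size, training time.
#' @export
glance.droplet_model <- function(x, ...) {
  tibble::tibble(algorithm = x$spec$algorithm, n_train = x$n_train,
                 train_time_ms = x$train_time_ms)
}

#' Optimization curve of a grid search
#'
#' Mean train and validation RMSE against the (first) grid variable, the
#' standard picture for reading off under- and over-fitting.
#'
#' @param object A [grid_search()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.droplet_grid_search <- function(object, ...) {
  var <- names(object$trace)[1]
  df <- object$trace |>
    dplyr::select(dplyr::all_of(var), "train_rmse", "val_rmse") |>
    tidyr::pivot_longer(-dplyr::all_of(var),
                        names_to = "set", values_to = "rmse") |>
    dplyr::mutate(set = sub("_rmse$", "", .data$set))
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[var]], y = .data$rmse,
                                   colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = var, y = "RMSE (uL)", colour = NULL,
                  title = paste("Hyperparameter tuning:", object$algorithm))
}

#' Bar chart of a model comparison
#'
#' @param object A [compare_algorithms()] result.
#' @param metric One of `"mae"`, `"rmse"`, `"r2"`.
#' @param ... Unused.
#' @return A ggplot object with mean +/- sd error bars.
#' @export
autoplot.droplet_comparison <- function(object, metric = c("rmse", "mae", "r2"),
                                        ...) {
  metric <- match.arg(metric)
  mcol <- paste0(metric, "_mean"); scol <- paste0(metric, "_sd")
  df <- object$summary
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$algorithm,
                                                      .data[[mcol]]),
                                   y = .data[[mcol]])) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data[[mcol]] - .data[[scol]],
                                        ymax = .data[[mcol]] + .data[[scol]]),
                           width = 0.2) +
    ggplot2::labs(x = NULL, y = toupper(metric)) +
    ggplot2::coord_flip()
}

#' Bar chart of normalized feature importance
#'
#' @param importance Tibble from [feature_importance()].
#' @return A ggplot object.
#' @export
plot_importance <- function(importance) {
  ggplot2::ggplot(importance,
                  ggplot2::aes(x = stats::reorder(.data$feature,
                                                  .data$importance),
                               y = .data$importance)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "normalized importance")
}
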