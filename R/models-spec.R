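#' Specification of a droplet-volume regression model
#'
#' Bundles an algorithm name, its hyperparameters and a seed. Missing
#' hyperparameters are filled with the package defaults, which correspond to
#' the tuned configurations used throughout: decision tree of depth 7,
#' random forest with 10 estimators, degree-7 polynomial regression, and
#' 100-epoch MLP / LSTM trained with Adam at learning rate 1e-3, batch 32.
#'
#' @param algorithm One of `"decision_tree"`, `"random_forest"`,
#'   `"polynomial_regression"`, `"mlp"`, `"lstm"`.
#' @param ... Hyperparameter overrides (e.g. `max_depth = 5`).
#' @param seed Integer seed controlling any training randomness.
#' @return An object of class `model_spec`.
#' @examples
#' model_spec("decision_tree", max_depth = 7)
#' @export
model_spec <- function(algorithm = c("decision_tree", "random_forest",
                                     "polynomial_regression", "mlp", "lstm"),
                       ..., seed = 1L) {
  algorithm <- match.arg(algorithm)
  defaults <- switch(algorithm,
    decision_tree = list(max_depth = 7, min_samples_split = 2,
                         min_samples_leaf = 1),
    random_forest = list(n_estimators = 10, criterion = "squared_error",
                         max_depth = NULL, min_samples_split = 2,
                         min_samples_leaf = 1),
    polynomial_regression = list(degree = 7),
    mlp = list(epochs = 100, learning_rate = 1e-3, batch_size = 32,
               hidden = c(64, 32)),
    lstm = list(epochs = 100, learning_rate = 1e-3, batch_size = 32,
                units = 32)
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) {
    stop_dropsizer(paste0("Unknown hyperparameter(s) for ", algorithm, ": ",
                          paste(unknown, collapse = ", ")),
                   class = "dropsizer_error_config")
  }
  hp <- utils::modifyList(defaults, over, keep.null = TRUE)
  if (algorithm == "random_forest" && hp$criterion != "squared_error") {
    stop_dropsizer("Only the squared-error split criterion is supported.",
                   class = "dropsizer_error_config")
  }
  structure(list(algorithm = algorithm, hyperparameters = hp,
                 seed = as.integer(seed)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  hp <- vapply(x$hyperparameters, function(v) {
    if (is.null(v)) "NULL" else paste(format(v), collapse = ",")
  }, character(1))
  cat(sprintf("<model_spec> %s (seed %d)\n  %s\n", x$algorithm, x$seed,
              paste(names(hp), hp, sep = " = ", collapse = "; ")))
  invisible(x)
}

#' The five default model specifications
#'
#' @param seed Seed applied to every spec.
#' @return Named list of five [model_spec()] objects at the package-default
#'   (tuned) hyperparameters.
#' @export
default_model_specs <- function(seed = 1L) {
  algs <- c("decision_tree", "random_forest", "polynomial_regression",
            "mlp", "lstm")
  stats::setNames(lapply(algs, function(a) model_spec(a, seed = seed)), algs)
}

#' Fit a droplet-volume regression model
#'
#' Trains the algorithm named by `spec` on the five print parameters
#' (see [feature_names()]) with `volume_uL` as the response. Features are
#' standardized to zero mean / unit variance for the polynomial, MLP and
#' LSTM engines (trees are scale-invariant and get raw features); the
#' network engines additionally standardize the response internally and
#' un-scale their predictions. Training is fully seeded and the wall-clock
#' training time is recorded.
#'
#' @param records Data frame with the feature columns and `volume_uL`.
#' @param spec A [model_spec()].
#' @return An object of class `droplet_model`.
#' @export
fit_droplet_model <- function(records, spec) {
  stopifnot(inherits(spec, "model_spec"))
  check_records(records)
  X <- as.matrix(records[feature_names()])
  y <- records$volume_uL
  hp <- spec$hyperparameters

  scaled <- spec$algorithm %in% c("polynomial_regression", "mlp", "lstm")
  xc <- colMeans(X)
  xs <- apply(X, 2, stats::sd)
  xs[!is.finite(xs) | xs == 0] <- 1
  Xs <- if (scaled) sweep(sweep(X, 2, xc), 2, xs, "/") else X
  yc <- mean(y)
  ys <- stats::sd(y)
  if (!is.finite(ys) || ys == 0) ys <- 1

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(spec$seed)

  t0 <- proc.time()[3]
  fit <- switch(spec$algorithm,
    decision_tree = {
      df <- data.frame(Xs, volume_uL = y)
      rpart::rpart(
        volume_uL ~ ., data = df, method = "anova",
        control = rpart::rpart.control(
          maxdepth = min(hp$max_depth, 30), cp = 0, xval = 0,
          minsplit = hp$min_samples_split, minbucket = hp$min_samples_leaf
        )
      )
    },
    random_forest = {
      # all features considered at every split (regression-forest convention
      # matching sklearn's max_features = 1.0)
      args <- list(x = as.data.frame(Xs), y = y, ntree = hp$n_estimators,
                   mtry = ncol(Xs),
                   nodesize = max(hp$min_samples_leaf,
                                  ceiling(hp$min_samples_split / 2)))
      if (!is.null(hp$max_depth)) args$maxnodes <- 2^hp$max_depth
      do.call(randomForest::randomForest, args)
    },
    polynomial_regression = poly_fit(Xs, y, hp$degree),
    mlp = mlp_fit(Xs, (y - yc) / ys, hidden = hp$hidden, epochs = hp$epochs,
                  lr = hp$learning_rate, batch = hp$batch_size),
    lstm = lstm_fit(Xs, (y - yc) / ys, units = hp$units, epochs = hp$epochs,
                    lr = hp$learning_rate, batch = hp$batch_size)
  )
  train_time_ms <- (proc.time()[3] - t0) * 1000

  structure(
    list(spec = spec, fit = fit, scaled = scaled,
         x_center = xc, x_scale = xs, y_center = yc, y_scale = ys,
         n_train = nrow(records), train_time_ms = unname(train_time_ms)),
    class = "droplet_model"
  )
}

check_records <- function(records, need_volume = TRUE) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    stop_dropsizer("`records` must be a non-empty data frame.",
                   class = "dropsizer_error_schema")
  }
  need <- c(feature_names(), if (need_volume) "volume_uL")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols)) {
    stop_dropsizer(paste0("`records` is missing column(s): ",
                          paste(missing_cols, collapse = ", ")),
                   class = "dropsizer_error_schema")
  }
  invisible(NULL)
}

#' Predict droplet volumes from a fitted model
#'
#' @param object A [fit_droplet_model()] result.
#' @param newdata Data frame with the five feature columns.
#' @param ... Unused.
#' @return Numeric vector of predicted volumes, uL.
#' @export
predict.droplet_model <- function(object, newdata, ...) {
  check_records(newdata, need_volume = FALSE)
  X <- as.matrix(newdata[feature_names()])
  Xs <- if (object$scaled) {
    sweep(sweep(X, 2, object$x_center), 2, object$x_scale, "/")
  } else X
  alg <- object$spec$algorithm
  switch(alg,
    decision_tree = unname(stats::predict(object$fit, data.frame(Xs))),
    random_forest = unname(stats::predict(object$fit, as.data.frame(Xs))),
    polynomial_regression = poly_predict(object$fit, Xs),
    mlp = mlp_predict(object$fit, Xs) * object$y_scale + object$y_center,
    lstm = lstm_predict(object$fit, Xs) * object$y_scale + object$y_center
  )
}

#' @export
print.droplet_model <- function(x, ...) {
  cat(sprintf("<droplet_model> %s fitted on %d records (train %.0f ms)\n",
              x$spec$algorithm, x$n_train, x$train_time_ms))
  invisible(x)
}

# ---- polynomial regression engine -----------------------------------------
# Full multivariate polynomial feature expansion (all monomials with total
# degree <= `degree` in the five standardized features) followed by ordinary
# least squares. The design grid usually has far fewer distinct parameter
# combinations than monomials; lm.fit's pivoted QR handles the rank
# deficiency and aliased coefficients are treated as zero at prediction.
poly_fit <- function(Xs, y, degree) {
  expo <- poly_exponents(ncol(Xs), degree)
  M <- poly_design(Xs, expo)
  fit <- stats::lm.fit(M, y)
  coef <- fit$coefficients
  coef[is.na(coef)] <- 0
  list(exponents = expo, coefficients = coef, degree = degree)
}

poly_predict <- function(fit, Xs) {
  drop(poly_design(Xs, fit$exponents) %*% fit$coefficients)
}

poly_exponents <- function(p, degree) {
  g <- do.call(expand.grid, rep(list(0:degree), p))
  g <- as.matrix(g[rowSums(g) <= degree, , drop = FALSE])
  g[order(rowSums(g)), , drop = FALSE]
}

poly_design <- function(Xs, expo) {
  n <- nrow(Xs); p <- ncol(Xs)
  maxd <- max(expo)
  pows <- lapply(seq_len(p), function(j) outer(Xs[, j], 0:maxd, `^`))
  M <- matrix(1, n, nrow(expo))
  for (k in seq_len(nrow(expo))) {
    col <- rep(1, n)
    for (j in seq_len(p)) {
      e <- expo[k, j]
      if (e > 0) col <- col * pows[[j]][, e + 1]
    }
    M[, k] <- col
  }
  M
}
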