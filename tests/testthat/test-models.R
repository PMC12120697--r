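test_that("splitting is a seeded 70/30 partition", {
  rec <- generate_records(1758, generator_config(seed = 1))
  sp <- split_dataset(rec, 0.7, seed = 42)
  expect_equal(nrow(sp$train), 1230)
  expect_equal(nrow(sp$test), 528)
  # disjoint and covering
  combined <- dplyr::bind_rows(sp$train, sp$test) |> dplyr::arrange(
    viscosity_mPa_s, nozzle_id_mm, printing_time_s, pressure_psi,
    cell_conc_per_mL, volume_uL)
  expect_equal(combined,
               dplyr::arrange(rec, viscosity_mPa_s, nozzle_id_mm,
                              printing_time_s, pressure_psi,
                              cell_conc_per_mL, volume_uL))

  small <- generate_records(10, generator_config(seed = 2))
  sp10 <- split_dataset(small, 0.7, seed = 1)
  expect_equal(c(nrow(sp10$train), nrow(sp10$test)), c(7, 3))

  expect_identical(split_dataset(rec, seed = 7)$train,
                   split_dataset(rec, seed = 7)$train)
  expect_error(split_dataset(rec, fraction = 1.2),
               class = "dropsizer_error_config")
  expect_error(split_dataset(small[1:5, ]), class = "dropsizer_error_config")
})

test_that("k-fold partitions are exact and averaged metrics check out", {
  rec <- generate_records(100, generator_config(seed = 3))
  cv <- kfold_cv(rec, model_spec("decision_tree", max_depth = 3, seed = 1),
                 k = 10)
  expect_equal(as.integer(table(cv$assignments)), rep(10L, 10))
  expect_equal(sort(unique(cv$assignments)), 1:10)
  expect_equal(nrow(cv$folds), 10)
  # the summary means are the arithmetic fold means
  expect_equal(cv$summary$mean[cv$summary$metric == "val_rmse"],
               mean(cv$folds$val_rmse), tolerance = 1e-12)
  expect_equal(cv$summary$mean[cv$summary$metric == "val_mae"],
               mean(cv$folds$val_mae), tolerance = 1e-12)
  expect_error(kfold_cv(rec, model_spec("decision_tree"), k = 101),
               class = "dropsizer_error_config")
})

test_that("degree-1 polynomial regression interpolates perfectly linear data", {
  rec <- linear_records(60)
  cv <- kfold_cv(rec, model_spec("polynomial_regression", degree = 1, seed = 2),
                 k = 10)
  expect_equal(mean(cv$folds$val_r2), 1, tolerance = 1e-9)

  model <- fit_droplet_model(rec, model_spec("polynomial_regression",
                                             degree = 1, seed = 2))
  expect_equal(predict(model, rec), rec$volume_uL, tolerance = 1e-6)
})

test_that("error metrics match hand-computed values and limits", {
  m <- regression_metrics(c(1, 2, 3), c(1, 2, 4))
  expect_equal(round(m$mae, 4), 0.3333)
  expect_equal(round(m$mse, 4), 0.3333)
  expect_equal(round(m$rmse, 4), 0.5774)
  expect_equal(m$r2, 0.5)

  perfect <- regression_metrics(c(2, 5, 9), c(2, 5, 9))
  expect_equal(unlist(perfect), c(mae = 0, mse = 0, rmse = 0, r2 = 1))

  y <- c(1, 4, 7, 2)
  const <- regression_metrics(y, rep(mean(y), 4))
  expect_equal(const$r2, 0)

  expect_warning(z <- regression_metrics(c(3, 3, 3), c(1, 2, 3)),
                 "zero-variance")
  expect_true(is.nan(z$r2))
})

test_that("rmse^2 equals mse and mae never exceeds rmse", {
  set.seed(99)
  for (i in 1:20) {
    y <- rnorm(50); p <- y + rnorm(50, sd = runif(1, 0.01, 2))
    m <- regression_metrics(y, p)
    expect_equal(m$rmse^2, m$mse, tolerance = 1e-12)
    expect_lte(m$mae, m$rmse + 1e-12)
  }
})

test_that("every engine is deterministic under a fixed seed", {
  rec <- generate_records(200, generator_config(seed = 5))
  probe <- generate_records(40, generator_config(seed = 6))
  for (alg in c("decision_tree", "random_forest", "polynomial_regression",
                "mlp", "lstm")) {
    spec <- model_spec(alg, seed = 11)
    if (alg %in% c("mlp", "lstm")) spec$hyperparameters$epochs <- 10
    p1 <- predict(fit_droplet_model(rec, spec), probe)
    p2 <- predict(fit_droplet_model(rec, spec), probe)
    expect_identical(p1, p2)
  }
})

test_that("decision-tree training error does not exceed validation error", {
  rec <- generate_records(600, generator_config(seed = 8))
  gaps <- vapply(1:10, function(s) {
    cv <- kfold_cv(rec, model_spec("decision_tree", seed = s), k = 5, seed = s)
    mean(cv$folds$val_mae) - mean(cv$folds$train_mae)
  }, numeric(1))
  expect_gt(mean(gaps), 0)
})

test_that("grid search recovers the generating tree depth", {
  set.seed(14)
  n <- 240
  rec <- generate_records(n, generator_config(seed = 14))
  rec$printing_time_s <- runif(n, 0.05, 0.15)
  # an 8-level hierarchical step function of dispensing time: recursive
  # binary splitting reaches every level at depth 3
  level <- findInterval(rec$printing_time_s,
                        seq(0.05, 0.15, length.out = 9)[2:8])
  rec$volume_uL <- c(0, 1, 4, 5, 10, 11, 14, 15)[level + 1] +
    rnorm(n, sd = 0.25)
  gs <- grid_search(rec, "decision_tree", list(max_depth = 1:19), k = 5,
                    seed = 14)
  best_depth <- gs$best_spec$hyperparameters$max_depth
  expect_gte(best_depth, 3)
  expect_lte(best_depth, 5)
  expect_equal(nrow(gs$trace), 19)
  # validation error is essentially flat-or-worse past the true depth
  expect_lt(min(gs$trace$val_rmse[3:5]), gs$trace$val_rmse[1])

  one <- grid_search(rec, "decision_tree", list(max_depth = 4), k = 5)
  expect_equal(one$best_spec$hyperparameters$max_depth, 4)
  expect_error(grid_search(rec, "decision_tree", list()),
               class = "dropsizer_error_config")
})

test_that("polynomial validation error turns non-monotone on noisy cubic data", {
  set.seed(23)
  n <- 60
  rec <- generate_records(n, generator_config(seed = 23))
  rec$printing_time_s <- runif(n, -1, 1)
  rec$volume_uL <- 5 + 2 * rec$printing_time_s - 3 * rec$printing_time_s^2 +
    4 * rec$printing_time_s^3 + rnorm(n, sd = 0.3)
  gs <- grid_search(rec, "polynomial_regression", list(degree = 1:9), k = 10,
                    seed = 23)
  best_degree <- gs$best_spec$hyperparameters$degree
  expect_gte(best_degree, 3)
  expect_gt(gs$trace$val_rmse[9], min(gs$trace$val_rmse))
})
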