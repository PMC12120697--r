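test_that("feature importance is normalized and finds the informative input", {
  rec <- generate_records(400, generator_config(seed = 4))
  imp <- feature_importance(rec, model_spec("random_forest", seed = 4))
  expect_setequal(imp$feature, feature_names())
  expect_true(all(imp$importance >= 0))
  expect_equal(sum(imp$importance), 1, tolerance = 1e-9)

  # response driven by dispensing time alone
  solo <- rec
  solo$volume_uL <- 50 * solo$printing_time_s + rnorm(400, sd = 0.01)
  imp2 <- feature_importance(solo, model_spec("random_forest", seed = 4))
  expect_gte(imp2$importance[imp2$feature == "printing_time_s"], 0.95)

  flat <- rec
  flat$volume_uL <- rep(5, nrow(flat))
  # randomForest itself warns about the degenerate response, then the
  # package warns about the uniform fallback
  expect_warning(expect_warning(imp3 <- feature_importance(flat), "uniform"),
                 "unique values")
  expect_equal(imp3$importance, rep(0.2, 5))
})

test_that("model comparison reports per-algorithm summaries without aborting", {
  rec <- generate_records(260, generator_config(seed = 6))
  specs <- list(model_spec("decision_tree", seed = 1),
                model_spec("polynomial_regression", degree = 2, seed = 1))
  cmp <- compare_algorithms(rec, specs, repeats = 2, seed = 6)
  expect_equal(nrow(cmp$summary), 2)
  expect_equal(cmp$summary$algorithm,
               c("decision_tree", "polynomial_regression"))
  expect_true(all(c("mae_mean", "mae_sd", "rmse_mean", "rmse_sd", "r2_mean",
                    "r2_sd", "train_time_ms", "test_time_ms") %in%
                    names(cmp$summary)))
  expect_equal(nrow(cmp$runs), 4)

  single <- compare_algorithms(rec, specs[1], repeats = 1, seed = 6)
  expect_equal(single$summary$mae_sd, 0)
  expect_equal(single$summary$r2_sd, 0)
})

test_that("shallow trees train faster than the multilayer perceptron", {
  rec <- generate_records(400, generator_config(seed = 9))
  sp <- split_dataset(rec, seed = 9)
  dt <- fit_droplet_model(sp$train, model_spec("decision_tree", seed = 9))
  mlp <- fit_droplet_model(sp$train, model_spec("mlp", seed = 9))
  expect_lt(dt$train_time_ms, mlp$train_time_ms)
})

test_that("tidy and glance methods expose harness results as tibbles", {
  rec <- generate_records(150, generator_config(seed = 10))
  cv <- kfold_cv(rec, model_spec("decision_tree", seed = 1), k = 5)
  expect_s3_class(tidy(cv), "tbl_df")
  expect_equal(nrow(tidy(cv)), 5)
  g <- glance(cv)
  expect_equal(nrow(g), 1)
  expect_equal(g$val_rmse, mean(cv$folds$val_rmse))

  gs <- grid_search(rec, "decision_tree", list(max_depth = c(2, 4)), k = 5)
  expect_equal(nrow(tidy(gs)), 2)
  expect_s3_class(autoplot(gs), "ggplot")

  cmp <- compare_algorithms(rec, list(model_spec("decision_tree")),
                            repeats = 1, seed = 2)
  expect_s3_class(glance(cmp), "tbl_df")
  expect_s3_class(autoplot(cmp), "ggplot")

  model <- fit_droplet_model(rec, model_spec("polynomial_regression",
                                             degree = 2))
  td <- tidy(model)
  expect_true("(Intercept)" %in% td$term)
  expect_equal(glance(model)$n_train, 150)
})
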