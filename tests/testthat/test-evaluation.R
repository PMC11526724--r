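# Grid search, split metrics, and the repeated-split sweep harness.

test_that("hyperparameter grids cover the explored ranges", {
  g <- model_grid("lasso")
  expect_equal(range(g$C), c(10^-1.5, 10^0.4))
  expect_identical(nrow(g), 10L)
  expect_identical(model_grid("knn")$K, 1:11)
  gs <- model_grid("svm")
  expect_setequal(unique(gs$gamma), 10^(-(2:5)))
  expect_equal(range(gs$C), c(10^-0.9, 10^0.9))
  expect_identical(model_grid("dt")$max_depth, 2:8)
})

test_that("ties on separable data go to the most regularized setting", {
  set.seed(1)
  y <- rep(0:1, each = 40)
  X <- cbind(y * 4 + rnorm(80, 0, 0.05), rnorm(80))
  colnames(X) <- c("s", "n")
  cs <- cv_search("lasso", X, y, k = 5, seed = 2)
  expect_equal(cs$cv_auc, 1.0)
  expect_equal(cs$params$C, min(model_grid("lasso")$C))
  cs2 <- cv_search("lasso", X, y, k = 5, seed = 2)
  expect_identical(cs, cs2)  # deterministic given the seed
  k <- cv_search("knn", X, y, k = 5, seed = 2)$params$K
  expect_true(k >= 1 && k <= 11)
})

test_that("too-small classes fail the fold contract with guidance", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(cv_search("lasso", X, c(rep(0, 8), 1, 1), k = 5), "smaller k",
               class = "dermaug_validation_error")
})

test_that("split metrics match hand confusion arithmetic", {
  m <- dermaug:::confusion_metrics(
    y = c(rep(1, 10), rep(0, 20)),
    pred = c(rep(1, 8), rep(0, 2), rep(1, 5), rep(0, 15)))
  expect_equal(m$sensitivity, 0.8)
  expect_equal(m$specificity, 0.75)
  expect_equal(m$accuracy, 23 / 30)
  prec <- 8 / 13
  expect_equal(m$f1, 2 * prec * 0.8 / (prec + 0.8))
})

test_that("perfect and random scores bracket the AUC", {
  y <- rep(0:1, each = 50)
  expect_equal(dermaug:::auc_score(y, y * 2 + 1), 1.0)
  set.seed(3)
  y2 <- rep(0:1, each = 5000)
  expect_lt(abs(dermaug:::auc_score(y2, rnorm(10000)) - 0.5), 0.02)
})

test_that("single-class test sets are rejected", {
  set.seed(1)
  y <- rep(0:1, each = 25)
  X <- matrix(rnorm(100), 50, 2)
  fit <- fit_model("lasso", tibble::tibble(C = 1), X, y)
  expect_error(evaluate_split(fit, X[1:10, ], rep(0, 10)), "both classes",
               class = "dermaug_validation_error")
})

test_that("every model family trains and scores on separable data", {
  set.seed(7)
  y <- rep(0:1, each = 60)
  X <- cbind(a = y * 3 + rnorm(120, 0, 0.3), b = rnorm(120))
  for (model in c("lasso", "knn", "svm", "dt")) {
    cs <- cv_search(model, X, y, k = 3, seed = 5)
    fit <- fit_model(model, cs$params, X, y)
    m <- evaluate_split(fit, X, y)
    expect_gt(m$auc, 0.95)
    expect_true(all(unlist(m[c("sensitivity", "specificity", "accuracy", "f1")]) >= 0 &
                      unlist(m[c("sensitivity", "specificity", "accuracy", "f1")]) <= 1),
                info = model)
  }
})

test_that("the sweep keeps synthetic rows out of the test partition", {
  out <- generate_feature_table(table_spec(120, 30, 10, 4, effect_size = 2, seed = 4))
  ex <- ir_sweep_experiment(out$table, models = "lasso", r_values = c(0.5, 1),
                            repeats = 2, cv_k = 3, seed = 11)
  # test sets are 20% stratified draws of real rows: 24 + 6 per repeat
  expect_true(all(ex$per_repeat$n_train <= 120 + 30 + 120))  # bounded by full augment
  expect_true(all(ex$per_repeat$n_synthetic ==
                    vapply(ex$per_repeat$r, function(r)
                      n_synthetic_for_ratio(24, 96, r), integer(1))))
  # std aggregated over repeats: one summary row per (model, r, metric)
  expect_identical(nrow(ex$summary), 2L * 5L)
  # reproducible end to end
  ex2 <- ir_sweep_experiment(out$table, models = "lasso", r_values = c(0.5, 1),
                             repeats = 2, cv_k = 3, seed = 11)
  expect_identical(ex$per_repeat, ex2$per_repeat)
})

test_that("separable tables reach near-perfect test AUC through the sweep", {
  out <- generate_feature_table(table_spec(160, 40, 20, 8, effect_size = 2, seed = 21))
  ex <- ir_sweep_experiment(out$table, models = "lasso", r_values = 1,
                            repeats = 3, cv_k = 3, seed = 5)
  auc <- dplyr::filter(ex$summary, .data$metric == "auc")
  expect_gte(auc$mean, 0.95)
})

test_that("permuted labels collapse the sweep to chance", {
  out <- generate_feature_table(table_spec(120, 60, 10, 4, effect_size = 2, seed = 31))
  tb <- out$table
  set.seed(99)
  tb$label <- sample(tb$label)
  ex <- ir_sweep_experiment(tb, models = "lasso", r_values = 1,
                            repeats = 3, cv_k = 3, seed = 6)
  auc <- dplyr::filter(ex$summary, .data$metric == "auc")
  expect_lt(abs(auc$mean - 0.5), 0.15)
})

test_that("experiment tidiers expose the summary surface", {
  out <- generate_feature_table(table_spec(80, 40, 6, 3, effect_size = 2, seed = 41))
  ex <- ir_sweep_experiment(out$table, models = "lasso", r_values = 1,
                            repeats = 2, cv_k = 3, seed = 2)
  td <- tidy(ex)
  expect_s3_class(td, "tbl_df")
  expect_setequal(unique(td$metric),
                  c("auc", "sensitivity", "specificity", "accuracy", "f1"))
  gl <- glance(ex)
  expect_identical(gl$best_model, "lasso")
  expect_s3_class(autoplot(ex), "ggplot")
})
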