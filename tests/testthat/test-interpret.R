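# Bootstrap-CI class-difference test, exact Shapley values, and projection
# adapters.

test_that("the bootstrap test detects a real mean shift", {
  set.seed(12)
  tb <- tibble::tibble(label = rep(0:1, each = 100),
                       f = c(rnorm(100), rnorm(100, 2)))
  r <- bootstrap_diff_test(tb, "f", M = 1000, seed = 7)
  expect_true(r$significant)
  expect_lt(abs(r$delta_hat - 2), 0.5)
  expect_true(r$ci_low <= r$delta_hat && r$delta_hat <= r$ci_high)
})

test_that("constant equal features give a degenerate zero interval", {
  tb <- tibble::tibble(label = rep(0:1, each = 20), f = rep(1, 40))
  r <- bootstrap_diff_test(tb, "f", M = 200, seed = 1)
  expect_identical(c(r$ci_low, r$ci_high), c(0, 0))
  expect_false(r$significant)
  expect_error(bootstrap_diff_test(tb[tb$label == 1, ], "f", M = 200),
               class = "dermaug_validation_error")
  expect_error(bootstrap_diff_test(tb, "f", statistic = "proportion", M = 200),
               NA)  # binary feature accepted
  tb$g <- rnorm(40)
  expect_error(bootstrap_diff_test(tb, "g", statistic = "proportion", M = 200),
               "binary", class = "dermaug_validation_error")
})

test_that("the CI covers a true difference at nominal rate", {
  # moderate replicate count; the full 500-replicate calibration runs in the
  # acceptance suite
  delta <- 0.7
  cover <- vapply(1:150, function(s) {
    set.seed(4000 + s)
    tb <- tibble::tibble(label = rep(0:1, each = 100),
                         f = c(rnorm(100), rnorm(100, delta)))
    r <- bootstrap_diff_test(tb, "f", M = 500, seed = s)
    r$ci_low <= delta && delta <= r$ci_high
  }, logical(1))
  expect_gt(mean(cover), 0.89)
})

test_that("feature-wise testing recovers informative features and their sign", {
  recov <- t(vapply(1:10, function(s) {
    out <- generate_feature_table(table_spec(100, 100, 50, 10,
                                             effect_size = 1.5, seed = 700 + s))
    res <- run_all_feature_tests(out$table, M = 500, seed = s)
    inf <- res$feature %in% out$informative
    c(hits = sum(res$significant[inf]),
      fpr = mean(res$significant[!inf]),
      pos = all(res$delta_hat[inf] > 0))
  }, numeric(3)))
  expect_gte(median(recov[, "hits"]), 9)
  expect_lte(median(recov[, "fpr"]), 0.1)
  expect_true(all(recov[, "pos"] == 1))  # melanoma-associated direction
})

test_that("null tables trigger roughly alpha x D significant calls", {
  out <- generate_feature_table(table_spec(100, 100, 40, 0, seed = 77))
  res <- run_all_feature_tests(out$table, M = 500, seed = 3)
  expect_identical(nrow(res), 40L)
  expect_lte(sum(res$significant), stats::qbinom(0.999, 40, 0.05) + 1)
})

test_that("exact shapley recovers the closed form for linear models", {
  w <- c(1.5, -2, 0.25, 4)
  f <- function(X) sum(w * X[1, ])
  inst <- setNames(c(0.5, 1, -2, 0.1), letters[1:4])
  sh <- exact_shapley(f, inst, matrix(0, 10, 4))
  expect_equal(sh$phi, unname(w * inst), tolerance = 1e-9)
  # efficiency
  expect_equal(sum(sh$phi), f(matrix(inst, 1)) - 0, tolerance = 1e-9)
})

test_that("exact shapley satisfies symmetry and dummy on constructed models", {
  # AND model: equal contributions
  f_and <- function(X) X[1, 1] * X[1, 2]
  sh <- exact_shapley(f_and, setNames(c(1, 1), c("a", "b")), matrix(0, 4, 2))
  expect_equal(sh$phi, c(0.5, 0.5), tolerance = 1e-9)
  # dummy: third feature never used
  f_d <- function(X) X[1, 1] * X[1, 2]
  sh3 <- exact_shapley(f_d, setNames(c(1, 1, 7), c("a", "b", "c")),
                       matrix(0, 4, 3))
  expect_equal(sh3$phi[3], 0, tolerance = 1e-12)
  expect_equal(sh3$phi[1], sh3$phi[2], tolerance = 1e-12)
  expect_error(exact_shapley(f_d, rnorm(16), matrix(0, 2, 16)), "adapter",
               class = "dermaug_capability_error")
})

test_that("the sampling estimator tracks exact values for wide models", {
  # D = 16 exceeds the enumeration limit; for a linear model the closed form
  # phi_i = w_i (x_i - baseline_i) is the independent reference
  set.seed(6)
  D <- 16
  w <- rnorm(D)
  f <- function(X) sum(w * X[1, ])
  X <- matrix(rnorm(3 * D), 3, D, dimnames = list(NULL, sprintf("x%02d", 1:D)))
  bg <- matrix(0, 5, D)
  rank_est <- shap_summary_adapter(f, X, bg, n_perm = 32, seed = 2)
  want <- colMeans(abs(X %*% diag(w)))
  names(want) <- colnames(X)
  rho <- cor(rank_est$mean_abs_phi,
             want[rank_est$feature], method = "spearman")
  expect_gte(rho, 0.9)
})

test_that("umap projection has the shape and determinism contract", {
  skip_if_not_installed("uwot")
  set.seed(10)
  X <- matrix(rnorm(60 * 5), 60, 5)
  lab <- rep(0:1, 30)
  src <- rep(c("real", "synthetic"), each = 30)
  u1 <- umap_projection_adapter(X, lab, src, seed = 4)
  u2 <- umap_projection_adapter(X, lab, src, seed = 4)
  expect_identical(nrow(u1), 60L)
  expect_equal(u1$umap_1, u2$umap_1, tolerance = 1e-12)
  expect_setequal(unique(u1$tag),
                  c("not-melanoma real", "melanoma real", "melanoma synthetic"))
})
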