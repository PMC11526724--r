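# Interpretability: bootstrap-CI class-difference test, exact Shapley values
# by subset enumeration, and the UMAP projection adapter.

#' Bootstrap confidence-interval test for a between-class feature difference
#'
#' Resamples each class with replacement (within class, preserving class
#' sizes) `M` times; for each resample computes the difference of the chosen
#' statistic, `delta = mu_melanoma - mu_not_melanoma` (label 1 minus label
#' 0); and forms the percentile `(alpha/2, 1 - alpha/2)` interval of the `M`
#' differences. The difference is declared significant when 0 lies outside
#' the interval.
#'
#' @param table Feature table with a binary `label` column.
#' @param feature Feature column name.
#' @param M Number of bootstrap resamples (default 1000, >= 100).
#' @param alpha Significance level in (0, 0.5) (default 0.05).
#' @param statistic `"mean"` for numeric features, `"proportion"` for binary
#'   ones (the mean of a 0/1 feature).
#' @param seed Integer seed.
#' @return A `dermaug_boottest` tibble row: `feature`, `delta_hat` (observed
#'   difference), `ci_low`, `ci_high`, `significant`.
#' @export
bootstrap_diff_test <- function(table, feature, M = 1000L, alpha = 0.05,
                                statistic = c("mean", "proportion"), seed = 1L) {
  statistic <- match.arg(statistic)
  check_number(M, "M", min = 100, integerish = TRUE)
  if (alpha <= 0 || alpha >= 0.5) stop_invalid("alpha", "must be in (0, 0.5)")
  x <- table[[feature]]
  if (is.null(x)) stop_invalid("feature", sprintf("no column '%s'", feature))
  y <- table$label
  x1 <- x[y == 1]; x0 <- x[y == 0]
  if (!length(x1) || !length(x0)) stop_invalid("table", "both classes must be non-empty")
  if (statistic == "proportion" && !all(x %in% c(0, 1))) {
    stop_invalid("statistic", "proportion requires a binary 0/1 feature")
  }
  deltas <- with_seed(seed, {
    m1 <- colMeans(matrix(x1[sample.int(length(x1), length(x1) * M, replace = TRUE)],
                          length(x1), M))
    m0 <- colMeans(matrix(x0[sample.int(length(x0), length(x0) * M, replace = TRUE)],
                          length(x0), M))
    m1 - m0
  })
  ci <- unname(quantile(deltas, c(alpha / 2, 1 - alpha / 2), type = 7))
  out <- tibble(feature = feature, delta_hat = mean(x1) - mean(x0),
                ci_low = ci[1], ci_high = ci[2],
                significant = ci[1] > 0 | ci[2] < 0)
  class(out) <- c("dermaug_boottest", class(out))
  out
}

#' Bootstrap-CI test for every feature of a table
#'
#' Runs [bootstrap_diff_test()] on each feature column. The sign of
#' `delta_hat` labels the class direction (positive = melanoma-associated).
#' No multiple-testing correction is applied by default; `bonferroni = TRUE`
#' divides alpha by the number of features.
#'
#' @inheritParams bootstrap_diff_test
#' @param bonferroni Apply a Bonferroni-adjusted alpha (default FALSE).
#' @return A `dermaug_boottest` tibble, one row per feature.
#' @export
run_all_feature_tests <- function(table, M = 1000L, alpha = 0.05,
                                  bonferroni = FALSE, seed = 1L) {
  feats <- setdiff(names(table), c("sample_id", "label", "source"))
  a <- if (bonferroni) alpha / length(feats) else alpha
  out <- purrr::map_dfr(seq_along(feats), function(i) {
    bootstrap_diff_test(table, feats[i], M = M, alpha = a, seed = seed + i)
  })
  class(out) <- c("dermaug_boottest", class(out))
  out
}

#' Exact Shapley attributions by subset enumeration
#'
#' For a prediction function `f` and one instance, computes the exact Shapley
#' value of every feature with the combinatorial weights
#' `|S|! (D - |S| - 1)! / D!`, enumerating all `2^D` subsets (`D <= 15`).
#' Features absent from a subset are replaced by the background column means.
#' Satisfies efficiency exactly: the attributions sum to
#' `f(instance) - f(baseline)`.
#'
#' @param predict_fn Function taking a one-row matrix and returning a scalar.
#' @param instance Named numeric vector.
#' @param background Matrix / data frame of background rows (its column means
#'   define the baseline).
#' @return A `dermaug_shapley` tibble: `feature`, `phi`.
#' @export
exact_shapley <- function(predict_fn, instance, background) {
  D <- length(instance)
  if (D > 15) abort("use adapter: exact enumeration limited to D <= 15",
                    class = "dermaug_capability_error")
  background <- as.matrix(background)
  if (!nrow(background)) stop_invalid("background", "must be non-empty")
  baseline <- colMeans(background)
  n_sub <- 2^D
  # f over all masked inputs, one evaluation per subset
  fvals <- numeric(n_sub)
  Xall <- matrix(baseline, n_sub, D, byrow = TRUE)
  inst <- as.numeric(instance)
  member <- matrix(FALSE, n_sub, D)
  for (i in seq_len(D)) {
    member[, i] <- bitwAnd(seq_len(n_sub) - 1L, bitwShiftL(1L, i - 1L)) > 0L
    Xall[member[, i], i] <- inst[i]
  }
  colnames(Xall) <- names(instance)
  for (s in seq_len(n_sub)) fvals[s] <- predict_fn(Xall[s, , drop = FALSE])
  sizes <- rowSums(member)
  wt <- factorial(0:(D - 1)) * factorial(D - 1 - (0:(D - 1))) / factorial(D)
  phi <- numeric(D)
  for (i in seq_len(D)) {
    without <- which(!member[, i])
    with_ <- without + 2^(i - 1)
    phi[i] <- sum(wt[sizes[without] + 1L] * (fvals[with_] - fvals[without]))
  }
  out <- tibble(feature = names(instance) %||% sprintf("x%d", seq_len(D)), phi = phi)
  class(out) <- c("dermaug_shapley", class(out))
  out
}

#' Shapley-based feature importance summary
#'
#' Mean absolute Shapley value per feature over a set of instances. For
#' `D <= 15` the exact enumeration of [exact_shapley()] is used; for larger D
#' a Monte-Carlo permutation estimator (random feature orderings, marginal
#' contributions against the background baseline) approximates the same
#' quantity.
#'
#' @param predict_fn Prediction function (one-row matrix -> scalar).
#' @param X Instances to explain (matrix / data frame).
#' @param background Background data (defaults to `X`).
#' @param n_perm Permutations per instance for the Monte-Carlo path.
#' @param seed Integer seed.
#' @return Tibble `feature`, `mean_abs_phi`, ranked descending.
#' @export
shap_summary_adapter <- function(predict_fn, X, background = X, n_perm = 64L,
                                 seed = 1L) {
  X <- as.matrix(X)
  D <- ncol(X)
  nm <- colnames(X) %||% sprintf("x%d", seq_len(D))
  baseline <- colMeans(as.matrix(background))
  phis <- matrix(0, nrow(X), D)
  if (D <= 15) {
    for (r in seq_len(nrow(X))) {
      phis[r, ] <- exact_shapley(predict_fn, setNames(X[r, ], nm), background)$phi
    }
  } else {
    with_seed(seed, {
      for (r in seq_len(nrow(X))) {
        acc <- numeric(D)
        for (p in seq_len(n_perm)) {
          ord <- sample.int(D)
          cur <- baseline
          f_prev <- predict_fn(matrix(cur, 1, dimnames = list(NULL, nm)))
          for (i in ord) {
            cur[i] <- X[r, i]
            f_new <- predict_fn(matrix(cur, 1, dimnames = list(NULL, nm)))
            acc[i] <- acc[i] + (f_new - f_prev)
            f_prev <- f_new
          }
        }
        phis[r, ] <- acc / n_perm
      }
    })
  }
  out <- tibble(feature = nm, mean_abs_phi = colMeans(abs(phis)))
  dplyr::arrange(out, dplyr::desc(.data$mean_abs_phi))
}

#' UMAP projection of a feature table (adapter)
#'
#' Projects rows to 2-D with UMAP (via the `uwot` package), tagging each
#' point by class and source so real and synthetic minority samples can be
#' compared visually.
#'
#' @param X Feature matrix.
#' @param labels Binary class labels.
#' @param source Optional `"real"`/`"synthetic"` flags.
#' @param seed Integer seed (projection is deterministic given the seed).
#' @param n_neighbors UMAP neighbourhood size.
#' @return Tibble `umap_1`, `umap_2`, `label`, `source`, `tag`.
#' @export
umap_projection_adapter <- function(X, labels, source = NULL, seed = 1L,
                                    n_neighbors = 15L) {
  if (!requireNamespace("uwot", quietly = TRUE)) {
    stop_capability("umap", "the uwot package is not installed")
  }
  X <- as.matrix(X)
  source <- source %||% rep("real", nrow(X))
  n_neighbors <- min(n_neighbors, nrow(X) - 1L)
  coords <- with_seed(seed, uwot::umap(X, n_neighbors = n_neighbors,
                                       n_threads = 1, n_sgd_threads = 1))
  tibble(umap_1 = coords[, 1], umap_2 = coords[, 2],
         label = as.integer(labels), source = source,
         tag = dplyr::case_when(
           labels == 1 & source == "synthetic" ~ "melanoma synthetic",
           labels == 1 ~ "melanoma real",
           TRUE ~ "not-melanoma real"))
}
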