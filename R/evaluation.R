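# Repeated-split evaluation harness: stratified cross-validated grid search
# (AUCROC figure of merit), classifier fitting behind a common score
# interface, and the imbalance-ratio sweep experiment.

#' Hyperparameter grid for one model family
#'
#' Grids follow the explored ranges: LASSO (L1-penalised logistic
#' classifier) C in `[10^-1.5, 10^0.4]`; KNN K in 1..11; RBF-SVM gamma in
#' `{1e-2, 1e-3, 1e-4, 1e-5}` with C in `[10^-0.9, 10^0.9]`; decision tree
#' max depth in 2..8. Continuous ranges are discretized to 10 log-spaced
#' points. Rows are ordered from least to most complex, which is also the
#' tie-break order of [cv_search()].
#'
#' @param model One of `"lasso"`, `"knn"`, `"svm"`, `"dt"`.
#' @return Tibble of grid points.
#' @export
model_grid <- function(model = c("lasso", "knn", "svm", "dt")) {
  model <- match.arg(model)
  switch(model,
    lasso = tibble(C = 10^seq(-1.5, 0.4, length.out = 10)),
    knn = tibble(K = 1:11),
    svm = tidyr::expand_grid(C = 10^seq(-0.9, 0.9, length.out = 10),
                             gamma = 10^(-(5:2)))[, c("C", "gamma")],
    dt = tibble(max_depth = 2:8)
  )
}

#' Fit one classifier at fixed hyperparameters
#'
#' Features are expected pre-scaled (the sweep harness z-scores with training
#' statistics). Returns a fitted object with a common `score` interface:
#' continuous scores increasing with the probability of the minority class
#' (class probabilities for lasso/knn/dt, decision values for svm).
#'
#' @param model Model id.
#' @param params One row of [model_grid()].
#' @param X Numeric matrix.
#' @param y Binary labels 0/1.
#' @return A `dermaug_fit` object.
#' @export
fit_model <- function(model, params, X, y) {
  X <- as.matrix(X)
  y <- as.integer(y)
  n <- nrow(X)
  fit <- switch(model,
    lasso = {
      # C is an inverse regularization strength; lambda = 1 / (n C).
      # glmnet warns about small per-class counts on the tiny CV folds the
      # harness intentionally uses; that advisory is muffled.
      withCallingHandlers(
        glmnet::glmnet(X, y, family = "binomial", alpha = 1,
                       lambda = 1 / (n * params$C), standardize = FALSE),
        warning = function(w) {
          if (grepl("fewer than 8\\s+observations", conditionMessage(w))) {
            invokeRestart("muffleWarning")
          }
        })
    },
    knn = list(X = X, y = y, K = params$K),
    svm = e1071::svm(X, factor(y, levels = c(0, 1)), kernel = "radial",
                     gamma = params$gamma, cost = params$C, scale = FALSE),
    dt = {
      df <- data.frame(y = factor(y, levels = c(0, 1)), X)
      rpart::rpart(y ~ ., data = df, method = "class",
                   control = rpart::rpart.control(
                     maxdepth = params$max_depth,
                     minsplit = max(2L, round(0.05 * n)), cp = 0))
    },
    stop_invalid("model", sprintf("unknown model '%s'", model)))
  structure(list(model = model, params = params, fit = fit,
                 score_type = if (model == "svm") "decision" else "prob"),
            class = "dermaug_fit")
}

#' Continuous minority-class scores of a fitted model
#' @param object A `dermaug_fit`.
#' @param X_test Feature matrix.
#' @param ... Unused.
#' @return Numeric score vector (higher = more melanoma-like).
#' @export
predict_scores <- function(object, X_test, ...) {
  X_test <- as.matrix(X_test)
  switch(object$model,
    lasso = as.numeric(predict(object$fit, X_test, type = "response")),
    knn = {
      pr <- class::knn(object$fit$X, X_test, factor(object$fit$y, levels = c(0, 1)),
                       k = object$fit$K, prob = TRUE)
      p <- attr(pr, "prob")
      ifelse(pr == "1", p, 1 - p)
    },
    svm = {
      dv <- attr(predict(object$fit, X_test, decision.values = TRUE),
                 "decision.values")
      # e1071 orients decision values toward the first factor level ("0")
      -as.numeric(dv)
    },
    dt = {
      df <- as.data.frame(X_test)
      names(df) <- colnames(object$fit$model)[-1] %||% names(df)
      predict(object$fit, df, type = "prob")[, "1"]
    })
}

auc_score <- function(y, scores) {
  as.numeric(pROC::auc(pROC::roc(response = y, predictor = scores,
                                 levels = c("0", "1"), direction = "<",
                                 quiet = TRUE)))
}

stratified_folds <- function(y, k, seed) {
  with_seed(seed, {
    fold <- integer(length(y))
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

#' Stratified k-fold grid search maximising validation AUCROC
#'
#' Evaluates every grid point with stratified `k`-fold cross-validation and
#' returns the one with the highest mean validation AUCROC; ties go to the
#' less complex setting (more regularization, smaller K, smaller depth).
#'
#' @param model Model id.
#' @param X,y Training data.
#' @param k Folds (default 5). Each class must have at least `k` samples.
#' @param grid Optional grid tibble (default [model_grid()]).
#' @param seed Integer seed for fold assignment.
#' @return List with `params` (best row) and `cv_auc` (its mean AUC).
#' @export
cv_search <- function(model, X, y, k = 5L, grid = NULL, seed = 1L) {
  X <- as.matrix(X); y <- as.integer(y)
  if (min(table(y)) < k) {
    abort(sprintf("class with fewer than k = %d samples; use a smaller k", k),
          class = "dermaug_validation_error")
  }
  grid <- grid %||% model_grid(model)
  fold <- stratified_folds(y, k, seed)
  mean_auc <- vapply(seq_len(nrow(grid)), function(g) {
    aucs <- vapply(seq_len(k), function(f) {
      tr <- fold != f
      fit <- fit_model(model, grid[g, ], X[tr, , drop = FALSE], y[tr])
      auc_score(y[!tr], predict_scores(fit, X[!tr, , drop = FALSE]))
    }, numeric(1))
    mean(aucs)
  }, numeric(1))
  best <- which.max(mean_auc)  # ties: first = least complex by grid order
  list(params = grid[best, ], cv_auc = mean_auc[best])
}

#' Classification metrics of a fitted model on a held-out split
#'
#' AUCROC from the continuous scores; sensitivity (recall of the melanoma
#' class, label 1), specificity, accuracy and F1 at the 0.5 probability
#' threshold (0 for decision-value scores).
#'
#' @param fit A `dermaug_fit`.
#' @param X_test,y_test Held-out data containing both classes.
#' @return Tibble row with `auc`, `sensitivity`, `specificity`, `accuracy`, `f1`.
#' @export
evaluate_split <- function(fit, X_test, y_test) {
  y_test <- as.integer(y_test)
  if (length(unique(y_test)) < 2) {
    abort("test set must contain both classes", class = "dermaug_validation_error")
  }
  scores <- predict_scores(fit, X_test)
  thr <- if (fit$score_type == "decision") 0 else 0.5
  pred <- as.integer(scores > thr)
  confusion_metrics(y_test, pred, auc = auc_score(y_test, scores))
}

confusion_metrics <- function(y, pred, auc = NA_real_) {
  tp <- sum(y == 1 & pred == 1); fn <- sum(y == 1 & pred == 0)
  tn <- sum(y == 0 & pred == 0); fp <- sum(y == 0 & pred == 1)
  sens <- if (tp + fn > 0) tp / (tp + fn) else 0
  spec <- if (tn + fp > 0) tn / (tn + fp) else 0
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  f1 <- if (prec + sens > 0) 2 * prec * sens / (prec + sens) else 0
  tibble(auc = auc, sensitivity = sens, specificity = spec,
         accuracy = (tp + tn) / length(y), f1 = f1)
}

#' Imbalance-ratio sweep experiment
#'
#' The full experimental harness: for each repeat, a stratified 80/20
#' train/test split is drawn; features are z-scored with training statistics;
#' ensemble feature selection is fitted on the training rows only; the
#' training minority class is oversampled to each target balance ratio; the
#' model grid is searched by stratified 5-fold CV on the augmented training
#' set; and the tuned model is evaluated on the untouched (all-real) test
#' rows. Metrics are aggregated as mean and sd over repeats.
#'
#' @param table Feature table (tibble with `label` and feature columns).
#' @param models Character vector of model ids.
#' @param method Oversampler (`"smote"` in this build).
#' @param r_values Target balance ratios (default `seq(0.5, 1, by = 0.1)`).
#' @param repeats Number of repeated splits (default 5).
#' @param cv_k CV folds in the grid search.
#' @param fs List of ensemble-FS settings (`M`, `top_t`, `k_final`,
#'   `k_neighbors`) or NULL to skip feature selection.
#' @param seed Master seed; every repeat derives its own seeds from it.
#' @return A `dermaug_experiment` object; its `summary` tibble has one row
#'   per (model, r) with mean/sd of each metric, `per_repeat` the raw rows.
#' @export
ir_sweep_experiment <- function(table, models = "lasso", method = "smote",
                                r_values = seq(0.5, 1, by = 0.1), repeats = 5L,
                                cv_k = 5L, fs = NULL, seed = 1L) {
  xy <- table_xy(table)
  rows <- list()
  for (rep_i in seq_len(repeats)) {
    rep_seed <- seed + 1000L * rep_i
    idx_test <- with_seed(rep_seed, {
      unlist(lapply(unique(xy$y), function(cls) {
        cand <- which(xy$y == cls)
        sample(cand, max(1L, round(0.2 * length(cand))))
      }))
    })
    tr <- setdiff(seq_len(nrow(xy$X)), idx_test)
    X_tr <- xy$X[tr, , drop = FALSE]; y_tr <- xy$y[tr]
    X_te <- xy$X[idx_test, , drop = FALSE]; y_te <- xy$y[idx_test]
    mu <- colMeans(X_tr)
    sg <- apply(X_tr, 2, sd); sg[sg == 0] <- 1
    X_tr <- sweep(sweep(X_tr, 2, mu), 2, sg, "/")
    X_te <- sweep(sweep(X_te, 2, mu), 2, sg, "/")
    sel <- colnames(X_tr)
    if (!is.null(fs)) {
      es <- ensemble_select(X_tr, y_tr,
                            M = fs$M %||% 100L, top_t = fs$top_t,
                            k_final = fs$k_final %||% 35L,
                            k_neighbors = fs$k_neighbors %||% 10L,
                            seed = rep_seed + 1L)
      sel <- es$selected
    }
    train_tbl <- dplyr::bind_cols(tibble(label = y_tr, source = "real"),
                                  as_tibble(as.data.frame(X_tr[, sel, drop = FALSE])))
    for (r in r_values) {
      aug <- augment_to_ratio(train_tbl, method = method, r = r,
                              seed = rep_seed + round(1e4 * r))
      axy <- table_xy(aug)
      for (model in models) {
        cs <- cv_search(model, axy$X, axy$y, k = cv_k, seed = rep_seed + 7L)
        fit <- fit_model(model, cs$params, axy$X, axy$y)
        met <- evaluate_split(fit, X_te[, sel, drop = FALSE], y_te)
        rows[[length(rows) + 1L]] <- dplyr::bind_cols(
          tibble(repeat_ = rep_i, model = model, method = method, r = r,
                 cv_auc = cs$cv_auc, n_train = nrow(axy$X),
                 n_synthetic = sum(aug$source == "synthetic")), met)
      }
    }
  }
  per_repeat <- dplyr::bind_rows(rows)
  summary <- per_repeat |>
    tidyr::pivot_longer(dplyr::all_of(c("auc", "sensitivity", "specificity",
                                        "accuracy", "f1")),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$model, .data$method, .data$r, .data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                     .groups = "drop")
  structure(list(summary = summary, per_repeat = per_repeat,
                 r_values = r_values, models = models, seed = seed),
            class = "dermaug_experiment")
}

#' @export
print.dermaug_experiment <- function(x, ...) {
  cat(sprintf("Imbalance-ratio sweep: %d model(s) x %d ratio(s), %d repeats\n",
              length(x$models), length(x$r_values),
              max(x$per_repeat$repeat_)))
  print(tidyr::pivot_wider(
    dplyr::filter(x$summary, .data$metric == "auc"),
    names_from = "r", values_from = c("mean", "sd")))
  invisible(x)
}
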