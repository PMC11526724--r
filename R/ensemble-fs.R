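#' ReliefF feature weights
#'
#' ReliefF for binary classes: features are min-max scaled to `[0, 1]`, every
#' instance is used as an anchor, and for each anchor the mean per-feature
#' difference to its `k` nearest hits (same class) is subtracted while the
#' mean difference to its `k` nearest misses (other class) is added; weights
#' are normalised by the number of anchors. Nearest neighbours use Manhattan
#' distance on the scaled features. A constant feature contributes exactly 0.
#'
#' @param X Numeric matrix or data frame (n x D).
#' @param y Binary labels (0/1), length n, both classes present.
#' @param k_neighbors Number of hits/misses per anchor (default 10; capped at
#'   class size - 1).
#' @param seed Integer seed (ties in neighbour order are resolved
#'   deterministically; the seed keeps the contract explicit).
#' @return Named numeric weight vector of length D.
#' @export
relief_weights <- function(X, y, k_neighbors = 10L, seed = 1L) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop_invalid("y", "must contain both classes")
  n <- nrow(X); D <- ncol(X)
  if (n < 2) stop_invalid("X", "needs at least 2 rows")
  rng <- apply(X, 2, range)
  span <- rng[2, ] - rng[1, ]
  span[span == 0] <- 1   # constant features scale to 0 everywhere
  Xs <- sweep(sweep(X, 2, rng[1, ]), 2, span, "/")
  dm <- as.matrix(stats::dist(Xs, method = "manhattan"))
  W <- numeric(D)
  for (a in seq_len(n)) {
    same <- which(y == y[a]); same <- same[same != a]
    other <- which(y != y[a])
    kh <- min(k_neighbors, length(same))
    km <- min(k_neighbors, length(other))
    if (kh < 1 || km < 1) next
    hits <- same[order(dm[a, same])][seq_len(kh)]
    misses <- other[order(dm[a, other])][seq_len(km)]
    diff_hit <- colMeans(abs(Xs[hits, , drop = FALSE] -
                               matrix(Xs[a, ], kh, D, byrow = TRUE)))
    diff_miss <- colMeans(abs(Xs[misses, , drop = FALSE] -
                                matrix(Xs[a, ], km, D, byrow = TRUE)))
    W <- W + diff_miss - diff_hit
  }
  W <- W / n
  names(W) <- colnames(X)
  W
}

#' Bootstrap index subsets
#'
#' Draws `M` multisets of `n_boot` indices i.i.d. uniformly with replacement
#' from `1..n`; reproducible from the seed.
#'
#' @param n Population size (>= 2).
#' @param M Number of subsets.
#' @param n_boot Subset size (default `n`).
#' @param seed Integer seed.
#' @return List of `M` integer vectors.
#' @export
bootstrap_subsets <- function(n, M = 100L, n_boot = n, seed = 1L) {
  check_number(n, "n", min = 2, integerish = TRUE)
  check_number(M, "M", min = 1, integerish = TRUE)
  check_number(n_boot, "n_boot", min = 2, integerish = TRUE)
  with_seed(seed, lapply(seq_len(M), function(j) sample.int(n, n_boot, replace = TRUE)))
}

#' Vote-based rank aggregation of an importance matrix
#'
#' Each of the M base learners votes for its `top_t` features by weight;
#' features are ranked by descending vote count, ties broken by ascending
#' mean rank across learners, then lexicographic name.
#'
#' @param importance M x D numeric matrix of per-bootstrap feature weights,
#'   with feature column names.
#' @param top_t Number of votes per learner (`1 <= top_t <= D`).
#' @return A `dermaug_ranking` tibble with columns `feature`, `votes`,
#'   `mean_rank`, `rank`.
#' @export
aggregate_votes <- function(importance, top_t) {
  importance <- as.matrix(importance)
  D <- ncol(importance)
  check_number(top_t, "top_t", min = 1, max = D, integerish = TRUE)
  nm <- colnames(importance) %||% sprintf("f%03d", seq_len(D))
  # per-row dense ranks: 1 = largest weight; ties by column order (stable)
  ranks <- t(apply(importance, 1, function(v) rank(-v, ties.method = "first")))
  votes <- colSums(ranks <= top_t)
  mean_rank <- colMeans(ranks)
  ord <- order(-votes, mean_rank, nm)
  out <- tibble(feature = nm[ord], votes = as.integer(votes[ord]),
                mean_rank = mean_rank[ord], rank = seq_len(D))
  class(out) <- c("dermaug_ranking", class(out))
  out
}

#' Homogeneous ensemble feature selection with ReliefF and voting
#'
#' Runs [relief_weights()] on `M` bootstrap subsets of the training data
#' (stratified by class by default, preserving class counts), aggregates the
#' M importance vectors by [aggregate_votes()], and returns the top `k_final`
#' feature names with the full ranking.
#'
#' @param X Feature matrix / data frame.
#' @param y Binary labels.
#' @param M Number of bootstrap subsets (default 100).
#' @param top_t Votes per learner (default `ceiling(0.25 * D)`).
#' @param k_final Number of features to select (default 35, the catalogue
#'   configuration; capped at D).
#' @param k_neighbors ReliefF neighbours.
#' @param stratified Resample within class (default TRUE).
#' @param seed Integer seed.
#' @return List with `selected` (character) and `ranking` (`dermaug_ranking`).
#' @export
ensemble_select <- function(X, y, M = 100L, top_t = NULL, k_final = 35L,
                            k_neighbors = 10L, stratified = TRUE, seed = 1L) {
  X <- as.matrix(X)
  D <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("f%03d", seq_len(D))
  top_t <- top_t %||% ceiling(0.25 * D)
  k_final <- min(k_final, D)
  y <- as.integer(y)
  n <- nrow(X)
  subsets <- if (stratified) {
    idx0 <- which(y == 0L); idx1 <- which(y == 1L)
    with_seed(seed, lapply(seq_len(M), function(j) {
      c(idx0[sample.int(length(idx0), length(idx0), replace = TRUE)],
        idx1[sample.int(length(idx1), length(idx1), replace = TRUE)])
    }))
  } else {
    bootstrap_subsets(n, M = M, n_boot = n, seed = seed)
  }
  imp <- matrix(0, M, D, dimnames = list(NULL, colnames(X)))
  for (j in seq_len(M)) {
    idx <- subsets[[j]]
    imp[j, ] <- relief_weights(X[idx, , drop = FALSE], y[idx],
                               k_neighbors = k_neighbors, seed = seed + j)
  }
  ranking <- aggregate_votes(imp, top_t)
  list(selected = ranking$feature[seq_len(k_final)], ranking = ranking,
       importance = imp)
}
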