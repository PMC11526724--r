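# ReliefF weighting, bootstrap subsets and vote aggregation, checked against
# hand computations and standard sampling theory.

test_that("relief weights equal a literal hit/miss hand computation", {
  # 6-sample, 2-feature dataset; k = 1 so each anchor has a unique nearest
  # hit and miss that can be enumerated by hand
  X <- matrix(c(0.0, 0.1, 0.2, 0.8, 0.9, 1.0,
                0.0, 1.0, 0.0, 1.0, 0.0, 1.0), ncol = 2)
  colnames(X) <- c("signal", "noise")
  y <- c(0, 0, 0, 1, 1, 1)
  got <- relief_weights(X, y, k_neighbors = 1)
  # naive oracle: scale, manhattan distances, per-anchor nearest hit/miss
  rngs <- apply(X, 2, range)
  Xs <- sweep(sweep(X, 2, rngs[1, ]), 2, rngs[2, ] - rngs[1, ], "/")
  W <- c(0, 0)
  for (a in 1:6) {
    d <- rowSums(abs(sweep(Xs, 2, Xs[a, ])))
    hits <- which(y == y[a]); hits <- hits[hits != a]
    misses <- which(y != y[a])
    h <- hits[which.min(d[hits])]
    m <- misses[which.min(d[misses])]
    W <- W + abs(Xs[a, ] - Xs[m, ]) - abs(Xs[a, ] - Xs[h, ])
  }
  expect_equal(unname(got), unname(W / 6), tolerance = 1e-9)
})

test_that("a label-copy feature always outweighs independent noise", {
  wins <- vapply(1:50, function(s) {
    set.seed(s)
    y <- rep(0:1, each = 100)
    X <- cbind(copy = y + rnorm(200, 0, 0.05), noise = rnorm(200))
    w <- relief_weights(X, y, seed = s)
    w[["copy"]] > w[["noise"]]
  }, logical(1))
  expect_true(all(wins))
})

test_that("constant features contribute exactly zero weight", {
  set.seed(1)
  X <- cbind(a = rnorm(40), const = rep(2, 40))
  w <- relief_weights(X, rep(0:1, 20))
  expect_identical(w[["const"]], 0)
  expect_error(relief_weights(X, rep(0, 40)), "class",
               class = "dermaug_validation_error")
})

test_that("bootstrap subsets reproduce and cover ~1 - 1/e unique indices", {
  a <- bootstrap_subsets(50, M = 3, seed = 7)
  b <- bootstrap_subsets(50, M = 3, seed = 7)
  expect_identical(a, b)
  expect_length(bootstrap_subsets(10, M = 1, seed = 1), 1)
  cover <- vapply(bootstrap_subsets(1000, M = 100, seed = 11),
                  function(idx) length(unique(idx)) / 1000, numeric(1))
  expect_lt(abs(mean(cover) - (1 - exp(-1))), 0.02)
})

test_that("vote aggregation matches a hand count and conserves votes", {
  imp <- rbind(c(a = 0.9, b = 0.5, c = 0.1, d = 0.0),
               c(a = 0.2, b = 0.8, c = 0.7, d = 0.1),
               c(a = 0.6, b = 0.1, c = 0.9, d = 0.8))
  r <- aggregate_votes(imp, top_t = 2)
  # hand count: row1 votes a,b; row2 votes b,c; row3 votes c,d
  votes <- setNames(r$votes, r$feature)
  expect_identical(votes[c("a", "b", "c", "d")], c(a = 1L, b = 2L, c = 2L, d = 1L))
  expect_identical(sum(r$votes), 3L * 2L)
  # ties: c beats b on mean rank (2.33 vs 2.67)? compute: b ranks 2,1,4; c 3,2,1
  expect_identical(r$feature[1:2], c("c", "b"))
})

test_that("unanimous rows reproduce the single-row ranking", {
  w <- c(a = 0.3, b = 0.9, c = 0.5)
  imp <- rbind(w, w, w)
  r <- aggregate_votes(imp, top_t = 1)
  expect_identical(r$feature[1], "b")
  expect_identical(r$feature, names(sort(w, decreasing = TRUE)))
})

test_that("top_t = D forces a tie resolved by mean rank", {
  imp <- rbind(c(a = 1, b = 2, c = 3), c(a = 3, b = 2, c = 1),
               c(a = 1, b = 3, c = 2))
  r <- aggregate_votes(imp, top_t = 3)
  expect_true(all(r$votes == 3L))
  expect_identical(r$feature[1], "b")  # best mean rank
})

test_that("a single identity-resample learner equals plain relief ranking", {
  set.seed(3)
  out <- generate_feature_table(table_spec(60, 30, 8, 3, effect_size = 1.5, seed = 3))
  xy <- dermaug:::table_xy(out$table)
  w <- relief_weights(xy$X, xy$y, seed = 5)
  r <- aggregate_votes(matrix(w, 1, dimnames = list(NULL, names(w))),
                       top_t = length(w))
  expect_identical(r$feature, names(sort(-rank(-w, ties.method = "first"),
                                         decreasing = TRUE)))
  expect_identical(r$feature, names(w)[order(-w)])
})

test_that("column permutation permutes the selection identically", {
  out <- generate_feature_table(table_spec(80, 40, 10, 3, effect_size = 1.2, seed = 9))
  xy <- dermaug:::table_xy(out$table)
  perm <- c(7, 2, 9, 1, 5, 10, 3, 8, 6, 4)
  s1 <- ensemble_select(xy$X, xy$y, M = 10, k_final = 5, seed = 4)
  s2 <- ensemble_select(xy$X[, perm], xy$y, M = 10, k_final = 5, seed = 4)
  expect_identical(s1$ranking$feature, s2$ranking$feature)
  expect_identical(s1$selected, s2$selected)
})

test_that("ensemble recovers planted informative features", {
  recov <- vapply(1:5, function(s) {
    out <- generate_feature_table(table_spec(300, 100, 50, 10,
                                             effect_size = 1.5, seed = 100 + s))
    xy <- dermaug:::table_xy(out$table)
    sel <- ensemble_select(xy$X, xy$y, M = 50, k_final = 10, seed = s)
    length(intersect(sel$selected, out$informative))
  }, numeric(1))
  expect_gte(median(recov), 8)
})

test_that("ensemble selection is more stable than a single relief run", {
  jac <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  res <- vapply(1:10, function(s) {
    out <- generate_feature_table(table_spec(200, 100, 30, 8,
                                             effect_size = 1.2, seed = 600 + s))
    xy <- dermaug:::table_xy(out$table)
    set.seed(s)
    split_ <- sample(nrow(xy$X)) %% 2 == 0
    top <- function(w, k) names(sort(w, decreasing = TRUE))[seq_len(k)]
    e1 <- ensemble_select(xy$X[split_, ], xy$y[split_], M = 25, k_final = 8, seed = s)
    e2 <- ensemble_select(xy$X[!split_, ], xy$y[!split_], M = 25, k_final = 8, seed = s + 1)
    r1 <- top(relief_weights(xy$X[split_, ], xy$y[split_]), 8)
    r2 <- top(relief_weights(xy$X[!split_, ], xy$y[!split_]), 8)
    jac(e1$selected, e2$selected) - jac(r1, r2)
  }, numeric(1))
  expect_gte(median(res), 0)
})
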