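# Real-vs-synthetic fidelity metrics: Hellinger distance (HD), pairwise
# correlation difference (PCD), summed absolute PMF error (MAEP) and the
# repeated-sample-vector rate (RSVR).

#' Shared-bin probability mass functions for a real/synthetic column pair
#'
#' Continuous columns are discretized into `n_bins` equal-width bins over the
#' pooled min--max of both columns (zero-count bins allowed); factor /
#' character columns use the union of their categories.
#'
#' @param real_col,syn_col Non-empty vectors.
#' @param n_bins Number of bins for continuous columns (default 20).
#' @return List with probability vectors `P` (real) and `Q` (synthetic).
#' @export
discretize_pair <- function(real_col, syn_col, n_bins = 20L) {
  if (!length(real_col) || !length(syn_col)) {
    stop_invalid("columns", "must be non-empty")
  }
  if (is.numeric(real_col) && is.numeric(syn_col)) {
    if (any(!is.finite(real_col)) || any(!is.finite(syn_col))) {
      stop_invalid("columns", "must be finite")
    }
    pooled <- range(c(real_col, syn_col))
    if (diff(pooled) < .Machine$double.eps) {
      return(list(P = 1, Q = 1))
    }
    brk <- seq(pooled[1], pooled[2], length.out = n_bins + 1L)
    cut_ <- function(v) tabulate(pmin(pmax(findInterval(v, brk, rightmost.closed = TRUE), 1L),
                                      n_bins), nbins = n_bins)
    P <- cut_(real_col); Q <- cut_(syn_col)
  } else {
    lev <- sort(unique(c(as.character(real_col), as.character(syn_col))))
    P <- table(factor(as.character(real_col), levels = lev))
    Q <- table(factor(as.character(syn_col), levels = lev))
  }
  list(P = as.numeric(P) / sum(P), Q = as.numeric(Q) / sum(Q))
}

#' Hellinger distance between two PMFs
#'
#' \eqn{HD(P, Q) = \frac{1}{\sqrt 2}\sqrt{\sum_j (\sqrt{P_j} - \sqrt{Q_j})^2}},
#' in `[0, 1]`: 0 for identical distributions, 1 for disjoint supports.
#'
#' @param pair A list with probability vectors `P` and `Q` of equal length
#'   (e.g. from [discretize_pair()]).
#' @return Numeric scalar in `[0, 1]`.
#' @export
hellinger <- function(pair) {
  check_pmf_pair(pair)
  sqrt(sum((sqrt(pair$P) - sqrt(pair$Q))^2)) / sqrt(2)
}

#' Summed absolute PMF error between two PMFs
#'
#' \eqn{\sum_j |P_j - Q_j|}, in `[0, 2]` (0 identical, 2 disjoint supports).
#' Despite the "mean" in its conventional name this quantity is a sum; set
#' `mean = TRUE` to divide by the number of bins.
#'
#' @inheritParams hellinger
#' @param mean Divide by the number of bins (default FALSE).
#' @return Numeric scalar.
#' @export
maep <- function(pair, mean = FALSE) {
  check_pmf_pair(pair)
  v <- sum(abs(pair$P - pair$Q))
  if (mean) v / length(pair$P) else v
}

check_pmf_pair <- function(pair) {
  if (!is.list(pair) || is.null(pair$P) || is.null(pair$Q) ||
      length(pair$P) != length(pair$Q) || any(pair$P < 0) || any(pair$Q < 0) ||
      abs(sum(pair$P) - 1) > 1e-9 || abs(sum(pair$Q) - 1) > 1e-9) {
    stop_invalid("pair", "P and Q must be equal-length probability vectors")
  }
  invisible(pair)
}

#' Pairwise correlation difference between real and synthetic data
#'
#' Frobenius norm of the difference between the Pearson correlation matrices
#' of the real and synthetic feature matrices. Constant columns get
#' correlation 0 with everything (diagonal 1) by convention.
#'
#' @param X_real,X_syn Matrices with the same >= 2 features and >= 3 rows each.
#' @return Non-negative scalar; 0 when the correlation structures agree.
#' @export
pcd <- function(X_real, X_syn) {
  X_real <- as.matrix(X_real); X_syn <- as.matrix(X_syn)
  if (ncol(X_real) < 2 || ncol(X_syn) != ncol(X_real)) {
    stop_invalid("X_real", "needs >= 2 matched features on both sides")
  }
  if (nrow(X_real) < 3 || nrow(X_syn) < 3) stop_invalid("X_real", "needs >= 3 rows each side")
  safe_cor <- function(X) {
    C <- suppressWarnings(stats::cor(X))
    C[!is.finite(C)] <- 0
    diag(C) <- 1
    C
  }
  norm(safe_cor(X_real) - safe_cor(X_syn), type = "F")
}

#' Repeated-sample-vector rate of a synthetic dataset
#'
#' Fraction of synthetic rows that are exactly equal (no rounding) to an
#' earlier synthetic row; duplicates are counted within the synthetic set
#' only. An empty set or all-unique set scores 0; `n` identical rows score
#' `(n - 1) / n`.
#'
#' @param X_syn Matrix or data frame of synthetic rows (may be empty).
#' @return Fraction in `[0, 1]`.
#' @export
rsvr <- function(X_syn) {
  X_syn <- as.data.frame(X_syn)
  if (!nrow(X_syn)) return(0)
  mean(duplicated(X_syn))
}

#' Synthetic-data quality report
#'
#' Per-feature Hellinger distance and summed absolute PMF error, their means,
#' the global pairwise correlation difference and the repeated-vector rate.
#'
#' @param X_real,X_syn Matrices / data frames with identical feature columns.
#' @param n_bins Bins for [discretize_pair()].
#' @return A `dermaug_quality` list: `per_feature` tibble, `mean_hd`,
#'   `mean_maep`, `pcd`, `rsvr`.
#' @export
quality_report <- function(X_real, X_syn, n_bins = 20L) {
  X_real <- as.data.frame(X_real); X_syn <- as.data.frame(X_syn)
  if (!identical(sort(names(X_real)), sort(names(X_syn)))) {
    stop_invalid("X_syn", "feature columns must match X_real")
  }
  X_syn <- X_syn[, names(X_real), drop = FALSE]
  per <- purrr::map_dfr(names(X_real), function(f) {
    pair <- discretize_pair(X_real[[f]], X_syn[[f]], n_bins)
    tibble(feature = f, hd = hellinger(pair), maep = maep(pair))
  })
  num <- vapply(X_real, is.numeric, logical(1))
  out <- list(per_feature = per,
              mean_hd = mean(per$hd), mean_maep = mean(per$maep),
              pcd = if (sum(num) >= 2 && nrow(X_real) >= 3 && nrow(X_syn) >= 3) {
                pcd(X_real[, num, drop = FALSE], X_syn[, num, drop = FALSE])
              } else NA_real_,
              rsvr = rsvr(X_syn))
  class(out) <- "dermaug_quality"
  out
}

#' @export
print.dermaug_quality <- function(x, ...) {
  cat("Synthetic-data quality report\n")
  cat(sprintf("  mean HD:   %.4f\n  mean MAEP: %.4f\n  PCD:       %.4f\n  RSVR:      %.4f\n",
              x$mean_hd, x$mean_maep, x$pcd, x$rsvr))
  invisible(x)
}
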