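#' Number of synthetic minority samples needed to reach a balance ratio
#'
#' For minority count `n_min`, majority count `n_maj` and target balance
#' ratio `r = (n_min + n_syn) / n_maj` in `(0, 1]` (1 = fully balanced), the
#' required count is `max(0, ceiling(r * n_maj) - n_min)`. Note this sweep
#' ratio is a different quantity from the majority/minority imbalance ratio
#' used to describe datasets (e.g. 160/40 = 4.00).
#'
#' @param n_min,n_maj Class counts (`n_min <= n_maj`).
#' @param r Target balance ratio in `(0, 1]`.
#' @return Integer number of synthetic samples.
#' @export
n_synthetic_for_ratio <- function(n_min, n_maj, r) {
  check_number(n_min, "n_min", min = 0, integerish = TRUE)
  check_number(n_maj, "n_maj", min = 1, integerish = TRUE)
  if (n_min > n_maj) stop_invalid("n_min", "must satisfy n_min <= n_maj")
  check_number(r, "r")
  if (r <= 0 || r > 1) stop_invalid("r", "must be in (0, 1]")
  max(0L, as.integer(ceiling(r * n_maj) - n_min))
}

#' SMOTE synthetic minority samples
#'
#' Each synthetic row is `x + u * (x_nn - x)` with `u ~ Uniform(0, 1)` and
#' `x_nn` one of the `k` nearest minority neighbours of `x` (Euclidean
#' distance on z-scored features); base points are drawn uniformly from the
#' minority rows. Synthetic rows therefore lie inside the minority convex
#' hull by construction.
#'
#' @param X_min Minority feature matrix (>= 2 rows).
#' @param n_syn Number of synthetic rows to create.
#' @param k Neighbourhood size (default 5; capped at `nrow - 1`).
#' @param seed Integer seed.
#' @return Matrix with `n_syn` rows on the original feature scale.
#' @export
smote_sample <- function(X_min, n_syn, k = 5L, seed = 1L) {
  X_min <- as.matrix(X_min)
  if (nrow(X_min) < 2) abort("SMOTE needs at least 2 minority rows",
                             class = "dermaug_validation_error")
  check_number(n_syn, "n_syn", min = 0, integerish = TRUE)
  if (n_syn == 0) return(X_min[0, , drop = FALSE])
  k <- min(k, nrow(X_min) - 1L)
  mu <- colMeans(X_min)
  sg <- apply(X_min, 2, sd); sg[sg == 0] <- 1
  Z <- sweep(sweep(X_min, 2, mu), 2, sg, "/")
  dm <- as.matrix(stats::dist(Z))
  diag(dm) <- Inf
  nn <- do.call(rbind, lapply(seq_len(nrow(X_min)),
                              function(i) order(dm[i, ])[seq_len(k)]))
  with_seed(seed, {
    base <- sample.int(nrow(X_min), n_syn, replace = TRUE)
    pick <- nn[cbind(base, sample.int(k, n_syn, replace = TRUE))]
    u <- runif(n_syn)
    X_min[base, , drop = FALSE] +
      u * (X_min[pick, , drop = FALSE] - X_min[base, , drop = FALSE])
  })
}

#' Oversample the minority class of a feature table to a target balance ratio
#'
#' Appends [n_synthetic_for_ratio()] synthetic minority rows generated by the
#' chosen method. Real rows are never modified or removed; synthetic rows
#' carry the minority label and `source = "synthetic"`. Only the SMOTE path
#' is implemented natively; `"ctgan"` and `"tvae"` are adapter slots for
#' external conditional generators and raise a capability error when no such
#' backend is available, as in this build.
#'
#' @param table Feature table (tibble with `label`, optional `sample_id`,
#'   `source`).
#' @param method `"smote"`, `"ctgan"` or `"tvae"`.
#' @param r Target balance ratio in `(0, 1]`.
#' @param seed Integer seed.
#' @param k SMOTE neighbourhood size.
#' @return The augmented tibble.
#' @export
augment_to_ratio <- function(table, method = c("smote", "ctgan", "tvae"),
                             r = 1.0, seed = 1L, k = 5L) {
  method <- match.arg(method)
  if (!"label" %in% names(table)) stop_invalid("table", "must have a `label` column")
  if (!all(table$label %in% c(0, 1))) stop_invalid("label", "must be binary 0/1")
  if (!"source" %in% names(table)) table$source <- "real"
  counts <- table(factor(table$label, levels = c(0, 1)))
  minority <- if (counts[["1"]] <= counts[["0"]]) 1L else 0L
  n_min <- min(counts); n_maj <- max(counts)
  n_syn <- n_synthetic_for_ratio(n_min, n_maj, r)
  if (n_syn == 0) return(table)
  if (method %in% c("ctgan", "tvae")) {
    stop_capability(method, "no conditional tabular generator backend is installed; use method = \"smote\"")
  }
  xy <- table_xy(table)
  X_min <- xy$X[table$label == minority, , drop = FALSE]
  syn <- smote_sample(X_min, n_syn, k = k, seed = seed)
  syn_tbl <- as_tibble(as.data.frame(syn))
  names(syn_tbl) <- xy$features
  meta <- tibble(label = rep(minority, n_syn), source = "synthetic")
  if ("sample_id" %in% names(table)) {
    meta <- dplyr::bind_cols(tibble(sample_id = sprintf("syn_%05d", seq_len(n_syn))), meta)
  }
  dplyr::bind_rows(table, dplyr::bind_cols(meta, syn_tbl))
}
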