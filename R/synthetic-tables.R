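#' Specification for a synthetic imbalanced feature table
#'
#' Describes a two-class tabular dataset emulating an extracted-feature table:
#' `n_maj` majority (label 0) and `n_min` minority (label 1) rows over
#' `n_features` columns, of which the first `n_informative` carry a
#' class-conditional mean shift of `effect_size` (in units of the feature
#' standard deviation) and share an equicorrelated Gaussian block with
#' pairwise Pearson correlation `block_corr`. The remaining features are
#' standard-normal noise, identical in distribution across classes.
#'
#' @param n_maj,n_min Majority / minority class sizes (`n_min <= n_maj`).
#' @param n_features Total number of features D.
#' @param n_informative Number of informative features (<= D).
#' @param effect_size Class mean shift in feature-sd units (>= 0).
#' @param block_corr Pairwise correlation within the informative block, in `[0, 1)`.
#' @param seed Integer seed.
#' @return An object of class `dermaug_table_spec`.
#' @export
table_spec <- function(n_maj, n_min, n_features, n_informative,
                       effect_size = 1, block_corr = 0, seed = 1L) {
  check_number(n_maj, "n_maj", min = 1, integerish = TRUE)
  check_number(n_min, "n_min", min = 1, integerish = TRUE)
  if (n_min > n_maj) stop_invalid("n_min", "must satisfy n_min <= n_maj")
  check_number(n_features, "n_features", min = 1, integerish = TRUE)
  check_number(n_informative, "n_informative", min = 0, integerish = TRUE)
  if (n_informative > n_features) {
    stop_invalid("n_informative", "must satisfy n_informative <= n_features")
  }
  check_number(effect_size, "effect_size", min = 0)
  check_number(block_corr, "block_corr", min = 0)
  if (block_corr >= 1) stop_invalid("block_corr", "must be in [0, 1)")
  check_number(seed, "seed", integerish = TRUE)
  structure(
    list(n_maj = as.integer(n_maj), n_min = as.integer(n_min),
         n_features = as.integer(n_features),
         n_informative = as.integer(n_informative),
         effect_size = effect_size, block_corr = block_corr,
         seed = as.integer(seed)),
    class = "dermaug_table_spec"
  )
}

#' Generate a synthetic imbalanced feature table with known ground truth
#'
#' @param spec A [table_spec()].
#' @return A list with `table` (a tibble with `sample_id`, `label`, `source`
#'   and feature columns `feat_001`, ...) and `informative` (the names of the
#'   planted informative features).
#' @examples
#' out <- generate_feature_table(table_spec(160, 40, 20, 5, effect_size = 1.5))
#' table(out$table$label)
#' @export
generate_feature_table <- function(spec) {
  if (!inherits(spec, "dermaug_table_spec")) {
    stop_invalid("spec", "must be created by table_spec()")
  }
  n <- spec$n_maj + spec$n_min
  D <- spec$n_features
  k <- spec$n_informative
  y <- c(rep(0L, spec$n_maj), rep(1L, spec$n_min))
  X <- with_seed(spec$seed, {
    X <- matrix(rnorm(n * D), n, D)
    if (k > 0) {
      # Equicorrelated block: x_i = sqrt(rho) z0 + sqrt(1 - rho) z_i keeps
      # unit variance and pairwise correlation rho.
      rho <- spec$block_corr
      if (rho > 0) {
        z0 <- rnorm(n)
        X[, seq_len(k)] <- sqrt(rho) * z0 +
          sqrt(1 - rho) * X[, seq_len(k), drop = FALSE]
      }
      X[y == 1L, seq_len(k)] <- X[y == 1L, seq_len(k), drop = FALSE] +
        spec$effect_size
    }
    X
  })
  nm <- sprintf("feat_%03d", seq_len(D))
  colnames(X) <- nm
  tbl <- dplyr::bind_cols(
    tibble(sample_id = sprintf("s%04d", seq_len(n)),
           label = y, source = "real"),
    as_tibble(X)
  )
  list(table = tbl, informative = nm[seq_len(k)])
}

# Split a feature table into its feature matrix and label vector.
table_xy <- function(table) {
  meta <- intersect(c("sample_id", "label", "source"), names(table))
  X <- as.matrix(table[, setdiff(names(table), meta), drop = FALSE])
  list(X = X, y = table$label, features = colnames(X))
}
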