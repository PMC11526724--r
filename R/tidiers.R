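# broom-style tidiers for the package's result objects.

#' @describeIn ensemble_select Tidy the aggregated ranking: one row per
#'   feature with votes, mean rank and final rank.
#' @param x A `dermaug_ranking`.
#' @param ... Unused.
#' @method tidy dermaug_ranking
#' @export
tidy.dermaug_ranking <- function(x, ...) {
  as_tibble(unclass(x))
}

#' @method tidy dermaug_experiment
#' @export
tidy.dermaug_experiment <- function(x, ...) {
  x$summary
}

#' @method glance dermaug_experiment
#' @export
glance.dermaug_experiment <- function(x, ...) {
  best <- x$summary |>
    dplyr::filter(.data$metric == "auc") |>
    dplyr::slice_max(.data$mean, n = 1, with_ties = FALSE)
  tibble(n_models = length(x$models), n_ratios = length(x$r_values),
         repeats = max(x$per_repeat$repeat_),
         best_model = best$model, best_r = best$r, best_auc = best$mean)
}

#' @method tidy dermaug_quality
#' @export
tidy.dermaug_quality <- function(x, ...) {
  x$per_feature
}

#' @method glance dermaug_quality
#' @export
glance.dermaug_quality <- function(x, ...) {
  tibble(mean_hd = x$mean_hd, mean_maep = x$mean_maep,
         pcd = x$pcd, rsvr = x$rsvr)
}

#' @method tidy dermaug_boottest
#' @export
tidy.dermaug_boottest <- function(x, ...) {
  as_tibble(unclass(x))
}
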