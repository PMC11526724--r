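# ggplot2 views of the result objects.

#' @method autoplot dermaug_experiment
#' @export
autoplot.dermaug_experiment <- function(object, metric = "auc", ...) {
  dat <- dplyr::filter(object$summary, .data$metric == !!metric)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$r, y = .data$mean,
                                    colour = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sd,
                                          ymax = .data$mean + .data$sd)) +
    ggplot2::labs(x = "target balance ratio r", y = sprintf("%s (mean ± sd)", metric),
                  title = "Imbalance-ratio sweep") +
    ggplot2::theme_minimal()
}

#' @method autoplot dermaug_quality
#' @export
autoplot.dermaug_quality <- function(object, ...) {
  dat <- tidyr::pivot_longer(object$per_feature, c("hd", "maep"),
                             names_to = "metric", values_to = "value")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$feature, y = .data$value)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, title = "Per-feature fidelity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' @method autoplot dermaug_boottest
#' @export
autoplot.dermaug_boottest <- function(object, top = 30L, ...) {
  dat <- dplyr::slice_max(as_tibble(unclass(object)), abs(.data$delta_hat), n = top)
  dat$feature <- factor(dat$feature, levels = dat$feature[order(dat$delta_hat)])
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$delta_hat, y = .data$feature,
                                    colour = .data$delta_hat > 0)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high)) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#1f6fb4", `FALSE` = "#2e8b57"),
                                 labels = c(`TRUE` = "melanoma-associated",
                                            `FALSE` = "not-melanoma-associated"),
                                 name = NULL) +
    ggplot2::labs(x = expression(Delta == mu[melanoma] - mu["not melanoma"]),
                  y = NULL, title = "Bootstrap-CI feature differences") +
    ggplot2::theme_minimal()
}

#' @method autoplot dermaug_ranking
#' @export
autoplot.dermaug_ranking <- function(object, top = 35L, ...) {
  dat <- head(as_tibble(unclass(object)), top)
  dat$feature <- factor(dat$feature, levels = rev(dat$feature))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$votes, y = .data$feature)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "ensemble votes", y = NULL,
                  title = "Ensemble feature-selection votes") +
    ggplot2::theme_minimal()
}

#' Display a lesion sample (image, mask and hair strokes)
#'
#' @param x A `dermaug_lesion`.
#' @param ... Unused.
#' @export
plot.dermaug_lesion <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 3), mar = c(0.5, 0.5, 2, 0.5))
  on.exit(graphics::par(op))
  plot_rgb <- function(img, main) {
    graphics::plot(0:1, 0:1, type = "n", axes = FALSE, xlab = "", ylab = "",
                   main = main, asp = 1)
    graphics::rasterImage(img, 0, 0, 1, 1)
  }
  plot_rgb(x$image, sprintf("lesion (label %d)", x$label))
  plot_rgb(array(rep(x$mask, 3), dim = c(dim(x$mask), 3)), "mask")
  plot_rgb(array(rep(x$hair_mask, 3), dim = c(dim(x$hair_mask), 3)), "hair strokes")
  invisible(x)
}
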