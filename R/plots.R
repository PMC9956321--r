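#' Plot a bagplot result
#'
#' Shows the point cloud with the bag and fence polygons and highlights the
#' flagged outliers.
#'
#' @param object A `bagplot_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bagplot_result
#' @export
autoplot.bagplot_result <- function(object, ...) {
  pts <- object$points
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y))
  poly_df <- function(m, what) {
    tibble(x = m[, 1], y = m[, 2], what = what)
  }
  if (!is.null(object$fence)) {
    p <- p + ggplot2::geom_polygon(data = poly_df(object$fence, "fence"),
                                   fill = "steelblue", alpha = 0.1,
                                   colour = "steelblue", linetype = 2)
  }
  if (!is.null(object$bag)) {
    p <- p + ggplot2::geom_polygon(data = poly_df(object$bag, "bag"),
                                   fill = "steelblue", alpha = 0.3,
                                   colour = "steelblue")
  }
  p <- p +
    ggplot2::geom_point(ggplot2::aes(colour = .data$outlier)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black", `TRUE` = "red"))
  if (!is.null(object$median)) {
    p <- p + ggplot2::annotate("point", x = object$median[1],
                               y = object$median[2], shape = 3, size = 3,
                               colour = "darkorange")
  }
  p + ggplot2::labs(colour = "outlier") + ggplot2::theme_minimal()
}

#' Plot per-sample bootstrap outlier probabilities
#'
#' One point per sample: estimated outlier probability with the one-sided
#' lower confidence bound as an error bar, significant samples highlighted,
#' and the 0.5 reference line of the binomial test.
#'
#' @param object An `outlier_table`.
#' @param top Show only the `top` samples of highest probability.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot outlier_table
#' @export
autoplot.outlier_table <- function(object, top = 20, ...) {
  df <- as_tibble(as.data.frame(object))
  df <- tidyr::drop_na(df, "probability")
  df <- head(df[order(-df$probability, -df$detections), ], top)
  df$sample_id <- factor(df$sample_id, levels = rev(df$sample_id))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$probability, y = .data$sample_id)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$ci_lower,
                                       xend = pmin(1, .data$probability),
                                       yend = .data$sample_id),
                          colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant)) +
    ggplot2::geom_vline(xintercept = 0.5, linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black", `TRUE` = "red")) +
    ggplot2::labs(x = "outlier probability", y = NULL,
                  colour = sprintf("p < %.2g", attr(object, "alpha"))) +
    ggplot2::theme_minimal()
}

#' Plot a performance table
#'
#' Mean performance (with standard-error ribbons) against the number of
#' predictor genes, one panel per metric, coloured by strategy when present.
#'
#' @param object A `performance_table`.
#' @param metrics Metrics to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot performance_table
#' @export
autoplot.performance_table <- function(object,
                                       metrics = c("accuracy", "brier",
                                                   "sensitivity", "specificity"),
                                       ...) {
  df <- as_tibble(as.data.frame(object))
  if (!"strategy" %in% names(df)) df$strategy <- "all"
  long <- purrr::list_rbind(purrr::map(metrics, function(m) {
    tibble(strategy = df$strategy, classifier = df$classifier,
           n_genes = df$n_genes, metric = m,
           mean = df[[m]], se = df[[paste0(m, "_se")]])
  }))
  long <- long[!is.na(long$mean), ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$n_genes, y = .data$mean,
                                     colour = .data$strategy,
                                     fill = .data$strategy)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$se,
                                      ymax = .data$mean + .data$se),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "number of predictor genes", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
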