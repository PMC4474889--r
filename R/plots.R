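#' Plot methods
#'
#' `autoplot()` methods give quick ggplot2 views of the main result types:
#' a connectivity matrix heat map per band, a t-statistic channel-by-frequency
#' map for group comparisons, the ROC curve with its operating point, and
#' group box plots for subject scores.
#'
#' @param object the result object.
#' @param band which band/frequency slice to show (connectivity results).
#' @param ... unused.
#' @return a ggplot object.
#' @name spectconn-autoplot
NULL

#' @rdname spectconn-autoplot
#' @export
autoplot.connectivity_result <- function(object, band = 1, ...) {
  bi <- if (is.character(band)) match(band, as.character(object$freqs)) else band
  df <- tibble::tibble(
    target = factor(rep(object$labels, times = length(object$labels)),
                    levels = object$labels),
    source = factor(rep(object$labels, each = length(object$labels)),
                    levels = object$labels),
    value = as.vector(object$values[, , bi]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$source, y = .data$target,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(title = sprintf("%s (%s)", object$measure,
                                  object$freqs[bi]),
                  x = "source", y = "target") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @rdname spectconn-autoplot
#' @export
autoplot.group_comparison <- function(object, ...) {
  tm <- attr(object, "t_matrix")
  if (!is.null(tm)) {
    df <- tibble::tibble(
      channel = factor(rep(rownames(tm), times = ncol(tm)),
                       levels = rownames(tm)),
      freq = rep(as.numeric(colnames(tm)), each = nrow(tm)),
      t = as.vector(tm))
    return(
      ggplot2::ggplot(df, ggplot2::aes(x = .data$freq, y = .data$channel,
                                       fill = .data$t)) +
        ggplot2::geom_tile() +
        ggplot2::scale_fill_gradient2() +
        ggplot2::labs(x = "frequency (Hz)", y = NULL,
                      fill = "t (pat - ctrl)") +
        ggplot2::theme_minimal())
  }
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$unit, y = .data$t,
                               colour = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "unit", y = "t (patient - control)") +
    ggplot2::theme_minimal()
}

#' @rdname spectconn-autoplot
#' @export
autoplot.roc_analysis <- function(object, ...) {
  df <- object$curve
  ggplot2::ggplot(df, ggplot2::aes(x = 1 - .data$specificity,
                                   y = .data$sensitivity)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point(data = object$optimal, colour = "red", size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("ROC (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' @rdname spectconn-autoplot
#' @param scores a tibble with `score` and `group` columns, as returned in
#'   the pipeline's `scores` element.
#' @export
plot_score_distributions <- function(scores, ...) {
  ggplot2::ggplot(scores, ggplot2::aes(x = .data$group, y = .data$score,
                                       fill = .data$group)) +
    ggplot2::geom_boxplot(alpha = 0.6, outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.7) +
    ggplot2::guides(fill = "none") +
    ggplot2::labs(x = NULL, y = "subject score") +
    ggplot2::theme_minimal()
}
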