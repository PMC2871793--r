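#' Histogram of linear-discriminant scores by group
#'
#' The classic one-dimensional view of a two-class LDA: per-sample LD
#' scores, colored by true group, with the decision boundary drawn where
#' the prior-adjusted score is zero.
#'
#' @param x a [fit_lda()] or [loocv_lda()] object.
#' @param binwidth histogram bin width (default: Freedman-Diaconis-ish
#'   choice from the score range).
#' @return a ggplot object.
#' @export
plot_ld_histogram <- function(x, binwidth = NULL) {
  scores <- if (inherits(x, "caste_lda")) {
    boundary <- -x$intercept
    x$scores
  } else if (inherits(x, "caste_loocv")) {
    boundary <- NA_real_
    x$predictions
  } else {
    abort("x must be a caste_lda or caste_loocv object",
          class = "castebias_argument_error")
  }
  if (is.null(binwidth)) {
    binwidth <- diff(range(scores$ld_score)) / 15
    if (!is.finite(binwidth) || binwidth <= 0) binwidth <- 1
  }
  p <- ggplot2::ggplot(scores, ggplot2::aes(x = .data$ld_score, fill = .data$group)) +
    ggplot2::geom_histogram(binwidth = binwidth, position = "identity",
                            alpha = 0.65, color = "grey30") +
    ggplot2::labs(x = "LD score", y = "frequency", fill = "group") +
    ggplot2::theme_minimal()
  if (is.finite(boundary)) {
    p <- p + ggplot2::geom_vline(xintercept = boundary, linetype = "dashed")
  }
  p
}

#' @export
autoplot.caste_lda <- function(object, ...) plot_ld_histogram(object, ...)

#' @export
autoplot.caste_loocv <- function(object, ...) plot_ld_histogram(object, ...)

#' Heatmap of z-transformed significant features
#'
#' @param heatmap_data output of [build_heatmap_data()].
#' @return a ggplot object (tile heatmap, samples in group blocks, features
#'   by ascending p).
#' @export
plot_expression_heatmap <- function(heatmap_data) {
  stopifnot_cols(heatmap_data, c("feature_id", "sample_id", "value"),
                 "heatmap data")
  ggplot2::ggplot(heatmap_data,
                  ggplot2::aes(x = .data$sample_id, y = .data$feature_id,
                               fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, fill = "z score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Median / quartile summary plot of normalized abundances
#'
#' @param summaries output of [summarize_abundance()] (optionally
#'   restricted to significant hits).
#' @return a ggplot object: per-hit median with quartile brackets, by
#'   group; outliers as open circles.
#' @export
plot_abundance_summary <- function(summaries) {
  stopifnot_cols(summaries, c("feature_id", "group", "median", "q1", "q3"),
                 "summaries")
  outl <- summaries |>
    dplyr::select("feature_id", "group", "outliers") |>
    tidyr::unnest("outliers")
  p <- ggplot2::ggplot(summaries,
                       ggplot2::aes(x = .data$group, y = .data$median)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$q1, ymax = .data$q3),
                             shape = 15) +
    ggplot2::facet_wrap(~feature_id, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "normalized spectral count") +
    ggplot2::theme_minimal()
  if (nrow(outl)) {
    p <- p + ggplot2::geom_point(data = outl,
                                 ggplot2::aes(y = .data$outliers),
                                 shape = 1, size = 2)
  }
  p
}
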