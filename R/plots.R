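#' Ordered contrast-score plot
#'
#' Bar plot of samples ordered by contrast score, optionally coloured by the
#' observed group -- the standard way to display an abstaining contrast-score
#' classifier (indeterminates sit on the zero line).
#'
#' @param object A `sample_predictions` tibble.
#' @param observed Optional `contrast_cohort` or data frame with `sample_id`
#'   and `label`, used to colour bars by observed group.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sample_predictions
#' @export
autoplot.sample_predictions <- function(object, observed = NULL, ...) {
  df <- tibble::as_tibble(object)
  if (!is.null(observed)) {
    obs <- tibble::as_tibble(observed)[, c("sample_id", "label")]
    df <- dplyr::left_join(df, obs, by = "sample_id")
  } else {
    df$label <- df$predicted
  }
  df <- dplyr::arrange(df, dplyr::desc(.data$score))
  df$rank <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$score,
                                   fill = .data$label)) +
    ggplot2::geom_col(width = 0.9) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "sample (ordered by score)", y = "contrast score",
                  fill = if (is.null(observed)) "predicted" else "observed") +
    ggplot2::theme_minimal()
}

#' Confusion-count tile plot for a performance report
#'
#' @param object A `performance_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot performance_report
#' @export
autoplot.performance_report <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$observed,
                                   fill = .data$n)) +
    ggplot2::geom_tile(colour = "grey40") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "predicted", y = "observed") +
    ggplot2::theme_minimal()
}

#' RFU distribution plot for a binding table
#'
#' Histogram of log10 RFU pooled over all replicates, with the positivity
#' threshold marked; assay-like data show a large background mode well below
#' the threshold and a small bound-signal mode above it.
#'
#' @param binding A `binding_tbl`.
#' @param rfu_threshold Threshold line to draw (default 20000).
#' @return A ggplot object.
#' @export
plot_rfu_distribution <- function(binding, rfu_threshold = 20000) {
  df <- tibble::tibble(log10_rfu = log10(pmax(binding$rfu, 1)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log10_rfu)) +
    ggplot2::geom_histogram(bins = 80, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = log10(rfu_threshold), colour = "red",
                        linetype = 2) +
    ggplot2::labs(x = "log10 RFU", y = "measurements") +
    ggplot2::theme_minimal()
}
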