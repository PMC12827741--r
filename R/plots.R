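#' Plot a score distribution against the two linkage thresholds
#'
#' Histogram of pairwise similarity scores with the non-match and match
#' thresholds drawn in; the three zones correspond to non-match, tentative
#' match and match.
#'
#' @param scores Numeric vector or tibble with a `score` column.
#' @param config A [linkage_config()] supplying the thresholds.
#' @param bins Histogram bins.
#' @return A ggplot object.
#' @export
plot_score_distribution <- function(scores, config = linkage_config(),
                                    bins = 40) {
  if (is.data.frame(scores)) scores <- scores$score
  df <- tibble::tibble(score = scores[!is.na(scores)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey65", colour = "grey30") +
    ggplot2::geom_vline(xintercept = config$threshold_nonmatch,
                        linetype = "dashed", colour = "orange") +
    ggplot2::geom_vline(xintercept = config$threshold_match,
                        linetype = "dashed", colour = "darkgreen") +
    ggplot2::labs(x = "similarity score", y = "pairs",
                  title = "Pair similarity scores",
                  subtitle = sprintf("thresholds: non-match < %.2f <= tentative < %.2f <= match",
                                     config$threshold_nonmatch,
                                     config$threshold_match)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @exportS3Method ggplot2::autoplot
autoplot.batch_job <- function(object, ...) {
  out <- batch_outcomes(object)
  if (is.null(out)) stop("job has not run yet", call. = FALSE)
  ggplot2::ggplot(out, ggplot2::aes(x = .data$outcome)) +
    ggplot2::geom_bar(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "records", title = "Batch import outcomes") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.linkage_eval <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue", width = 0.5) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, title = "Linkage evaluation") +
    ggplot2::theme_minimal()
}
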