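#' Box-and-whisker statistics by spirometric grade
#'
#' Standard box-plot summaries of a readout per group: lower quartile (Q1),
#' median (Q2), upper quartile (Q3) by linear interpolation of order
#' statistics (type 7), whiskers at `Q1 - 1.5 IQR` and `Q3 + 1.5 IQR`
#' (clamped to the observed range) and the count of outliers beyond them.
#' Empty groups are omitted with a warning.
#'
#' @param data tibble with the readout and grouping columns.
#' @param value value column name.
#' @param group grouping column name (default `"gold_class"`).
#' @return Tibble with one row per non-empty group.
#' @export
gold_boxplot_stats <- function(data, value, group = "gold_class") {
  if (!all(c(value, group) %in% names(data))) {
    stop("missing columns in `data`", call. = FALSE)
  }
  groups <- unique(as.character(data[[group]]))
  rows <- list()
  for (g in groups) {
    v <- data[[value]][data[[group]] == g]
    v <- v[is.finite(v)]
    if (!length(v)) {
      warning(sprintf("group '%s' is empty and was omitted", g), call. = FALSE)
      next
    }
    q <- unname(quantile(v, c(0.25, 0.5, 0.75), type = 7))
    iqr <- q[3] - q[1]
    lo <- q[1] - 1.5 * iqr
    hi <- q[3] + 1.5 * iqr
    rows[[length(rows) + 1L]] <- tibble::tibble(
      group = g, n = length(v),
      q1 = q[1], median = q[2], q3 = q[3],
      whisker_lo = max(lo, min(v)), whisker_hi = min(hi, max(v)),
      n_outliers = sum(v < lo | v > hi))
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "quartile_type") <- 7L
  out
}

#' Box plots of whole-lung tPRM readouts by grade
#'
#' @param data case-level tibble with a grade column and readout columns.
#' @param values readout column names to plot.
#' @param group grade column (default `"gold_class"`).
#' @return A ggplot.
#' @export
plot_gold_boxplots <- function(data, values, group = "gold_class") {
  long <- tidyr::pivot_longer(data, cols = dplyr::all_of(values),
                              names_to = "readout", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data[[group]], y = .data$value,
                                     fill = .data[[group]])) +
    ggplot2::geom_boxplot(outlier.size = 0.6, show.legend = FALSE) +
    ggplot2::facet_wrap(~readout, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn evaluate_classifier ROC curve plot.
#' @param object a `tprm_eval`.
#' @method autoplot tprm_eval
#' @export
autoplot.tprm_eval <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path(linewidth = 0.8, colour = "#2c7fb8") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("ROC (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' Bar plot of mRMR feature ranks
#'
#' @param ranking a [mrmr_rank()] tibble.
#' @return A ggplot.
#' @export
plot_feature_ranks <- function(ranking) {
  ggplot2::ggplot(ranking,
                  ggplot2::aes(x = stats::reorder(.data$feature, -.data$score),
                               y = .data$score)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::labs(x = NULL, y = "mRMR score") +
    ggplot2::theme_minimal()
}
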