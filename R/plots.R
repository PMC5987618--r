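#' Plot a 3' UTR length histogram
#'
#' Bar chart of binned feature lengths, optionally faceted by species if
#' the histogram table carries a `species` column.
#'
#' @param hist_tbl Tibble from [length_histogram()] (optionally with a
#'   `species` column prepended).
#' @return A ggplot object.
#' @export
plot_length_histogram <- function(hist_tbl) {
  p <- ggplot2::ggplot(hist_tbl,
                       ggplot2::aes(x = .data$bin_start + 25,
                                    y = .data$count)) +
    ggplot2::geom_col(width = diff(range(hist_tbl$bin_end))[1] /
                        max(1, nrow(hist_tbl)) * 0.9,
                      fill = "steelblue") +
    ggplot2::labs(x = "3' UTR length (nt)", y = "Genes") +
    ggplot2::theme_minimal()
  if ("species" %in% names(hist_tbl))
    p <- p + ggplot2::facet_wrap(~species, scales = "free_y")
  p
}

#' Plot repeat fractions per feature class and species
#'
#' @param report Tibble from [repeat_fraction()] rows, with a `species`
#'   column (as produced by [run_pipeline()]).
#' @return A ggplot object.
#' @export
plot_repeat_fractions <- function(report) {
  ggplot2::ggplot(report,
                  ggplot2::aes(x = .data$species,
                               y = 100 * .data$fraction,
                               fill = .data$feature)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "Repeat content (%)", fill = "Feature") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Histogram of per-gene log10 ratios with the zero reference
#'
#' Works for both clade length ratios ([length_log_ratio()]) and rate
#' ratios ([fit_bm_rates()] output).
#'
#' @param ratios Numeric vector of log10 ratios (`NA`s dropped).
#' @param xlab Axis label.
#' @return A ggplot object.
#' @export
plot_log10_ratios <- function(ratios,
                              xlab = "log10(focal / background)") {
  df <- tibble::tibble(log10_ratio = ratios[!is.na(ratios)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log10_ratio)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey35") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "red") +
    ggplot2::labs(x = xlab, y = "Genes") +
    ggplot2::theme_minimal()
}

#' @method autoplot utr3_bm_fits
#' @export
autoplot.utr3_bm_fits <- function(object, ...) {
  plot_log10_ratios(object$log10_ratio[object$flag == "ok"],
                    xlab = "log10(sigma2 focal / sigma2 background)")
}
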