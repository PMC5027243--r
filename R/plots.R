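# ggplot2 visualizations of the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a deletion size spectrum
#'
#' @param object A `radsig_spectrum` from [deletion_size_spectrum()].
#' @param max_length Right edge of the plotted spectrum (default 30 bp;
#'   the `">100"` bin is always shown).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.radsig_spectrum <- function(object, max_length = 30L, ...) {
  keep <- c(as.character(seq_len(max_length)), ">100")
  df <- object[object$length_bin %in% keep, , drop = FALSE]
  y <- if ("fraction" %in% names(df)) "fraction" else "count"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$length_bin,
                                   y = .data[[y]])) +
    ggplot2::geom_col(fill = "grey25") +
    ggplot2::labs(x = "deletion length (bp)", y = y) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot a feature-association battery
#'
#' Shows each feature's q-value against its magnitude of difference; the
#' dual significance rule's rejection region is shaded.
#'
#' @param object A `radsig_feature_tests` tibble.
#' @param q_threshold,magnitude_threshold The dual-rule thresholds used.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.radsig_feature_tests <- function(object, q_threshold = 0.01,
                                          magnitude_threshold = 0.05, ...) {
  df <- tidy.radsig_feature_tests(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$magnitude_diff,
                                   y = -log10(pmax(.data$q_value, 1e-300)),
                                   colour = .data$significant)) +
    ggplot2::geom_vline(xintercept = magnitude_threshold,
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(q_threshold),
                        linetype = "dashed") +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_text(ggplot2::aes(label = .data$feature), vjust = -1,
                       show.legend = FALSE, size = 3) +
    ggplot2::labs(x = "magnitude of difference",
                  y = expression(-log[10](q)), colour = "significant") +
    ggplot2::theme_minimal()
}

#' Plot a relative indel probability profile
#'
#' @param object A `radsig_profile` from [indel_probability_profile()].
#' @param chrom Optional single chromosome to show.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.radsig_profile <- function(object, chrom = NULL, ...) {
  df <- object$profile
  if (!is.null(chrom)) df <- df[df$chrom == chrom, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = (.data$start + .data$end) / 2e6,
                                   y = .data$probability)) +
    ggplot2::geom_line(colour = "grey25") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "relative indel probability") +
    ggplot2::theme_minimal()
}

#' Plot per-bin mutation density ratios
#'
#' @param ratios Tibble from [density_ratio()].
#' @param feature Axis label for the binned feature.
#' @return A ggplot.
#' @export
plot_density_ratio <- function(ratios, feature = "feature bin") {
  ggplot2::ggplot(ratios[!ratios$undefined, , drop = FALSE],
                  ggplot2::aes(x = .data$bin, y = .data$ratio)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(x = feature, y = "mutation density / background density") +
    ggplot2::theme_minimal()
}
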