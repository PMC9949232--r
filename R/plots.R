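#' Plot a summit-window saturation curve
#'
#' @param curve A [saturation_analysis()] result.
#' @return A ggplot.
#' @export
plot_saturation <- function(curve) {
  sel <- attr(curve, "selected_window")
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$window, y = .data$n_overlapping)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = sel, linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "summit window (bp)", y = "overlapping peaks",
                  title = sprintf("Saturation at %d bp", sel)) +
    ggplot2::theme_minimal()
}

#' Plot a genomic feature-class distribution
#'
#' @param dist A [feature_distribution()] tibble.
#' @return A ggplot.
#' @export
plot_feature_distribution <- function(dist) {
  ggplot2::ggplot(dist, ggplot2::aes(x = .data$feature_class, y = .data$fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "fraction of peaks") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a metagene profile
#'
#' @param mg A [metagene_profile()] result.
#' @return A ggplot of the mean per-million coverage over flank and scaled
#'   gene-body bins.
#' @export
plot_metagene <- function(mg) {
  stopifnot(inherits(mg, "metagene_matrix"))
  nf <- mg$flank %/% mg$flank_bin
  ggplot2::ggplot(mg$profile, ggplot2::aes(x = .data$bin, y = .data$mean)) +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::geom_vline(xintercept = c(nf + 0.5, nf + mg$body_bins + 0.5),
                        linetype = "dotted") +
    ggplot2::labs(x = "5' flank | scaled gene body | 3' flank",
                  y = "mean coverage (per million)") +
    ggplot2::theme_minimal()
}

#' Plot actual versus expected RNA-peak element distributions
#'
#' @param actual An [element_distribution()] tibble.
#' @param expected Optional [expected_element_distribution()] tibble.
#' @return A ggplot.
#' @export
plot_element_distribution <- function(actual, expected = NULL) {
  df <- mutate(actual, which = "actual")
  if (!is.null(expected)) {
    df <- bind_rows(df, tibble(element = expected$element,
                               n = NA_integer_,
                               fraction = expected$expected_fraction,
                               which = "expected"))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$element, y = .data$fraction,
                                   fill = .data$which)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "fraction of peaks", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Volcano plot of a differential-expression fit
#'
#' @param object A `tet_de` object.
#' @param ... Unused.
#' @return A ggplot with genes coloured by direction.
#' @export
#' @importFrom ggplot2 autoplot
autoplot.tet_de <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2_fc,
                                   y = -log10(.data$p_adjust),
                                   colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(up = "forestgreen",
                                            down = "firebrick",
                                            unchanged = "grey60")) +
    ggplot2::labs(x = "log2 fold change (Tet-null / wt)",
                  y = "-log10 adjusted p") +
    ggplot2::theme_minimal()
}

#' @export
ggplot2::autoplot
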