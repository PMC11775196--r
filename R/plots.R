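#' Volcano plot of an isoform differential result
#'
#' @param object A `ps_diff` tibble from [differential_isoform()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.ps_diff <- function(object, ...) {
  lfc <- attr(object, "lfc_min")
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$log2fc,
                               y = -log10(pmax(.data$p_adj, 1e-300)),
                               colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = c(-lfc, lfc), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::scale_colour_manual(values = c(up = "#2e7d32",
                                            down = "#d81b60",
                                            ns = "grey70")) +
    ggplot2::labs(x = "log2 fold change (short / full)",
                  y = "-log10 adjusted p", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Mean coverage profile around peak centers
#'
#' @param object A `ps_signal` object from [signal_matrix()].
#' @param ... Ignored.
#' @return A ggplot of the column-mean profile.
#' @export
autoplot.ps_signal <- function(object, ...) {
  df <- tibble(offset = object$bin_mid, signal = object$profile)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$offset, y = .data$signal)) +
    ggplot2::geom_line(linewidth = 0.8, colour = "#1565c0") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "distance from peak center (bp)",
                  y = "mean coverage") +
    ggplot2::theme_minimal()
}

#' Bar chart of Venn region sizes
#'
#' @param object A `ps_venn` tibble from [venn()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.ps_venn <- function(object, ...) {
  df <- tidy(object) %>%
    mutate(region = factor(.data$region, levels = .data$region))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region, y = .data$n)) +
    ggplot2::geom_col(fill = "#455a64") +
    ggplot2::labs(x = NULL, y = "members") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Localization profile bar chart
#'
#' @param profile A tibble from [localization_profile()].
#' @return A ggplot.
#' @export
plot_localization <- function(profile) {
  df <- profile %>%
    mutate(compartment = factor(.data$compartment,
                                levels = rev(.data$compartment)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$compartment)) +
    ggplot2::geom_col(fill = "#6a1b9a") +
    ggplot2::labs(x = "normalized annotation score", y = NULL) +
    ggplot2::theme_minimal()
}
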