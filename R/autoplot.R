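#' Plots of analysis results
#'
#' `autoplot()` methods return ggplot objects: a volcano plot for a DE
#' contrast, an entropy histogram for a specificity profile (bin width
#' 0.3 bits, so the first bar is the narrow-pattern stratum), a bar chart
#' of commonality counts, and a fold/q scatter for enrichment results.
#'
#' @param object An analysis result.
#' @param ... Unused.
#' @return A [ggplot2::ggplot] object.
#' @name coldatlas-autoplot
NULL

#' @rdname coldatlas-autoplot
#' @method autoplot cold_de
#' @export
autoplot.cold_de <- function(object, ...) {
  df <- tidy(object)
  df <- df[!is.na(df$pvalue), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc,
                                   y = -log10(pmax(.data$pvalue, 1e-300)),
                                   colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(down = "#4575b4", ns = "grey70",
                                            up = "#d73027")) +
    ggplot2::labs(
      title = sprintf("%s, %g h cold vs control", attr(object, "organ"),
                      attr(object, "duration_h")),
      x = "log2 fold change (cold / control)", y = "-log10 p", colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' @rdname coldatlas-autoplot
#' @param binwidth Histogram bin width in bits.
#' @method autoplot cold_specificity
#' @export
autoplot.cold_specificity <- function(object, binwidth = 0.3, ...) {
  df <- tidy(object)
  df <- df[!is.na(df$H), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$H)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "#74add1", colour = "white") +
    ggplot2::labs(x = "Shannon entropy H (bits)", y = "genes") +
    ggplot2::theme_minimal()
}

#' @rdname coldatlas-autoplot
#' @method autoplot cold_commonality
#' @export
autoplot.cold_commonality <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = factor(.data$k), y = .data$n_genes)) +
    ggplot2::geom_col(fill = "#74add1") +
    ggplot2::labs(x = "number of contrasts", y = "genes",
                  title = sprintf("%s-regulated genes shared by k contrasts",
                                  attr(object, "direction"))) +
    ggplot2::theme_minimal()
}

#' @rdname coldatlas-autoplot
#' @method autoplot cold_enrichment
#' @export
autoplot.cold_enrichment <- function(object, ...) {
  df <- tidy(object)
  df <- df[is.finite(df$enrichment), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$enrichment,
                                   y = -log10(pmax(.data$qvalue, 1e-300)),
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey70", `TRUE` = "#d73027")) +
    ggplot2::labs(x = "log2 %target(DE) / %target(non-DE)", y = "-log10 q",
                  colour = "q <= threshold") +
    ggplot2::theme_minimal()
}
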