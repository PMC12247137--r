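#' Plot a population mean delta-F/F0 time course
#'
#' Ribbon of mean plus/minus SEM over a neuron subset, with stimulus epochs
#' shaded — the standard population-response figure for activated neurons.
#'
#' @param object A `dff_tbl` from [compute_dff()].
#' @param neurons Optional neuron subset (default all).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dff_tbl <- function(object, neurons = NULL, ...) {
  pop <- population_mean_dff(object, neurons)
  epochs <- attr(object, "epochs")
  p <- ggplot2::ggplot(pop, ggplot2::aes(x = .data$time, y = .data$mean_dff))
  if (!is.null(epochs) && nrow(epochs) > 0) {
    p <- p + ggplot2::geom_rect(
      data = epochs, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$onset, xmax = .data$offset,
                   ymin = -Inf, ymax = Inf),
      fill = "grey85"
    )
  }
  p +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_dff - .data$sem_dff,
                                      ymax = .data$mean_dff + .data$sem_dff),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = "time (s)", y = expression(Delta * F / F[0] ~ "(%)")) +
    ggplot2::theme_minimal()
}

#' Volcano plot of a differential-expression table
#'
#' @param object A `deg_tbl` from [wilcoxon_de()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.deg_tbl <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$log2fc, y = -log10(.data$p),
                               color = .data$passes)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p", color = "passes") +
    ggplot2::theme_minimal()
}

#' Bar chart of a stimulus-overlap summary
#'
#' @param overlap One-row tibble from [summarize_overlap()].
#' @return A ggplot object.
#' @export
plot_overlap <- function(overlap) {
  df <- tibble(
    group = factor(
      c("both", paste0(overlap$stim_a, " only"), paste0(overlap$stim_b, " only")),
      levels = c("both", paste0(overlap$stim_a, " only"), paste0(overlap$stim_b, " only"))
    ),
    pct = c(overlap$pct_both, overlap$pct_only_a, overlap$pct_only_b)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f%%", .data$pct)),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "% of responding neurons") +
    ggplot2::theme_minimal()
}

#' Bar chart of per-marker positive fractions
#'
#' @param positivity_tbl Tibble from [positivity()].
#' @return A ggplot object.
#' @export
plot_marker_fractions <- function(positivity_tbl) {
  ggplot2::ggplot(positivity_tbl,
                  ggplot2::aes(x = stats::reorder(.data$gene, -.data$fraction),
                               y = 100 * .data$fraction)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(x = NULL, y = "% positive cells") +
    ggplot2::theme_minimal()
}

#' Bar chart of Venn combination counts
#'
#' Disjoint marker-combination counts from [marker_venn()], an upset-style
#' alternative to a drawn Venn diagram.
#'
#' @param venn_tbl Tibble from [marker_venn()].
#' @return A ggplot object.
#' @export
plot_venn_counts <- function(venn_tbl) {
  ggplot2::ggplot(venn_tbl,
                  ggplot2::aes(x = stats::reorder(.data$combination, -.data$n),
                               y = .data$n)) +
    ggplot2::geom_col(fill = "seagreen") +
    ggplot2::labs(x = NULL, y = "cells") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
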