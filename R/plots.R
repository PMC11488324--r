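#' Volcano plot of carrier-vs-WT differential peaks
#'
#' @param object An `mtsc_diff`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mtsc_diff <- function(object, ...) {
  d <- object$results
  s <- object$summary
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log2_fc,
                                  y = -log10(pmax(.data$q_value, 1e-300)),
                                  colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * log2(s$fc_threshold),
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(s$alpha), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2(fold change)", y = "-log10(Q value)",
                  colour = "significant") +
    ggplot2::theme_minimal()
}

#' Histogram of permutation-null significant-peak counts
#'
#' @param object An `mtsc_perm`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mtsc_perm <- function(object, ...) {
  ggplot2::ggplot(object$reps, ggplot2::aes(x = .data$n_significant)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "steelblue", colour = "white") +
    ggplot2::labs(x = "significant peaks per random split", y = "replicates") +
    ggplot2::theme_minimal()
}

#' Barnyard scatter of per-cell species counts
#'
#' @param object An `mtsc_barnyard`.
#' @param counts The per-cell count tibble the classification was run on.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mtsc_barnyard <- function(object, counts = NULL, ...) {
  d <- object$cells
  if (!is.null(counts)) {
    frag_cols <- grep("^n_frag_", names(counts), value = TRUE)
    d <- left_join(d, counts[, c("barcode", frag_cols)], by = "barcode")
    ggplot2::ggplot(d, ggplot2::aes(x = .data[[frag_cols[1]]],
                                    y = .data[[frag_cols[2]]],
                                    colour = .data$singlet)) +
      ggplot2::geom_point(alpha = 0.5, size = 0.8) +
      ggplot2::labs(x = frag_cols[1], y = frag_cols[2], colour = "singlet") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(d, ggplot2::aes(x = .data$major_fraction,
                                    fill = .data$singlet)) +
      ggplot2::geom_histogram(bins = 50) +
      ggplot2::labs(x = "major-species nuclear fraction", y = "cells") +
      ggplot2::theme_minimal()
  }
}

#' Boxplot of per-cell mtDNA content by cell type and group
#'
#' @param data Tibble with `cell_type`, a grouping column and
#'   `mito_content_pct`.
#' @param group Grouping column (default `age_group`).
#' @return A ggplot.
#' @export
plot_content_by_type <- function(data, group = "age_group") {
  ggplot2::ggplot(data, ggplot2::aes(x = .data$cell_type,
                                     y = .data$mito_content_pct,
                                     fill = .data[[group]])) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = NULL, y = "mtDNA content (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
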