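#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Volcano plot of a moderated contrast
#'
#' @param object A `moderated_contrast`.
#' @param q_max,lfc_min Highlighting thresholds (defaults: the predominance
#'   thresholds).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.moderated_contrast <- function(object, q_max = 5e-4, lfc_min = 1, ...) {
  df <- tidy(object)
  df$called <- df$q < q_max & abs(df$estimate) > lfc_min
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = -log10(.data$p),
                                   colour = .data$called)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(x = "log2 fold change", y = expression(-log[10]~p)) +
    ggplot2::theme_minimal()
}

#' Bar chart of the strongest enriched categories
#'
#' @param object An `enrichment_result`.
#' @param top Number of terms to show (by p-value).
#' @param ... Unused.
#' @export
autoplot.enrichment_result <- function(object, top = 20, ...) {
  df <- dplyr::slice_min(dplyr::filter(tidy(object), .data$enriched),
                         .data$p, n = top, with_ties = FALSE)
  df$label <- factor(df$label, levels = rev(df$label))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$neglog10p, y = .data$label)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = expression(-log[10]~p), y = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of an enrichment matrix
#'
#' Terms x gene-set tiles of `-log10 p`; non-enriched cells stay blank, the
#' layout used for category-enrichment overviews.
#'
#' @param object An `enrichment_matrix`.
#' @param ... Unused.
#' @export
autoplot.enrichment_matrix <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              cols = -c("term", "label"),
                              names_to = "set", values_to = "neglog10p")
  long$label <- factor(long$label, levels = rev(unique(long$label)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$set, y = .data$label,
                                     fill = .data$neglog10p)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_gradient(low = "lemonchiffon", high = "red3",
                                 na.value = "grey92",
                                 name = expression(-log[10]~p)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Replicate-QC bar chart
#'
#' Per-group replicate Pearson correlations with a 0.95 guide line.
#'
#' @param object A `replicate_qc` tibble.
#' @param ... Unused.
#' @export
autoplot.replicate_qc <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$pcc)) +
    ggplot2::geom_col(fill = "darkseagreen") +
    ggplot2::geom_hline(yintercept = 0.95, linetype = "dashed") +
    ggplot2::coord_cartesian(ylim = c(min(0.9, min(df$pcc)), 1)) +
    ggplot2::labs(x = NULL, y = "replicate PCC") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
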