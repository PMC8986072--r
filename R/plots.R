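#' Volcano plot of a DE result
#'
#' @param de A `de_result`.
#' @param label_top Number of top DEGs (by p value) to label.
#' @return A ggplot object.
#' @export
plot_volcano <- function(de, label_top = 0) {
  vt <- volcano_table(de)
  p <- ggplot2::ggplot(vt, ggplot2::aes(x = .data$log2fc, y = .data$neg_log10_p)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$is_deg), size = 0.8, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
      name = "DEG") +
    ggplot2::geom_vline(xintercept = c(-1, 1) * log2(attr(de, "fold_threshold")),
      linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p",
      title = attr(de, "contrast")$name) +
    ggplot2::theme_minimal()
  if (label_top > 0) {
    lab <- vt |> filter(.data$is_deg) |> arrange(dplyr::desc(.data$neg_log10_p)) |>
      head(label_top)
    p <- p + ggplot2::geom_text(data = lab,
      ggplot2::aes(label = .data$gene_id), size = 2.5, vjust = -0.6)
  }
  p
}

#' @export
autoplot.de_result <- function(object, ...) plot_volcano(object, ...)

#' Dot-and-box plot of composition scores by participant group
#'
#' @param scores A `composition_scores` tibble.
#' @param meta Sample metadata.
#' @param subsets Optional subset filter.
#' @return A ggplot object.
#' @export
plot_scores <- function(scores, meta, subsets = NULL) {
  df <- as_tibble(scores) |>
    left_join(select(meta, "sample_id", "group"), by = "sample_id")
  if (!is.null(subsets)) df <- filter(df, .data$subset %in% subsets)
  df$group <- factor(df$group, levels = SAMPLE_GROUPS)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$score,
    colour = .data$group)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, size = 0.8, alpha = 0.7) +
    ggplot2::facet_wrap(~subset, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "composition score (log2 units)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' @export
autoplot.composition_scores <- function(object, meta, ...) {
  plot_scores(object, meta, ...)
}

#' PCA scatter of sample coordinates
#'
#' @param embedding Output of [pca_embed()].
#' @param colour Metadata column to colour by (default `group` if present).
#' @return A ggplot object.
#' @export
plot_pca <- function(embedding, colour = "group") {
  co <- embedding$coordinates
  ve <- embedding$variance_explained
  aes <- if (colour %in% names(co)) {
    ggplot2::aes(x = .data$PC1, y = .data$PC2, colour = .data[[colour]])
  } else {
    ggplot2::aes(x = .data$PC1, y = .data$PC2)
  }
  ggplot2::ggplot(co, aes) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * ve[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * ve[2])) +
    ggplot2::theme_minimal()
}

#' Bubble plot of top enrichment results
#'
#' @param results An `enrichment_result`.
#' @param k How many top sets to show.
#' @return A ggplot object.
#' @export
plot_enrichment <- function(results, k = 10) {
  df <- top_k(results, k) |>
    mutate(set_name = factor(.data$set_name, levels = rev(.data$set_name)))
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(.data$fdr_q), y = .data$set_name,
    size = .data$overlap)) +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::labs(x = "-log10 FDR q", y = NULL, size = "overlap") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.enrichment_result <- function(object, ...) plot_enrichment(object, ...)

#' Concordance scatter of fold changes between two contrasts
#'
#' @param deA,deB `de_result` objects.
#' @param genes Gene IDs to plot.
#' @return A ggplot object faceted by direction in `deA`.
#' @export
plot_concordance <- function(deA, deB, genes) {
  fa <- deA$log2fc[match(genes, deA$gene_id)]
  fb <- deB$log2fc[match(genes, deB$gene_id)]
  df <- tibble(gene_id = genes, fc_a = fa, fc_b = fb,
    direction = ifelse(fa >= 0, "up", "down"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fc_a, y = .data$fc_b)) +
    ggplot2::geom_point(size = 1, alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
      colour = "firebrick", linewidth = 0.6) +
    ggplot2::facet_wrap(~direction, scales = "free") +
    ggplot2::labs(x = "log2 FC (contrast A)", y = "log2 FC (contrast B)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
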