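#' Plot sample PCA
#'
#' @param object An `expression_pca`.
#' @param sheet Optional sample sheet to colour points by tissue and shape
#'   by genotype.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.expression_pca <- function(object, sheet = NULL, ...) {
  df <- tidy(object)
  ve <- glance(object)$variance_explained
  if (!is.null(sheet)) {
    df <- left_join(df, sample_sheet(sheet), by = "sample_id")
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2,
                                          colour = .data$tissue,
                                          shape = .data$genotype))
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2))
  }
  p + ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * ve[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * ve[2])
    ) +
    ggplot2::theme_minimal()
}

#' Plot cis/trans category proportions per tissue
#'
#' @param results Classified tibble from [classify_hse()].
#' @return A ggplot object.
#' @export
plot_hse_proportions <- function(results) {
  df <- hse_summary(results)$by_tissue
  ggplot2::ggplot(df, ggplot2::aes(.data$tissue, .data$proportion,
                                   fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_brewer(palette = "Set2") +
    ggplot2::labs(x = NULL, y = "proportion of classified pairs") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot homoeolog-bias trajectory counts per tissue
#'
#' @param heb_groups Tibble with `tissue` and `group` per pair.
#' @return A ggplot object.
#' @export
plot_heb_groups <- function(heb_groups) {
  df <- heb_groups %>% count(.data$tissue, .data$group)
  ggplot2::ggplot(df, ggplot2::aes(.data$tissue, .data$n,
                                   fill = .data$group)) +
    ggplot2::geom_col(position = "fill") +
    ggplot2::labs(x = NULL, y = "fraction of pairs") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot module eigengene profiles
#'
#' @param network A `coexpression_network`.
#' @return A ggplot object.
#' @export
plot_module_eigengenes <- function(network) {
  eig <- network$eigengenes
  df <- as_tibble(eig) %>%
    mutate(sample = rownames(eig)) %>%
    tidyr::pivot_longer(-"sample", names_to = "module",
                        values_to = "eigengene")
  ggplot2::ggplot(df, ggplot2::aes(.data$sample, .data$eigengene,
                                   group = .data$module,
                                   colour = .data$module)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
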