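#' Genotype matrix heatmap
#'
#' Tile plot of REF/LOSS/GAIN status per accession and gene, in the colour
#' convention used throughout CNV surveys (losses blue, gains red).
#'
#' @param object A `cn_genotypes` object.
#' @param genes Optional character vector restricting/ordering the genes.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cn_genotypes <- function(object, genes = NULL, ...) {
  calls <- object$calls
  if (!is.null(genes)) {
    calls <- calls[calls$gene %in% genes, ]
    calls$gene <- factor(calls$gene, levels = genes)
  }
  ggplot2::ggplot(calls, ggplot2::aes(x = .data$gene, y = .data$accession,
                                      fill = .data$status)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(
      REF = "grey85", LOSS = "#2166ac", GAIN = "#b2182b",
      CONFLICT = "#fdb863"
    ), na.value = "white") +
    ggplot2::labs(x = NULL, y = NULL, fill = "status") +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5, hjust = 1),
      axis.text.y = ggplot2::element_blank()
    )
}

#' Cluster pattern frequency bar chart
#'
#' @param census An `mgc_census` object.
#' @param cluster Optional cluster name to restrict to.
#' @return A ggplot object.
#' @export
plot_pattern_counts <- function(census, cluster = NULL) {
  counts <- census$pattern_counts
  if (!is.null(cluster)) counts <- counts[counts$cluster == cluster, ]
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$pattern, y = .data$n)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::facet_wrap(~cluster, scales = "free_x") +
    ggplot2::labs(x = "CNV pattern", y = "accessions") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Phenotype scan p-value plot
#'
#' Minus-log10 p per scanned variable, with the significance threshold drawn
#' as a dashed line.
#'
#' @param object A `phenotype_scan` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phenotype_scan <- function(object, ...) {
  alpha <- attr(object, "alpha") %||% 0.05
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$variable, y = -log10(.data$p_value),
                                   colour = .data$significant)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#b2182b", `FALSE` = "grey50")) +
    ggplot2::labs(x = NULL, y = expression(-log[10](italic(p))), colour = "significant") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Het-SNP count separation by PAV group
#'
#' Jittered per-accession heterozygous-site counts at a locus, grouped by
#' presence/absence classification — the visual form of the het-excess
#' signal for cryptic duplication.
#'
#' @param profiles Tibble from [count_het_snps()].
#' @param pav Tibble from [classify_pav_groups()].
#' @param locus Gene id to plot.
#' @return A ggplot object.
#' @export
plot_het_separation <- function(profiles, pav, locus = "CYP705A2") {
  df <- profiles %>%
    filter(.data$gene == locus) %>%
    inner_join(pav[, c("accession", "group")], by = "accession")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$n_het)) +
    ggplot2::geom_jitter(width = 0.2, height = 0, alpha = 0.4, colour = "#2166ac") +
    ggplot2::labs(x = "presence/absence group", y = sprintf("het sites at %s", locus)) +
    ggplot2::theme_minimal()
}
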