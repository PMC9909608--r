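#' Find terpene-synthase / cytochrome P450 gene pairs by proximity
#'
#' A CYP is paired with a TS when the gap between their gene borders is at
#' most `window` bp (30 kb by default, the published pairing rule).
#' Overlapping genes have distance 0; distances are strand-ignored and
#' border-to-border; cross-chromosome pairs are never emitted; one CYP may
#' pair with several TSs and vice versa.
#'
#' @param ts_genes,cyp_genes Gene tibbles (`gene_id`, `chrom`, `start`,
#'   `end`); pseudogenes are expected to have been excluded by the caller.
#' @param window Maximum border-to-border gap in bp (inclusive).
#' @return A tibble: `ts`, `cyp`, `distance`.
#' @export
find_ts_cyp_pairs <- function(ts_genes, cyp_genes, window = 30000) {
  validate_intervals(ts_genes, "find_ts_cyp_pairs(ts_genes)")
  validate_intervals(cyp_genes, "find_ts_cyp_pairs(cyp_genes)")
  grid <- tidyr::expand_grid(
    ts_i = seq_len(nrow(ts_genes)),
    cyp_i = seq_len(nrow(cyp_genes))
  )
  ts <- ts_genes[grid$ts_i, ]
  cyp <- cyp_genes[grid$cyp_i, ]
  gap <- pmax(0, pmax(ts$start, cyp$start) - pmin(ts$end, cyp$end))
  keep <- ts$chrom == cyp$chrom & gap <= window
  tibble(
    ts = ts$gene_id[keep],
    cyp = cyp$gene_id[keep],
    distance = gap[keep]
  ) %>%
    arrange(.data$ts, .data$cyp)
}

#' Classify per-gene CNV variability
#'
#' A gene is `variable` when gains plus losses occur in at least `min_frac`
#' of the genotyped (non-missing, non-conflict) accessions — the published
#' "at least 1% of accessions" rule with an inclusive boundary. Genes with no
#' genotyped accession are left unclassified (`NA`).
#'
#' @param genotypes A `cn_genotypes` object or long call tibble.
#' @param min_frac Inclusive variability threshold (default 0.01).
#' @return A tibble: `gene`, `n_genotyped`, `n_variant`, `variant_frac`,
#'   `variability` (`"variable"`/`"invariable"`/`NA`).
#' @export
classify_variability <- function(genotypes, min_frac = 0.01) {
  calls <- if (inherits(genotypes, "cn_genotypes")) genotypes$calls else genotypes
  calls %>%
    group_by(.data$gene) %>%
    summarise(
      n_genotyped = sum(.data$status %in% c("REF", "LOSS", "GAIN")),
      n_variant = sum(.data$status %in% c("LOSS", "GAIN")),
      .groups = "drop"
    ) %>%
    mutate(
      variant_frac = dplyr::if_else(.data$n_genotyped > 0,
                                    .data$n_variant / .data$n_genotyped,
                                    NA_real_),
      variability = dplyr::case_when(
        .data$n_genotyped == 0 ~ NA_character_,
        .data$variant_frac >= min_frac ~ "variable",
        TRUE ~ "invariable"
      )
    )
}

#' Compare CNV variability of paired versus nonpaired genes
#'
#' For each gene family (TS and CYP separately), tests whether genes
#' occurring in TS-CYP pairs carry CNVs in a larger fraction of accessions
#' than nonpaired genes, using the two-sided Wilcoxon rank-sum test with
#' continuity correction on per-gene variant-carrier fractions (or,
#' optionally, on the binary variable/invariable labels).
#'
#' @param variability Tibble from [classify_variability()] covering all TS
#'   and CYP genes.
#' @param pairs Pair tibble from [find_ts_cyp_pairs()].
#' @param ts_ids,cyp_ids Character vectors of all TS and all CYP gene ids.
#' @param use_binary Use 0/1 variability labels instead of fractions.
#' @return An object of class `paired_vs_nonpaired`: tibble with one row per
#'   family (`family`, `n_paired`, `n_nonpaired`, `median_paired`,
#'   `median_nonpaired`, `statistic`, `p_value`).
#' @export
compare_paired_vs_nonpaired <- function(variability, pairs, ts_ids, cyp_ids,
                                        use_binary = FALSE) {
  paired_genes <- unique(c(pairs$ts, pairs$cyp))
  one_family <- function(family, ids) {
    v <- variability[variability$gene %in% ids & !is.na(variability$variant_frac), ]
    val <- if (use_binary) as.numeric(v$variability == "variable") else v$variant_frac
    is_paired <- v$gene %in% paired_genes
    if (sum(is_paired) < 2 || sum(!is_paired) < 2) {
      warn(sprintf("compare_paired_vs_nonpaired: degenerate groups for %s; skipped", family))
      return(tibble(
        family = family, n_paired = sum(is_paired), n_nonpaired = sum(!is_paired),
        median_paired = NA_real_, median_nonpaired = NA_real_,
        statistic = NA_real_, p_value = NA_real_
      ))
    }
    wt <- wilcoxon_ct(val[is_paired], val[!is_paired])
    tibble(
      family = family,
      n_paired = sum(is_paired),
      n_nonpaired = sum(!is_paired),
      median_paired = median(val[is_paired]),
      median_nonpaired = median(val[!is_paired]),
      statistic = wt$statistic,
      p_value = wt$p_value
    )
  }
  out <- bind_rows(one_family("TS", ts_ids), one_family("CYP", cyp_ids))
  class(out) <- c("paired_vs_nonpaired", class(out))
  out
}
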