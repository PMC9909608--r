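#' Tidy genotype integration results
#'
#' @param x A `cn_genotypes` object.
#' @param ... Unused.
#' @return The long call tibble (`accession`, `gene`, `status`,
#'   `n_platforms`, `platforms`).
#' @export
tidy.cn_genotypes <- function(x, ...) x$calls

#' One-row summary of genotype integration
#'
#' @param x A `cn_genotypes` object.
#' @param ... Unused.
#' @return A tibble: cell counts by status, multi-platform cell count and
#'   concordance percentage.
#' @export
glance.cn_genotypes <- function(x, ...) {
  tibble(
    n_cells = nrow(x$calls),
    n_loss = sum(x$calls$status == "LOSS"),
    n_gain = sum(x$calls$status == "GAIN"),
    n_conflict = sum(x$calls$status == "CONFLICT"),
    n_multi = x$concordance$n_multi,
    concordance_pct = concordance_fraction(x)
  )
}

#' Tidy a population census
#'
#' @param x An `mgc_census` object.
#' @param ... Unused.
#' @return The per-cluster pattern count tibble.
#' @export
tidy.mgc_census <- function(x, ...) x$pattern_counts

#' One-row summary of a population census
#'
#' @param x An `mgc_census` object.
#' @param ... Unused.
#' @export
glance.mgc_census <- function(x, ...) {
  tibble(
    n_accessions = x$n_accessions,
    n_complete = x$n_complete,
    n_incomplete = x$n_incomplete,
    n_variable = x$n_variable,
    no_cnv_pct = x$no_cnv_pct,
    n_affected_genes = x$n_affected_genes
  )
}

#' Tidy a Wilcoxon rank-sum result
#'
#' @param x A `wilcoxon_ct` object.
#' @param ... Unused.
#' @export
tidy.wilcoxon_ct <- function(x, ...) {
  tibble(
    statistic = x$statistic, p_value = x$p_value,
    n_x = x$n_x, n_y = x$n_y,
    method = if (x$exact) "exact" else "normal approximation"
  )
}

#' Tidy Kruskal-Wallis + Dunn results
#'
#' @param x A `kw_dunn` object.
#' @param ... Unused.
#' @return The pairwise comparison tibble (`group1`, `group2`, `z`, `p_raw`,
#'   `p_adj`).
#' @export
tidy.kw_dunn <- function(x, ...) x$pairwise

#' One-row omnibus summary of a Kruskal-Wallis + Dunn result
#'
#' @param x A `kw_dunn` object.
#' @param ... Unused.
#' @export
glance.kw_dunn <- function(x, ...) x$omnibus
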