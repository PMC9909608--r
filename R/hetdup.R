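genotype_class <- function(gt) {
  gt <- gsub("|", "/", gt, fixed = TRUE)
  dplyr::case_when(
    gt %in% c("./.", ".") ~ "missing",
    gt == "0/0" ~ "homref",
    gt %in% c("0/1", "1/0") ~ "het",
    gt == "1/1" ~ "homalt",
    TRUE ~ "other"
  )
}

#' Count heterozygous SNPs per accession at a gene locus
#'
#' Arabidopsis accessions are naturally inbred, so a genuine heterozygous call
#' is rare; an excess of heterozygous calls at a locus is the signature of a
#' divergent duplicate elsewhere in the genome whose reads cross-map onto the
#' reference gene model. This function filters a SNP table to biallelic
#' single-nucleotide sites lying in the exons of each supplied gene
#' (multi-allelic records and indels are excluded), optionally applies a
#' minor-allele-frequency floor computed across non-missing calls, and counts
#' per accession the heterozygous and homozygous-alternate sites.
#'
#' @param snps Long SNP tibble from [read_snp_genotypes()] (columns `chrom`,
#'   `pos` (0-based), `ref`, `alt`, `accession`, `gt`).
#' @param genes Gene tibble with an `exons` list-column ([mgc_annotation()]
#'   layout); counts are produced for every gene in it.
#' @param accessions Optional character vector restricting/ordering the
#'   accessions; accessions absent from the SNP table are an error.
#' @param maf_min Optional minimum minor-allele frequency in `(0, 1)`.
#' @return A tibble: `accession`, `gene`, `n_het`, `n_homalt`, `n_sites`.
#' @export
count_het_snps <- function(snps, genes, accessions = NULL, maf_min = NULL) {
  stopifnot(all(c("chrom", "pos", "ref", "alt", "accession", "gt") %in% names(snps)))
  if (is.null(accessions)) {
    accessions <- sort(unique(snps$accession))
  } else {
    missing_acc <- setdiff(accessions, unique(snps$accession))
    if (length(missing_acc) > 0) {
      abort(sprintf("count_het_snps: accession(s) absent from SNP table: %s",
                    paste(head(missing_acc, 5), collapse = ", ")))
    }
  }

  biallelic <- !grepl(",", snps$alt, fixed = TRUE) &
    nchar(snps$ref) == 1 & nchar(snps$alt) == 1 & snps$alt != "."

  out <- purrr::map_dfr(seq_len(nrow(genes)), function(i) {
    ex <- genes$exons[[i]]
    if (is.null(ex) || nrow(ex) == 0) {
      abort(sprintf("count_het_snps: gene %s has no exons", genes$gene_id[i]))
    }
    in_exon <- rep(FALSE, nrow(snps))
    for (j in seq_len(nrow(ex))) {
      in_exon <- in_exon |
        (snps$chrom == ex$chrom[j] & snps$pos >= ex$start[j] & snps$pos < ex$end[j])
    }
    sub <- snps[biallelic & in_exon, , drop = FALSE]
    sub$class <- genotype_class(sub$gt)

    if (!is.null(maf_min) && nrow(sub) > 0) {
      site_freq <- sub %>%
        group_by(.data$chrom, .data$pos) %>%
        summarise(
          af = {
            cls <- .data$class[.data$class != "missing"]
            if (length(cls) == 0) 0 else {
              (sum(cls == "het") + 2 * sum(cls == "homalt")) / (2 * length(cls))
            }
          },
          .groups = "drop"
        )
      keep <- site_freq[pmin(site_freq$af, 1 - site_freq$af) >= maf_min, ]
      sub <- semi_join(sub, keep, by = c("chrom", "pos"))
    }

    n_sites <- nrow(distinct(sub, .data$chrom, .data$pos))
    counts <- sub %>%
      filter(.data$accession %in% accessions) %>%
      group_by(.data$accession) %>%
      summarise(
        n_het = sum(.data$class == "het"),
        n_homalt = sum(.data$class == "homalt"),
        .groups = "drop"
      )
    tibble(accession = accessions) %>%
      left_join(counts, by = "accession") %>%
      mutate(
        gene = genes$gene_id[i],
        n_het = dplyr::coalesce(.data$n_het, 0L),
        n_homalt = dplyr::coalesce(.data$n_homalt, 0L),
        n_sites = n_sites
      ) %>%
      select("accession", "gene", "n_het", "n_homalt", "n_sites")
  })
  out
}

#' Classify presence/absence groups for a reference gene pair and its cryptic
#' duplicate pair
#'
#' Combines read-depth evidence at the reference pair (e.g. CYP705A2 and
#' BARS1) and a linked marker gene deleted together with it (the CYP705A3
#' role) with the heterozygous/homozygous-alternate SNP profiles at both loci:
#'
#' * reference pair present (marker and first locus clearly covered) and
#'   het-SNP excess at both loci -> `PP-PP` (both pairs present);
#' * reference pair present without het excess -> `PP-AA`;
#' * reference region absent (marker depth ~ 0) but intermediate cross-mapped
#'   depth and homozygous-alternate SNPs at both loci -> `AA-PP` (only the
#'   divergent duplicate pair present);
#' * depth ~ 0 at all three loci and no SNP evidence -> `AA-AA`;
#' * anything else -> `INCONCLUSIVE`.
#'
#' @param profiles Het-SNP profile tibble from [count_het_snps()] covering the
#'   two pair loci.
#' @param rd Wide RD measurement tibble (first column `accession`) covering
#'   the pair loci and the marker gene.
#' @param pair Character vector of the two reference-pair gene ids.
#' @param marker Gene id of the linked marker gene.
#' @param h_min Minimum number of het (or hom-alt) sites that counts as
#'   excess; the default 3 suppresses isolated genotyping errors while
#'   catching divergence well below 1% over a 1.5-kb exonic target.
#' @param rd_absent Depth at or below which a locus is considered absent.
#' @param rd_low Depth above which the first pair locus is considered
#'   clearly present.
#' @return A tibble: `accession`, `group` (one of `PP-AA`, `PP-PP`, `AA-PP`,
#'   `AA-AA`, `INCONCLUSIVE`), plus the evidence columns used.
#' @export
classify_pav_groups <- function(profiles, rd,
                                pair = c("CYP705A2", "BARS1"),
                                marker = "CYP705A3",
                                h_min = 3, rd_absent = 0.5, rd_low = 1.0) {
  stopifnot(length(pair) == 2)
  need <- c(pair, marker)
  missing_genes <- setdiff(need, names(rd))
  if (length(missing_genes) > 0) {
    abort(sprintf("classify_pav_groups: RD table lacks gene(s): %s",
                  paste(missing_genes, collapse = ", ")))
  }
  prof <- profiles %>%
    filter(.data$gene %in% pair) %>%
    tidyr::pivot_wider(
      id_cols = "accession",
      names_from = "gene",
      values_from = c("n_het", "n_homalt")
    )
  ev <- rd %>%
    select("accession", all_of(need)) %>%
    rename(rd_1 = all_of(pair[1]), rd_2 = all_of(pair[2]),
           rd_marker = all_of(marker)) %>%
    inner_join(prof, by = "accession") %>%
    rename(
      het_1 = all_of(paste0("n_het_", pair[1])),
      het_2 = all_of(paste0("n_het_", pair[2])),
      homalt_1 = all_of(paste0("n_homalt_", pair[1])),
      homalt_2 = all_of(paste0("n_homalt_", pair[2]))
    )

  ev$group <- dplyr::case_when(
    is.na(ev$rd_1) | is.na(ev$rd_2) | is.na(ev$rd_marker) ~ "INCONCLUSIVE",
    # reference region present: marker covered and locus 1 clearly present
    ev$rd_marker > rd_absent & ev$rd_1 > rd_low &
      ev$het_1 >= h_min & ev$het_2 >= h_min ~ "PP-PP",
    ev$rd_marker > rd_absent & ev$rd_1 > rd_low &
      ev$het_1 < h_min & ev$het_2 < h_min ~ "PP-AA",
    # reference region absent, cross-mapping from the divergent duplicates
    ev$rd_marker <= rd_absent & ev$rd_1 > rd_absent &
      ev$homalt_1 >= h_min & ev$homalt_2 >= h_min &
      ev$het_1 < h_min & ev$het_2 < h_min ~ "AA-PP",
    # nothing anywhere
    ev$rd_marker <= rd_absent & ev$rd_1 <= rd_absent & ev$rd_2 <= rd_absent &
      ev$het_1 + ev$het_2 + ev$homalt_1 + ev$homalt_2 < h_min ~ "AA-AA",
    TRUE ~ "INCONCLUSIVE"
  )
  ev %>%
    select("accession", "group", "rd_1", "rd_2", "rd_marker",
           "het_1", "het_2", "homalt_1", "homalt_2")
}

#' Pearson correlation of het-site counts between two loci
#'
#' The cohort-wide correlation of heterozygous-SNP counts between two
#' paralogous loci: when both duplicates travel together on one insertion,
#' the same accessions show het excess at both loci and the correlation is
#' high.
#'
#' @param profiles Profile tibble from [count_het_snps()].
#' @param loci Character vector of the two gene ids.
#' @return Pearson r, or `NA` (with a warning) when either locus has zero
#'   variance or fewer than 3 complete pairs.
#' @export
locus_het_correlation <- function(profiles, loci = c("CYP705A2", "BARS1")) {
  stopifnot(length(loci) == 2)
  wide <- profiles %>%
    filter(.data$gene %in% loci) %>%
    tidyr::pivot_wider(id_cols = "accession", names_from = "gene",
                       values_from = "n_het")
  x <- wide[[loci[1]]]
  y <- wide[[loci[2]]]
  ok <- stats::complete.cases(x, y)
  if (sum(ok) < 3) {
    warn("locus_het_correlation: fewer than 3 complete pairs")
    return(NA_real_)
  }
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
    warn("locus_het_correlation: zero variance at a locus")
    return(NA_real_)
  }
  stats::cor(x[ok], y[ok], method = "pearson")
}
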