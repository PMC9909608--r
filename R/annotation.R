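#' Synthetic reference annotation of the four metabolic gene clusters
#'
#' Builds the gene models used throughout the package: the member, intervening
#' and noncoding genes of the thalianol, marneral, tirucalladienol and
#' arabidiol/baruol clusters, each with strand and exon structure. The gene
#' identifiers and the order of genes follow the published organisation of the
#' Arabidopsis clusters; the coordinates are synthetic stand-ins with realistic
#' gene sizes and spacing (no computation in the package depends on the real
#' genome positions, only on relative layout).
#'
#' @return A tibble with one row per gene: `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand`, `category` (one of `TS`, `CYP`,
#'   `acyltransferase`, `other`, `noncoding`, `intervening`), `cluster`,
#'   `role` (`member`, `intervening` or `noncoding`), and a list-column
#'   `exons` of per-gene exon tibbles (`chrom`, `start`, `end`).
#' @export
mgc_annotation <- function() {
  lay <- function(cluster, chrom, origin, ids, categories, roles,
                  size = 3000, gap = 3000) {
    n <- length(ids)
    starts <- origin + (seq_len(n) - 1) * (size + gap)
    tibble(
      gene_id = ids,
      chrom = chrom,
      start = starts,
      end = starts + size,
      strand = rep(c("+", "-"), length.out = n),
      category = categories,
      cluster = cluster,
      role = roles
    )
  }

  thalianol <- lay(
    "thalianol", "chr5", 19230000,
    ids = c(
      "AT5G47950", "RABA4C", "AT5G47970", "AT5G47980",
      "AT5G07035", "CYP705A5", "CYP708A2", "THAS1"
    ),
    categories = c(
      "acyltransferase", "intervening", "intervening", "acyltransferase",
      "noncoding", "CYP", "CYP", "TS"
    ),
    roles = c(
      "member", "intervening", "intervening", "member",
      "noncoding", "member", "member", "member"
    )
  )
  marneral <- lay(
    "marneral", "chr5", 2000000,
    ids = c(
      "CYP705A12", "CYP71A16", "AT5G00580", "AT5G06325",
      "AT5G06335", "MRN1"
    ),
    categories = c("CYP", "CYP", "noncoding", "noncoding", "noncoding", "TS"),
    roles = c("member", "member", "noncoding", "noncoding", "noncoding", "member")
  )
  tirucalladienol <- lay(
    "tirucalladienol", "chr5", 14000000,
    ids = c(
      "CCB3", "SCPL1", "AT5G36125", "CYP716A1", "HCF109",
      "AT5G36130", "CYP716A2", "PEN3", "AT5G36160"
    ),
    categories = c(
      "intervening", "acyltransferase", "intervening", "CYP", "intervening",
      "other", "CYP", "TS", "intervening"
    ),
    roles = c(
      "intervening", "member", "intervening", "member", "intervening",
      "member", "member", "member", "intervening"
    ),
    size = 2800, gap = 2400
  )
  arabidiol <- lay(
    "arabidiol_baruol", "chr4", 8500000,
    ids = c(
      "CYP705A1", "PEN1", "CYP702A2", "CYP702A3", "CYP705A2",
      "CYP705A3", "BARS1", "CYP705A4", "CSLB06", "CYP702A5",
      "CYP702A6", "AT4G15390", "BIA1"
    ),
    categories = c(
      "CYP", "TS", "CYP", "CYP", "CYP",
      "CYP", "TS", "CYP", "intervening", "CYP",
      "CYP", "acyltransferase", "acyltransferase"
    ),
    roles = c(
      "member", "member", "member", "member", "member",
      "member", "member", "member", "intervening", "member",
      "member", "member", "member"
    ),
    size = 3000, gap = 3400
  )

  genes <- bind_rows(thalianol, marneral, tirucalladienol, arabidiol)
  genes$exons <- purrr::pmap(
    list(genes$chrom, genes$start, genes$end, genes$category),
    function(chrom, gs, ge, category) {
      if (category == "noncoding") {
        return(tibble(chrom = chrom, start = gs, end = ge))
      }
      # two exons: 900 bp and 1200 bp, within the gene body
      tibble(
        chrom = chrom,
        start = c(gs + 100, gs + 1400),
        end = c(gs + 1000, gs + 2600)
      )
    }
  )
  genes
}

#' Cluster definitions derived from an annotation
#'
#' One row per metabolic gene cluster, with the ordered member genes (the order
#' used by pattern classification), the intervening genes, and the genomic
#' span. Member order for the thalianol cluster is the order used to name the
#' published CNV variants: AT5G47980, CYP705A5, CYP708A2, THAS1, AT5G47950.
#'
#' @param annotation Gene tibble from [mgc_annotation()] (or one with the same
#'   columns).
#' @return A tibble: `cluster`, `chrom`, `start`, `end`, list-columns
#'   `members` and `intervening`.
#' @export
cluster_definitions <- function(annotation) {
  member_order <- list(
    thalianol = c("AT5G47980", "CYP705A5", "CYP708A2", "THAS1", "AT5G47950"),
    marneral = c("MRN1", "CYP71A16", "CYP705A12"),
    tirucalladienol = c("PEN3", "SCPL1", "CYP716A1", "AT5G36130", "CYP716A2"),
    arabidiol_baruol = c(
      "CYP705A1", "PEN1", "CYP702A2", "CYP702A3", "CYP705A2",
      "CYP705A3", "BARS1", "CYP705A4", "CYP702A5", "CYP702A6",
      "AT4G15390", "BIA1"
    )
  )
  annotation %>%
    filter(!is.na(.data$cluster)) %>%
    group_by(.data$cluster, .data$chrom) %>%
    summarise(
      start = min(.data$start),
      end = max(.data$end),
      members = list(intersect(
        member_order[[first(.data$cluster)]],
        .data$gene_id[.data$role == "member"]
      )),
      intervening = list(.data$gene_id[.data$role == "intervening"]),
      .groups = "drop"
    ) %>%
    arrange(match(.data$cluster, names(member_order)))
}

#' Default CNV-region catalog over the synthetic clusters
#'
#' A catalog of common copy-number-variable regions laid out to mirror the
#' published structure of CNV accumulation over the four clusters: the
#' thalianol cluster is entirely contained in one large variant; the
#' tirucalladienol variable region occupies one end of the cluster; the
#' arabidiol/baruol cluster has three distinct variable regions separated by
#' invariable segments; the marneral variants are intergenic only.
#'
#' @param clusters Cluster tibble from [cluster_definitions()].
#' @return An interval tibble (`chrom`, `start`, `end`, `name`) suitable for
#'   [cluster_cnv_coverage()] and for writing as BED.
#' @export
default_cnv_catalog <- function(clusters) {
  cl <- function(name) clusters[clusters$cluster == name, ]
  th <- cl("thalianol")
  ti <- cl("tirucalladienol")
  ab <- cl("arabidiol_baruol")
  mr <- cl("marneral")

  # one very large variant spans the whole thalianol cluster, plus smaller
  # internal variants matching the deletion footprints
  th_regions <- tibble(
    chrom = th$chrom,
    start = c(th$start - 100000, th$start + 9000, th$end - 22000),
    end = c(th$end + 100000, th$start + 21000, th$end - 2000),
    name = c("CNV_large_thalianol", "CNV_th_1", "CNV_th_2")
  )
  ti_len <- ti$end - ti$start
  ti_regions <- tibble(
    chrom = ti$chrom,
    start = ti$start + ti_len - round(0.796 * ti_len),
    end = ti$end,
    name = "CNV_ti_1"
  )
  ab_len <- ab$end - ab$start
  # three variable regions; third sized so the union is 53.1% of the span
  ab_r1 <- c(ab$start + 12800, ab$start + 25000)
  ab_r2 <- c(ab$start + 25600, ab$start + 44600)
  ab_target <- round(0.531 * ab_len)
  ab_r3_len <- ab_target - (ab_r1[2] - ab_r1[1]) - (ab_r2[2] - ab_r2[1])
  ab_r3 <- c(ab$start + 57600, ab$start + 57600 + ab_r3_len)
  ab_regions <- tibble(
    chrom = ab$chrom,
    start = c(ab_r1[1], ab_r2[1], ab_r3[1]),
    end = c(ab_r1[2], ab_r2[2], ab_r3[2]),
    name = c("CNV_ab_1", "CNV_ab_2", "CNV_ab_3")
  )
  mr_len <- mr$end - mr$start
  # intergenic variants only: two gaps between gene bodies
  mr_target <- round(0.528 * mr_len)
  mr_regions <- tibble(
    chrom = mr$chrom,
    start = c(mr$start + 3000, mr$start + 15000),
    end = c(mr$start + 9000, mr$start + 15000 + (mr_target - 6000)),
    name = c("CNV_mr_1", "CNV_mr_2")
  )
  bind_rows(th_regions, ti_regions, ab_regions, mr_regions)
}

#' Built-in named CNV pattern definitions
#'
#' Reads the editable pattern table shipped with the package, defining the
#' five named thalianol-cluster variants (A-E) as required member-gene
#' statuses: A = loss of AT5G47980 + CYP705A5 combined with loss of THAS1
#' (CYP708A2 retained); B = loss of AT5G47980 + CYP705A5 + CYP708A2;
#' C = loss of CYP708A2 alone; D = loss of CYP705A5 + CYP708A2 + THAS1;
#' E = duplication of AT5G47980.
#'
#' @param path Optional path to an alternative pattern table (TSV with columns
#'   `cluster`, `label`, `gene`, `status`).
#' @return A tibble with columns `cluster`, `label`, `gene`, `status`.
#' @export
pattern_definitions <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "thalianol_patterns.tsv", package = "mgcnv")
  }
  defs <- readr::read_tsv(path, col_types = "cccc", progress = FALSE)
  stopifnot(all(c("cluster", "label", "gene", "status") %in% names(defs)))
  defs
}
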