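#' Percent of each cluster span covered by CNV regions
#'
#' @param clusters Cluster tibble from [cluster_definitions()].
#' @param cnv_regions Interval tibble of CNV regions (e.g. from [read_bed()]).
#' @return A tibble: `cluster`, `coverage_pct`.
#' @export
cluster_cnv_coverage <- function(clusters, cnv_regions) {
  tibble(
    cluster = clusters$cluster,
    coverage_pct = purrr::map_dbl(seq_len(nrow(clusters)), function(i) {
      100 * union_coverage(clusters[i, c("chrom", "start", "end")], cnv_regions)
    })
  )
}

# status vector -> label, given this cluster's definitions
label_status_vector <- function(statuses, members, defs_cluster) {
  if (any(is.na(statuses))) {
    return(NA_character_)
  }
  if (any(statuses == "CONFLICT")) {
    return("UNRESOLVED")
  }
  if (all(statuses == "REF")) {
    return("REF")
  }
  if (nrow(defs_cluster) > 0) {
    for (lab in unique(defs_cluster$label)) {
      want <- defs_cluster[defs_cluster$label == lab, ]
      want_status <- setNames(want$status, want$gene)[members]
      if (all(statuses == want_status)) {
        return(lab)
      }
    }
  }
  # unnamed vector: canonical string over the non-REF members
  nz <- statuses != "REF"
  paste(paste0(members[nz], ":", statuses[nz]), collapse = "+")
}

#' Classify per-accession cluster CNV patterns
#'
#' For each accession and cluster, assembles the member-gene status vector (in
#' the cluster's canonical member order) and labels it: a named variant when
#' it exactly matches a definition from [pattern_definitions()] (the five
#' thalianol variants A-E by default), `"REF"` when all members are REF, an
#' `"UNRESOLVED"` label when any member call is CONFLICT, `NA` when any member
#' is ungenotyped, and otherwise a canonical `gene:STATUS+...` string so that
#' previously undescribed variants are reported rather than forced into the
#' nearest named one.
#'
#' @param genotypes A `cn_genotypes` object or a long call tibble
#'   (`accession`, `gene`, `status`).
#' @param clusters Cluster tibble from [cluster_definitions()].
#' @param defs Pattern definition tibble; defaults to the shipped table.
#' @return A tibble: `accession`, `cluster`, `pattern`.
#' @export
classify_patterns <- function(genotypes, clusters, defs = pattern_definitions()) {
  calls <- if (inherits(genotypes, "cn_genotypes")) genotypes$calls else genotypes
  accs <- sort(unique(calls$accession))
  status_mat <- tidyr::pivot_wider(
    calls[, c("accession", "gene", "status")],
    names_from = "gene", values_from = "status"
  )
  out <- purrr::map_dfr(seq_len(nrow(clusters)), function(i) {
    members <- clusters$members[[i]]
    cl_name <- clusters$cluster[i]
    defs_cluster <- defs[defs$cluster == cl_name, , drop = FALSE]
    missing_members <- setdiff(members, names(status_mat))
    sm <- status_mat
    for (m in missing_members) sm[[m]] <- NA_character_
    tibble(
      accession = sm$accession,
      cluster = cl_name,
      pattern = purrr::map_chr(seq_len(nrow(sm)), function(j) {
        label_status_vector(
          unlist(sm[j, members], use.names = FALSE),
          members, defs_cluster
        )
      })
    )
  })
  arrange(out, .data$accession, .data$cluster)
}

#' Population census of cluster CNV
#'
#' Summarises a genotype matrix at the cohort level: how many accessions carry
#' at least one member-gene gain or loss in any cluster, how many genes are
#' affected per cluster, and per-pattern accession counts (optionally split by
#' a grouping variable such as country or genetic group). Accessions with any
#' ungenotyped member gene are reported separately (`n_incomplete`) and are
#' excluded from the no-CNV denominator, since their invariability cannot be
#' asserted. Intervening genes are not counted towards an accession being
#' "variable"; their affected counts are reported separately.
#'
#' @param genotypes A `cn_genotypes` object or long call tibble.
#' @param clusters Cluster tibble from [cluster_definitions()].
#' @param defs Pattern definitions passed to [classify_patterns()].
#' @param groups Optional tibble `accession`, `group` for per-group pattern
#'   counts.
#' @return An object of class `mgc_census`: list with `n_accessions`,
#'   `n_complete`, `n_incomplete`, `n_variable`, `no_cnv_pct`,
#'   `affected_genes` (tibble `cluster`, `gene`, `n_loss`, `n_gain`),
#'   `n_affected_genes`, `pattern_counts` (tibble `cluster`, `pattern`, `n`,
#'   optionally by group), and `patterns` (the per-accession classification).
#' @export
population_census <- function(genotypes, clusters, defs = pattern_definitions(),
                              groups = NULL) {
  calls <- if (inherits(genotypes, "cn_genotypes")) genotypes$calls else genotypes
  members <- unlist(clusters$members)
  member_calls <- calls %>%
    filter(.data$gene %in% members) %>%
    mutate(cluster = rep(clusters$cluster, lengths(clusters$members))[
      match(.data$gene, members)
    ])

  accs <- unique(calls$accession)
  per_acc <- member_calls %>%
    group_by(.data$accession) %>%
    summarise(
      n_called = sum(!is.na(.data$status) & .data$status != "CONFLICT"),
      n_variant = sum(.data$status %in% c("LOSS", "GAIN"), na.rm = TRUE),
      .groups = "drop"
    )
  # accessions absent from the member-gene calls entirely count as incomplete
  n_members <- length(members)
  complete <- per_acc$accession[per_acc$n_called == n_members]
  n_incomplete <- length(accs) - length(complete)
  variable <- per_acc$accession[per_acc$n_variant > 0]
  n_variable_complete <- sum(complete %in% variable)

  affected <- member_calls %>%
    group_by(.data$cluster, .data$gene) %>%
    summarise(
      n_loss = sum(.data$status == "LOSS", na.rm = TRUE),
      n_gain = sum(.data$status == "GAIN", na.rm = TRUE),
      .groups = "drop"
    ) %>%
    filter(.data$n_loss + .data$n_gain > 0)

  intervening <- unlist(clusters$intervening)
  affected_intervening <- calls %>%
    filter(.data$gene %in% intervening,
           .data$status %in% c("LOSS", "GAIN")) %>%
    count(.data$gene, name = "n_variant")

  patterns <- classify_patterns(calls, clusters, defs)
  if (!is.null(groups)) {
    patterns <- left_join(patterns, groups, by = "accession")
    pattern_counts <- patterns %>%
      filter(!is.na(.data$pattern), .data$pattern != "REF") %>%
      count(.data$cluster, .data$pattern, .data$group, name = "n")
  } else {
    pattern_counts <- patterns %>%
      filter(!is.na(.data$pattern), .data$pattern != "REF") %>%
      count(.data$cluster, .data$pattern, name = "n")
  }

  structure(
    list(
      n_accessions = length(accs),
      n_complete = length(complete),
      n_incomplete = n_incomplete,
      n_variable = n_variable_complete,
      no_cnv_pct = if (length(complete) > 0) {
        100 * (1 - n_variable_complete / length(complete))
      } else {
        NA_real_
      },
      affected_genes = affected,
      n_affected_genes = nrow(affected),
      affected_intervening = affected_intervening,
      pattern_counts = pattern_counts,
      patterns = patterns
    ),
    class = "mgc_census"
  )
}

#' @export
print.mgc_census <- function(x, ...) {
  cat("<mgc_census> ", x$n_accessions, " accessions (",
      x$n_incomplete, " incompletely genotyped)\n", sep = "")
  cat(sprintf(
    "  %.1f%% of fully genotyped accessions without member-gene CNV\n",
    x$no_cnv_pct
  ))
  cat("  affected member genes: ", x$n_affected_genes, "\n", sep = "")
  invisible(x)
}
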