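#' Assemble and validate a pipeline configuration
#'
#' A pipeline run is configured by one structured key-value (YAML) file with
#' per-stage sections; arguments passed directly override file values. All
#' randomness flows from the single top-level `seed`.
#'
#' @param path Optional YAML file.
#' @param ... Overrides: any of `seed`, `n_accessions`, `policy`,
#'   `scan_alpha`, `maf_min`, a nested `thresholds` list, and any
#'   [cohort_config()] argument under `cohort`.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(path = NULL, ...) {
  cfg <- list(
    seed = 1,
    n_accessions = 300,
    policy = "conflict",
    scan_alpha = 0.05,
    maf_min = NULL,
    thresholds = default_thresholds(),
    cohort = list()
  )
  if (!is.null(path)) {
    file_cfg <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, file_cfg)
  }
  overrides <- list(...)
  if (length(overrides) > 0) cfg <- utils::modifyList(cfg, overrides)

  th <- cfg$thresholds
  if (!is.null(th$rd_loss) && !is.null(th$rd_gain) && th$rd_loss >= th$rd_gain) {
    abort("pipeline_config: thresholds$rd_loss must be < thresholds$rd_gain")
  }
  if (!is.null(th$mlpa_loss) && !is.null(th$mlpa_gain) && th$mlpa_loss >= th$mlpa_gain) {
    abort("pipeline_config: thresholds$mlpa_loss must be < thresholds$mlpa_gain")
  }
  if (!is.null(th$ddpcr_loss_max) && !is.null(th$ddpcr_gain_min) &&
      th$ddpcr_loss_max >= th$ddpcr_gain_min) {
    abort("pipeline_config: thresholds$ddpcr_loss_max must be < thresholds$ddpcr_gain_min")
  }
  if (!cfg$policy %in% c("conflict", "priority")) {
    abort("pipeline_config: policy must be 'conflict' or 'priority'")
  }
  if (cfg$scan_alpha <= 0 || cfg$scan_alpha >= 1) {
    abort("pipeline_config: scan_alpha must be in (0, 1)")
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Orchestrates simulate -> genotype -> patterns -> hetdup -> invdedup ->
#' pairs -> scan in dependency order, writing each stage's outputs (in the
#' package's standard text formats) plus a JSON summary into `out_dir`. Every
#' output is reproducible: rerunning with the same configuration yields
#' byte-identical files. The configuration hash and seed are recorded in the
#' summary.
#'
#' @param config A [pipeline_config()] (or a path to a YAML config file).
#' @param out_dir Output directory, created if needed.
#' @return An object of class `mgc_pipeline_run`: list with `out_dir`,
#'   `summary` (named list, also written as `summary.json`) and the main
#'   in-memory results.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  if (is.character(config)) config <- pipeline_config(path = config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  cohort_args <- utils::modifyList(
    list(n_accessions = config$n_accessions, seed = config$seed),
    config$cohort
  )
  cohort <- generate_cohort(do.call(cohort_config, cohort_args))
  inputs_dir <- file.path(out_dir, "inputs")
  write_cohort(cohort, inputs_dir)

  th <- config$thresholds

  ## genotype ---------------------------------------------------------------
  rd_calls <- call_genotypes(cohort$rd, "RD", th)
  mlpa_calls <- call_genotypes(normalize_mlpa(cohort$mlpa_raw), "MLPA", th)
  dd_genes <- setdiff(names(cohort$ddpcr), c("accession", "DCL1"))
  dd_norm <- cohort$ddpcr["accession"]
  for (g in dd_genes) {
    dd_norm[[g]] <- normalize_ddpcr(cohort$ddpcr[[g]], cohort$ddpcr$DCL1,
                                    attr(cohort$ddpcr, "background"))
  }
  dd_calls <- call_genotypes(dd_norm, "DDPCR", th)
  genotypes <- integrate_genotypes(rd_calls, mlpa_calls, dd_calls,
                                   policy = config$policy)
  write_genotype_matrix(genotypes$calls, file.path(out_dir, "genotypes.tsv"),
                        header = sprintf("seed=%d", config$seed))
  readr::write_tsv(genotypes$concordance$discordant,
                   file.path(out_dir, "discordant_cells.tsv"))

  ## patterns ---------------------------------------------------------------
  coverage <- cluster_cnv_coverage(cohort$clusters, cohort$cnv_catalog)
  census <- population_census(genotypes, cohort$clusters, groups = cohort$meta)
  readr::write_tsv(census$patterns, file.path(out_dir, "patterns_report.tsv"))
  readr::write_tsv(census$pattern_counts, file.path(out_dir, "pattern_counts.tsv"))

  ## hetdup -----------------------------------------------------------------
  pair_genes <- cohort$annotation[cohort$annotation$gene_id %in%
                                    c("CYP705A2", "BARS1"), ]
  profiles <- count_het_snps(cohort$snps, pair_genes,
                             accessions = cohort$accessions,
                             maf_min = config$maf_min)
  pav <- classify_pav_groups(profiles, cohort$rd)
  readr::write_tsv(pav, file.path(out_dir, "pav_groups.tsv"))

  ## invdedup ---------------------------------------------------------------
  inv_region <- thalianol_inversion_region(cohort$annotation)
  deduped <- cohort$sv_calls %>%
    filter_sv_calls() %>%
    dedup_sv_calls()
  inv <- inversion_presence(cohort$sv_calls, inv_region, cohort$accessions)
  write_sv_calls(deduped, file.path(out_dir, "inversions.tsv"))
  readr::write_tsv(inv, file.path(out_dir, "inversion_presence.tsv"))

  ## pairs ------------------------------------------------------------------
  pairs_res <- NULL
  if (!is.null(cohort$ts_cyp)) {
    pairs_tbl <- find_ts_cyp_pairs(cohort$ts_cyp$ts, cohort$ts_cyp$cyp)
    variability <- classify_variability(genotypes)
    pairs_res <- compare_paired_vs_nonpaired(
      variability, pairs_tbl,
      ts_ids = cohort$ts_cyp$ts$gene_id,
      cyp_ids = cohort$ts_cyp$cyp$gene_id
    )
    readr::write_tsv(pairs_tbl, file.path(out_dir, "ts_cyp_pairs.tsv"))
    readr::write_tsv(as_tibble(pairs_res), file.path(out_dir, "pairs_test.tsv"))
  }

  ## scan -------------------------------------------------------------------
  scan_groups <- pav %>%
    filter(.data$group %in% c("PP-AA", "PP-PP")) %>%
    select("accession", "group")
  scan_res <- phenotype_scan(cohort$phenotypes, scan_groups,
                             alpha = config$scan_alpha)
  readr::write_tsv(as_tibble(scan_res), file.path(out_dir, "scan.tsv"))

  ## summary ----------------------------------------------------------------
  summary <- list(
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)),
    n_accessions = length(cohort$accessions),
    thresholds = th[c("rd_loss", "rd_gain", "mlpa_loss", "mlpa_gain",
                      "ddpcr_loss_max", "ddpcr_gain_min")],
    concordance_pct = concordance_fraction(genotypes),
    no_cnv_pct = census$no_cnv_pct,
    n_affected_genes = census$n_affected_genes,
    cluster_coverage_pct = setNames(as.list(coverage$coverage_pct),
                                    coverage$cluster),
    pav_group_counts = as.list(table(pav$group)),
    inversion_pct = 100 * mean(inv$inverted),
    scan_significant = sum(scan_res$significant),
    pairs_p_values = if (!is.null(pairs_res)) {
      setNames(as.list(pairs_res$p_value), pairs_res$family)
    }
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  structure(
    list(
      out_dir = out_dir,
      summary = summary,
      cohort = cohort,
      genotypes = genotypes,
      census = census,
      coverage = coverage,
      pav = pav,
      inversions = inv,
      pairs = pairs_res,
      scan = scan_res
    ),
    class = "mgc_pipeline_run"
  )
}

#' @export
print.mgc_pipeline_run <- function(x, ...) {
  s <- x$summary
  cat("<mgc_pipeline_run> seed ", s$seed, ", ", s$n_accessions,
      " accessions -> ", x$out_dir, "\n", sep = "")
  cat(sprintf("  concordance: %.1f%%; no-CNV accessions: %.1f%%\n",
              s$concordance_pct, s$no_cnv_pct))
  cat(sprintf("  compact thalianol haplotype: %.1f%%\n", s$inversion_pct))
  cat("  PAV groups: ",
      paste(names(s$pav_group_counts), unlist(s$pav_group_counts),
            sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}
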