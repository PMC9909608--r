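gene_row <- function(id, chrom, start, end) {
  tibble::tibble(gene_id = id, chrom = chrom, start = start, end = end)
}

test_that("pairing uses the border-to-border 30-kb window inclusively", {
  ts <- gene_row("TS1", "c1", 0, 2000)
  expect_equal(
    find_ts_cyp_pairs(ts, gene_row("CYP1", "c1", 10000, 12000))$distance, 8000
  )
  # gap of exactly 30000 is paired; 30001 is not
  expect_equal(nrow(find_ts_cyp_pairs(ts, gene_row("CYP1", "c1", 32000, 34000))), 1)
  expect_equal(nrow(find_ts_cyp_pairs(ts, gene_row("CYP1", "c1", 32001, 34000))), 0)
  # overlapping genes pair at distance 0
  expect_equal(find_ts_cyp_pairs(ts, gene_row("CYP1", "c1", 1000, 3000))$distance, 0)
  # cross-chromosome pairs are never emitted
  expect_equal(nrow(find_ts_cyp_pairs(ts, gene_row("CYP1", "c2", 0, 2000))), 0)
})

test_that("pairing equals a brute-force all-pairs distance check", {
  # 5 TS + 8 CYP placed to yield exactly 6 pairs
  ts <- dplyr::bind_rows(
    gene_row("TS1", "c1", 0, 2000),
    gene_row("TS2", "c1", 100000, 102000),
    gene_row("TS3", "c2", 0, 2000),
    gene_row("TS4", "c2", 500000, 502000),
    gene_row("TS5", "c3", 0, 2000)
  )
  cyp <- dplyr::bind_rows(
    gene_row("CYP1", "c1", 5000, 7000),      # pairs TS1
    gene_row("CYP2", "c1", 20000, 22000),    # pairs TS1
    gene_row("CYP3", "c1", 110000, 112000),  # pairs TS2
    gene_row("CYP4", "c1", 130000, 132000),  # pairs TS2 (gap 28000)
    gene_row("CYP5", "c2", 25000, 27000),    # pairs TS3
    gene_row("CYP6", "c2", 470000, 472000),  # pairs TS4
    gene_row("CYP7", "c3", 40000, 42000),    # pairs none (gap 38000)
    gene_row("CYP8", "c4", 0, 2000)          # pairs none
  )
  got <- find_ts_cyp_pairs(ts, cyp)
  expect_equal(nrow(got), 6)
  # independent brute force
  brute <- list()
  for (i in seq_len(nrow(ts))) {
    for (j in seq_len(nrow(cyp))) {
      if (ts$chrom[i] != cyp$chrom[j]) next
      gap <- max(0, max(ts$start[i], cyp$start[j]) - min(ts$end[i], cyp$end[j]))
      if (gap <= 30000) {
        brute[[length(brute) + 1]] <-
          tibble::tibble(ts = ts$gene_id[i], cyp = cyp$gene_id[j], distance = gap)
      }
    }
  }
  brute <- dplyr::arrange(dplyr::bind_rows(brute), ts, cyp)
  expect_equal(got, brute)
})

test_that("variability classification uses the inclusive 1% rule", {
  mk <- function(n_variant, n_total, gene = "g1") {
    tibble::tibble(
      accession = paste0("a", seq_len(n_total)),
      gene = gene,
      status = c(rep("LOSS", n_variant), rep("REF", n_total - n_variant))
    )
  }
  expect_equal(classify_variability(mk(10, 1000))$variability, "variable")
  expect_equal(classify_variability(mk(9, 1000))$variability, "invariable")
  expect_equal(classify_variability(mk(0, 500))$variability, "invariable")
  # all-NA gene is unclassified
  na_gene <- tibble::tibble(accession = "a1", gene = "g1", status = NA_character_)
  expect_true(is.na(classify_variability(na_gene)$variability))
  # denominator excludes NA and CONFLICT calls
  mixed <- dplyr::bind_rows(mk(1, 99), tibble::tibble(
    accession = "a100", gene = "g1", status = "CONFLICT"
  ))
  expect_equal(classify_variability(mixed)$n_genotyped, 99)
})

test_that("raising the variability threshold never makes a gene variable", {
  set.seed(3)
  calls <- tibble::tibble(
    accession = rep(paste0("a", 1:200), times = 5),
    gene = rep(paste0("g", 1:5), each = 200),
    status = sample(c("REF", "LOSS", "GAIN"), 1000, replace = TRUE,
                    prob = c(0.97, 0.02, 0.01))
  )
  fracs <- c(0.005, 0.01, 0.02, 0.05, 0.1)
  prev <- NULL
  for (f in fracs) {
    v <- classify_variability(calls, min_frac = f)
    n_var <- sum(v$variability == "variable", na.rm = TRUE)
    if (!is.null(prev)) expect_lte(n_var, prev)
    prev <- n_var
  }
})

test_that("paired-vs-nonpaired comparison detects planted variability excess", {
  variability <- tibble::tibble(
    gene = c(paste0("TSP", 1:10), paste0("TSN", 1:10)),
    n_genotyped = 1000,
    n_variant = c(rep(500, 10), rep(0, 10)),
    variant_frac = c(rep(0.5, 10), rep(0, 10)),
    variability = c(rep("variable", 10), rep("invariable", 10))
  )
  pairs <- tibble::tibble(ts = paste0("TSP", 1:10), cyp = character(10), distance = 0)
  res <- suppressWarnings(compare_paired_vs_nonpaired(
    variability, pairs,
    ts_ids = variability$gene, cyp_ids = character(0)
  ))
  expect_lt(res$p_value[res$family == "TS"], 0.001)
  expect_warning(
    compare_paired_vs_nonpaired(variability, pairs, ts_ids = variability$gene,
                                cyp_ids = character(0)),
    "degenerate groups for CYP"
  )
  # identical groups: p near 1
  flat <- dplyr::mutate(variability, variant_frac = 0.5)
  res_flat <- suppressWarnings(compare_paired_vs_nonpaired(
    flat, pairs, ts_ids = flat$gene, cyp_ids = character(0)
  ))
  expect_equal(res_flat$p_value[res_flat$family == "TS"], 1)
})

test_that("planted paired-gene variability excess is detected in cohorts", {
  co <- generate_cohort(cohort_config(n_accessions = 300, seed = 41))
  gt <- integrate_genotypes(call_genotypes(co$rd, "RD"))
  pairs_tbl <- find_ts_cyp_pairs(co$ts_cyp$ts, co$ts_cyp$cyp)
  res <- compare_paired_vs_nonpaired(
    classify_variability(gt), pairs_tbl,
    ts_ids = co$ts_cyp$ts$gene_id, cyp_ids = co$ts_cyp$cyp$gene_id
  )
  expect_true(all(res$p_value < 0.01))
  expect_gt(res$median_paired[1], res$median_nonpaired[1])
})
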