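make_cluster <- function() {
  tibble::tibble(
    cluster = "thalianol", chrom = "c1", start = 0, end = 1000,
    members = list(c("AT5G47980", "CYP705A5", "CYP708A2", "THAS1", "AT5G47950")),
    intervening = list(c("RABA4C", "AT5G47970"))
  )
}

acc_calls <- function(accession, statuses) {
  tibble::tibble(
    accession = accession,
    gene = c("AT5G47980", "CYP705A5", "CYP708A2", "THAS1", "AT5G47950"),
    status = statuses
  )
}

test_that("cluster CNV coverage is the union-coverage percentage of the span", {
  cl <- make_cluster()
  expect_equal(
    cluster_cnv_coverage(cl, genomic_interval("c1", 0, 1000))$coverage_pct, 100
  )
  expect_equal(
    cluster_cnv_coverage(cl, genomic_interval("c1", c(0, 500), c(250, 750)))$coverage_pct, 50
  )
  expect_equal(cluster_cnv_coverage(cl, genomic_interval("c1", 0, 10)[0, ])$coverage_pct, 0)
})

test_that("named thalianol variants are recognised from status vectors", {
  cl <- make_cluster()
  cases <- list(
    list(c("LOSS", "LOSS", "REF", "LOSS", "REF"), "A"),
    list(c("LOSS", "LOSS", "LOSS", "REF", "REF"), "B"),
    list(c("REF", "REF", "LOSS", "REF", "REF"), "C"),
    list(c("REF", "LOSS", "LOSS", "LOSS", "REF"), "D"),
    list(c("GAIN", "REF", "REF", "REF", "REF"), "E"),
    list(rep("REF", 5), "REF")
  )
  for (cs in cases) {
    out <- classify_patterns(acc_calls("a1", cs[[1]]), cl)
    expect_equal(out$pattern, cs[[2]])
  }
})

test_that("unnamed, unresolved and incomplete vectors are labelled distinctly", {
  cl <- make_cluster()
  # an undescribed vector gets a canonical label, not the nearest named one
  out <- classify_patterns(acc_calls("a1", c("LOSS", "REF", "REF", "REF", "REF")), cl)
  expect_equal(out$pattern, "AT5G47980:LOSS")
  out2 <- classify_patterns(acc_calls("a1", c("LOSS", "LOSS", "LOSS", "LOSS", "REF")), cl)
  expect_false(out2$pattern %in% c("A", "B", "C", "D", "E", "REF"))
  # CONFLICT in the vector
  expect_equal(
    classify_patterns(acc_calls("a1", c("CONFLICT", rep("REF", 4))), cl)$pattern,
    "UNRESOLVED"
  )
  # any NA member -> pattern NA
  expect_true(is.na(
    classify_patterns(acc_calls("a1", c(NA, rep("REF", 4))), cl)$pattern
  ))
})

test_that("the named patterns are mutually exclusive", {
  cl <- make_cluster()
  defs <- pattern_definitions()
  labs <- unique(defs$label)
  for (lab in labs) {
    d <- defs[defs$label == lab, ]
    v <- setNames(d$status, d$gene)[cl$members[[1]]]
    out <- classify_patterns(acc_calls("a1", unname(v)), cl, defs)
    expect_equal(out$pattern, lab)
  }
})

test_that("population census counts accessions, genes and patterns consistently", {
  cl <- make_cluster()
  calls <- dplyr::bind_rows(
    acc_calls("a1", rep("REF", 5)),
    acc_calls("a2", c("LOSS", "LOSS", "REF", "LOSS", "REF")), # variant A
    acc_calls("a3", rep("REF", 5)),
    acc_calls("a4", rep("REF", 5))
  )
  cz <- population_census(calls, cl)
  expect_equal(cz$n_accessions, 4)
  expect_equal(cz$n_variable, 1)
  expect_equal(cz$no_cnv_pct, 75)
  expect_equal(cz$n_affected_genes, 3)
  expect_equal(cz$pattern_counts$pattern, "A")
  expect_equal(cz$pattern_counts$n, 1)

  # all-REF matrix: no affected genes
  all_ref <- dplyr::bind_rows(acc_calls("a1", rep("REF", 5)),
                              acc_calls("a2", rep("REF", 5)))
  expect_equal(population_census(all_ref, cl)$n_affected_genes, 0)

  # order invariance
  cz2 <- population_census(calls[sample(nrow(calls)), ], cl)
  expect_equal(glance(cz2), glance(cz))

  # incompletely genotyped accessions are excluded from the denominator
  with_na <- dplyr::bind_rows(calls, acc_calls("a5", c(NA, rep("REF", 4))))
  cz3 <- population_census(with_na, cl)
  expect_equal(cz3$n_incomplete, 1)
  expect_equal(cz3$no_cnv_pct, 75)
})

test_that("census recovers planted pattern frequencies on a synthetic cohort", {
  freqs <- tibble::tibble(
    cluster = c("thalianol", "thalianol"),
    label = c("A", "E"),
    freq = c(0.05, 0.01)
  )
  n <- 2000
  co <- generate_cohort(cohort_config(
    n_accessions = n, seed = 19, pattern_freqs = freqs, ts_cyp = FALSE
  ))
  gt <- integrate_genotypes(call_genotypes(co$rd, "RD"))
  cz <- population_census(gt, co$clusters)
  counts <- cz$pattern_counts[cz$pattern_counts$cluster == "thalianol", ]
  for (lab in c("A", "E")) {
    p <- freqs$freq[freqs$label == lab]
    se <- sqrt(p * (1 - p) / n)
    # generator plants the pattern at its nominal binomial rate
    planted <- sum(co$truth$events$label == lab)
    expect_lt(abs(planted / n - p), 3 * se)
    # and the census recovers the planted count (small allowance for RD noise)
    expect_lt(abs(sum(counts$n[counts$pattern == lab]) - planted), 6)
  }
})
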