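toy_gene <- function() {
  g <- tibble::tibble(
    gene_id = "GENE1", chrom = "c1", start = 100, end = 1000,
    strand = "+", category = "CYP", cluster = NA_character_, role = "member"
  )
  g$exons <- list(tibble::tibble(chrom = "c1", start = c(100, 500), end = c(300, 1000)))
  g
}

toy_snps <- function() {
  # 5 exonic biallelic SNPs; acc1 het at 3 of them, homalt at 1
  sites <- tibble::tibble(
    chrom = "c1", pos = c(110, 150, 200, 600, 900), ref = "A", alt = "G"
  )
  long <- tidyr::expand_grid(sites, accession = c("acc1", "acc2"))
  long$gt <- c(
    "0/1", "0/0", "0/1", "0/0", "0/1", "0/0", "1/1", "0/0", "0/0", "0/0"
  )
  long
}

test_that("het counting filters to exonic biallelic SNPs", {
  out <- count_het_snps(toy_snps(), toy_gene())
  a1 <- out[out$accession == "acc1", ]
  expect_equal(a1$n_het, 3)
  expect_equal(a1$n_homalt, 1)
  expect_equal(a1$n_sites, 5)
  expect_equal(out$n_het[out$accession == "acc2"], 0)
})

test_that("multi-allelic, indel and non-exonic records are excluded", {
  snps <- toy_snps()
  extra <- tidyr::expand_grid(
    tibble::tibble(
      chrom = "c1",
      pos = c(120, 130, 400),          # 400 lies between the exons
      ref = c("A", "AT", "A"),
      alt = c("G,T", "A", "G")
    ),
    accession = c("acc1", "acc2")
  )
  extra$gt <- "0/1"
  out <- count_het_snps(dplyr::bind_rows(snps, extra), toy_gene())
  # none of the three decoys counts towards sites or het totals
  expect_equal(unique(out$n_sites), 5)
  expect_equal(out$n_het[out$accession == "acc1"], 3)
  expect_equal(out$n_het[out$accession == "acc2"], 0)
})

test_that("the optional frequency filter drops rare sites", {
  snps <- toy_snps()
  # site 110 is het only in acc1 -> af 0.25; with maf_min 0.3 it is dropped
  out <- count_het_snps(snps, toy_gene(), maf_min = 0.3)
  expect_lt(unique(out$n_sites), 5)
})

test_that("het counting validates its inputs", {
  expect_error(count_het_snps(toy_snps(), toy_gene(), accessions = "missing_acc"),
               "absent")
  g <- toy_gene()
  g$exons <- list(tibble::tibble(chrom = character(), start = numeric(), end = numeric()))
  expect_error(count_het_snps(toy_snps(), g), "no exons")
})

test_that("het counts are invariant to SNP record order", {
  snps <- toy_snps()
  shuffled <- snps[sample(nrow(snps)), ]
  expect_equal(count_het_snps(snps, toy_gene()), count_het_snps(shuffled, toy_gene()))
})

test_that("PAV groups are classified from depth plus SNP evidence", {
  profiles <- tibble::tibble(
    accession = rep(c("a1", "a2", "a3", "a4"), each = 2),
    gene = rep(c("CYP705A2", "BARS1"), 4),
    n_het = c(12, 15, 0, 0, 0, 0, 0, 0),
    n_homalt = c(0, 0, 0, 0, 10, 8, 0, 0),
    n_sites = 135
  )
  rd <- tibble::tibble(
    accession = c("a1", "a2", "a3", "a4"),
    CYP705A2 = c(2.1, 2.0, 1.5, 0),
    BARS1 = c(1.9, 2.1, 0.6, 0),
    CYP705A3 = c(2.0, 1.9, 0.0, 0)
  )
  out <- classify_pav_groups(profiles, rd)
  expect_equal(out$group[match(c("a1", "a2", "a3", "a4"), out$accession)],
               c("PP-PP", "PP-AA", "AA-PP", "AA-AA"))
})

test_that("missing depth gives INCONCLUSIVE", {
  profiles <- tibble::tibble(
    accession = rep("a1", 2), gene = c("CYP705A2", "BARS1"),
    n_het = 0, n_homalt = 0, n_sites = 10
  )
  rd <- tibble::tibble(accession = "a1", CYP705A2 = NA_real_,
                       BARS1 = 2, CYP705A3 = 2)
  expect_equal(classify_pav_groups(profiles, rd)$group, "INCONCLUSIVE")
})

test_that("locus het correlation behaves on degenerate and perfect inputs", {
  prof <- function(h1, h2) {
    tibble::tibble(
      accession = rep(paste0("a", seq_along(h1)), 2),
      gene = rep(c("CYP705A2", "BARS1"), each = length(h1)),
      n_het = c(h1, h2), n_homalt = 0, n_sites = 10
    )
  }
  expect_equal(locus_het_correlation(prof(c(0, 1, 2, 3), c(0, 1, 2, 3))), 1)
  expect_equal(locus_het_correlation(prof(c(0, 1, 2, 3), c(3, 2, 1, 0))), -1)
  expect_warning(r <- locus_het_correlation(prof(c(1, 1, 1), c(0, 1, 2))),
                 "zero variance")
  expect_true(is.na(r))
})

test_that("planted duplication structure drives the het-excess signal", {
  co <- generate_cohort(cohort_config(n_accessions = 400, seed = 23, ts_cyp = FALSE))
  pair_genes <- co$annotation[co$annotation$gene_id %in% c("CYP705A2", "BARS1"), ]
  prof <- count_het_snps(co$snps, pair_genes, accessions = co$accessions)
  truth <- co$truth$dup_group
  by_group <- dplyr::inner_join(
    prof[prof$gene == "CYP705A2", ], truth, by = "accession"
  )
  # PP-AA accessions carry no divergent sites by construction
  expect_true(all(by_group$n_het[by_group$group == "PP-AA"] == 0))
  # PP-PP accessions essentially always carry them
  expect_true(all(by_group$n_het[by_group$group == "PP-PP"] > 0))
  # the count scales as Binomial(round(1500 * 0.09), 0.8)
  m <- mean(by_group$n_het[by_group$group == "PP-PP"])
  n_pp <- sum(by_group$group == "PP-PP")
  mu <- 135 * 0.8
  se <- sqrt(135 * 0.8 * 0.2 / n_pp)
  expect_lt(abs(m - mu), 3 * se)
})
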