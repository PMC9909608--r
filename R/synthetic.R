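# run code with a private RNG stream seeded from `seed`, restoring the
# caller's RNG state afterwards, so cohort generation is reproducible and
# side-effect free
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Default planted CNV event frequencies
#'
#' One planted event (or none) is drawn per accession per cluster. The
#' default frequencies are the population rates reported for the 1,152
#' genotyped accessions: thalianol variants A-E in 37/4/5/3/5 accessions;
#' the CYP702A3 deletion in 564, CYP702A2 duplication in 50, CYP702A5
#' deletion in 35 accessions (etc.) of the arabidiol/baruol cluster; the
#' three-gene tirucalladienol deletion region in ~1.4% of accessions; and a
#' single private marneral variant.
#'
#' @return A tibble: `cluster`, `label`, `freq`.
#' @export
default_event_freqs <- function() {
  tibble(
    cluster = c(
      rep("thalianol", 5),
      "marneral",
      "tirucalladienol",
      rep("arabidiol_baruol", 6)
    ),
    label = c(
      "A", "B", "C", "D", "E",
      "CYP705A12_loss",
      "PEN3_region_loss",
      "CYP702A3_loss", "CYP702A2_gain", "CYP702A5_loss",
      "CYP705A4_loss", "BIA1_loss", "PEN1_CYP705A1_loss"
    ),
    freq = c(
      37, 4, 5, 3, 5,
      1,
      15,
      564, 50, 35, 2, 1, 3
    ) / 1152
  )
}

# label -> named vector of non-REF member statuses
event_effects <- function(defs = pattern_definitions()) {
  named <- split(defs, defs$label)
  th <- purrr::map(named, function(d) {
    v <- setNames(d$status, d$gene)
    v[v != "REF"]
  })
  c(th, list(
    CYP705A12_loss = c(CYP705A12 = "LOSS"),
    PEN3_region_loss = c(AT5G36130 = "LOSS", CYP716A2 = "LOSS", PEN3 = "LOSS"),
    CYP702A3_loss = c(CYP702A3 = "LOSS"),
    CYP702A2_gain = c(CYP702A2 = "GAIN"),
    CYP702A5_loss = c(CYP702A5 = "LOSS"),
    CYP705A4_loss = c(CYP705A4 = "LOSS"),
    BIA1_loss = c(BIA1 = "LOSS"),
    PEN1_CYP705A1_loss = c(PEN1 = "LOSS", CYP705A1 = "LOSS")
  ))
}

#' Expected read-depth levels at the reference paralog pair, by PAV group
#'
#' Returns the copy-number level a mapping-based read-depth assay is expected
#' to report at the reference CYP705A2/BARS1 pair (and the linked marker
#' CYP705A3) for each presence/absence group. For `AA-PP` accessions the
#' reference region is gone but reads from the divergent duplicates still
#' cross-map, producing the intermediate levels 1.5 and 0.6 with a clear zero
#' at the marker; for `PP-PP` the CYP705A2 duplicate is similar enough to
#' double the apparent level (4) while the divergent BARS1 duplicate is
#' invisible (2).
#'
#' @param group One of `"PP-AA"`, `"PP-PP"`, `"AA-PP"`, `"AA-AA"`.
#' @return Named numeric vector: `locus1`, `locus2`, `marker`.
#' @export
cross_mapping_rd_levels <- function(group) {
  switch(group,
    "PP-AA" = c(locus1 = 2.0, locus2 = 2.0, marker = 2.0),
    "PP-PP" = c(locus1 = 4.0, locus2 = 2.0, marker = 2.0),
    "AA-PP" = c(locus1 = 1.5, locus2 = 0.6, marker = 0.0),
    "AA-AA" = c(locus1 = 0.0, locus2 = 0.0, marker = 0.0),
    abort(sprintf("cross_mapping_rd_levels: unknown group '%s'", group))
  )
}

#' Configuration for a synthetic accession cohort
#'
#' Collects and validates all generator parameters. The defaults are the
#' study conditions of the population analysis the package re-implements:
#' 1,152 naturally inbred accessions; RD covering every accession while MLPA
#' and ddPCR cover ~20% and ~2% subsets; planted cluster CNV events at the
#' published population frequencies ([default_event_freqs()]); CYP705A2/BARS1
#' presence/absence groups at 628:326:14:15; a 65% frequency of the compact
#' (inverted) thalianol-cluster haplotype; paralog divergence 0.09 (the ~91%
#' identity of the cryptic BARS1 duplicate) over 1.5 kb of exonic target with
#' a 0.8 per-site detection probability.
#'
#' @param n_accessions Number of accessions.
#' @param seed Integer RNG seed; all cohort randomness flows from it.
#' @param sigma_rd Additive s.d. of read-depth noise.
#' @param sigma_mlpa Multiplicative (log-normal) s.d. of MLPA noise.
#' @param sigma_ddpcr Additive s.d. of normalized ddPCR copy number.
#' @param mlpa_fraction,ddpcr_fraction Fractions of accessions assayed by
#'   MLPA / ddPCR.
#' @param pattern_freqs Event-frequency tibble (`cluster`, `label`, `freq`).
#' @param dup_group_freqs Named probabilities of the four PAV groups.
#' @param inversion_freq Frequency of the compact (inverted) thalianol
#'   haplotype.
#' @param duplicate_divergence Substitution rate between the reference genes
#'   and their cryptic duplicates.
#' @param exon_length Exonic bases carrying divergent sites at each locus.
#' @param p_det Per-divergent-site detection probability in the SNP calls.
#' @param phenotype_effect Planted group mean shift (in s.d. units) of the
#'   planted phenotype variables.
#' @param n_phenotypes,n_planted_phenotypes Total and planted-effect
#'   phenotype variable counts.
#' @param ts_cyp Generate the genome-wide TS/CYP gene complement.
#' @param n_ts,n_cyp Genome-wide TS and CYP gene counts.
#' @param paired_variability,nonpaired_variability Per-accession CNV carrier
#'   probability for paired / nonpaired TS-CYP genes (a 5x planted excess by
#'   default).
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_accessions = 1152,
                          seed = 1,
                          sigma_rd = 0.25,
                          sigma_mlpa = 0.1,
                          sigma_ddpcr = 0.1,
                          mlpa_fraction = 0.2,
                          ddpcr_fraction = 0.02,
                          pattern_freqs = default_event_freqs(),
                          dup_group_freqs = c(
                            "PP-AA" = 628 / 983, "PP-PP" = 326 / 983,
                            "AA-PP" = 14 / 983, "AA-AA" = 15 / 983
                          ),
                          inversion_freq = 649 / 997,
                          duplicate_divergence = 0.09,
                          exon_length = 1500,
                          p_det = 0.8,
                          phenotype_effect = 1.0,
                          n_phenotypes = 10,
                          n_planted_phenotypes = 3,
                          ts_cyp = TRUE,
                          n_ts = 48,
                          n_cyp = 242,
                          paired_variability = 0.05,
                          nonpaired_variability = 0.01) {
  cfg <- as.list(environment())
  if (n_accessions < 1) abort("cohort_config: n_accessions must be >= 1")
  if (sigma_rd <= 0 || sigma_mlpa <= 0 || sigma_ddpcr <= 0) {
    abort("cohort_config: noise s.d. values must be > 0")
  }
  if (duplicate_divergence <= 0 || duplicate_divergence >= 1) {
    abort("cohort_config: duplicate_divergence must be in (0, 1)")
  }
  if (p_det < 0 || p_det > 1) abort("cohort_config: p_det must be in [0, 1]")
  bad <- pattern_freqs %>%
    group_by(.data$cluster) %>%
    summarise(total = sum(.data$freq), .groups = "drop") %>%
    filter(.data$total > 1)
  if (nrow(bad) > 0) {
    abort(sprintf("cohort_config: event frequencies exceed 1 for cluster(s): %s",
                  paste(bad$cluster, collapse = ", ")))
  }
  if (abs(sum(dup_group_freqs) - 1) > 1e-8) {
    abort("cohort_config: dup_group_freqs must sum to 1")
  }
  if (n_planted_phenotypes > n_phenotypes) {
    abort("cohort_config: more planted than total phenotype variables")
  }
  structure(cfg, class = "cohort_config")
}

# synthetic genome-wide TS/CYP complement: a subset of TSs has CYPs placed
# within pairing distance; everything else is isolated
simulate_ts_cyp_genome <- function(n_ts, n_cyp, n_paired_ts = 18, n_paired_cyp = 27) {
  chroms <- paste0("chr", 1:5)
  gene <- function(id, chrom, start, category) {
    tibble(
      gene_id = id, chrom = chrom, start = start, end = start + 3000,
      strand = "+", category = category, cluster = NA_character_, role = "member"
    )
  }
  ts_rows <- list()
  cyp_rows <- list()
  # paired TSs at 200-kb spacing, each with 1-2 nearby CYPs
  cyp_left <- n_paired_cyp
  for (i in seq_len(n_paired_ts)) {
    chrom <- chroms[(i - 1) %% 5 + 1]
    pos <- 1e6 + ((i - 1) %/% 5) * 200000
    ts_rows[[i]] <- gene(sprintf("TS%02d", i), chrom, pos, "TS")
    n_here <- min(cyp_left, if (i <= n_paired_cyp - n_paired_ts) 2 else 1)
    for (k in seq_len(n_here)) {
      cyp_id <- sprintf("CYPP%02d_%d", i, k)
      # within the 30-kb pairing window: gaps of 5 kb and 22 kb
      offset <- if (k == 1) 3000 + 5000 else 3000 + 22000
      cyp_rows[[length(cyp_rows) + 1]] <- gene(cyp_id, chrom, pos + offset, "CYP")
      cyp_left <- cyp_left - 1
    }
  }
  # nonpaired TSs and CYPs, isolated at 500-kb spacing far from the paired set
  for (i in seq_len(n_ts - n_paired_ts)) {
    chrom <- chroms[(i - 1) %% 5 + 1]
    pos <- 2e7 + ((i - 1) %/% 5) * 500000
    ts_rows[[n_paired_ts + i]] <- gene(sprintf("TSN%02d", i), chrom, pos, "TS")
  }
  for (i in seq_len(n_cyp - n_paired_cyp)) {
    chrom <- chroms[(i - 1) %% 5 + 1]
    pos <- 5e7 + ((i - 1) %/% 5) * 500000
    cyp_rows[[length(cyp_rows) + 1]] <- gene(sprintf("CYPN%03d", i), chrom, pos, "CYP")
  }
  ts <- bind_rows(ts_rows)
  cyp <- bind_rows(cyp_rows)
  exon_template <- function(g) {
    purrr::map2(g$chrom, g$start, function(ch, s) {
      tibble(chrom = ch, start = c(s + 100, s + 1400), end = c(s + 1000, s + 2600))
    })
  }
  ts$exons <- exon_template(ts)
  cyp$exons <- exon_template(cyp)
  list(ts = ts, cyp = cyp)
}

#' Generate a synthetic accession cohort with planted ground truth
#'
#' Produces every input the downstream pipeline consumes — RD, raw MLPA and
#' ddPCR measurement tables, a per-accession SNP genotype table at the
#' CYP705A2/BARS1 loci, a redundant noisy inversion-call table, phenotype
#' variables, plus the annotation and CNV catalog — together with the planted
#' truth (`$truth`) needed to score recovery. Deterministic given
#' `config$seed`.
#'
#' Measurement models: RD is `max(0, Normal(cn_apparent, sigma_rd))`; raw
#' MLPA intensity is `probe_efficiency * (cn_apparent/2) * LogNormal(0,
#' sigma_mlpa)` with a fixed per-probe efficiency (so per-probe median
#' normalization is genuinely required); ddPCR concentrations are constructed
#' so that control-gene normalization returns `max(0, cn_apparent +
#' Normal(0, sigma_ddpcr))`. `cn_apparent` is the copy number a mapping-based
#' assay sees; it equals the true copy number everywhere except at the
#' CYP705A2/BARS1/CYP705A3 loci of accessions carrying the divergent
#' duplicate pair (see [cross_mapping_rd_levels()]). Divergent duplicates
#' contribute `Binomial(round(exon_length * duplicate_divergence), p_det)`
#' heterozygous-coded exonic sites per locus in `PP-PP` accessions and the
#' same count homozygous-alternate in `AA-PP` accessions. Each planted
#' inversion emits 1-4 redundant calls with breakpoints jittered within
#' +/-500 bp, supporting reads 2-40, and at least one call above the score
#' filter; decoy calls violating the length/score filters are mixed in.
#'
#' @param config A [cohort_config()].
#' @return An object of class `mgc_cohort`: list with `config`, `annotation`,
#'   `clusters`, `cnv_catalog`, `ts_cyp`, `accessions`, `meta` (genetic-group
#'   labels), `rd`, `mlpa_raw`, `ddpcr` (with the `DCL1` control column and a
#'   `background` attribute), `snps`, `sv_calls`, `phenotypes`, and `truth`
#'   (list: `cn_true`, `cn_apparent`, `events`, `dup_group`, `inversion`,
#'   `planted_phenotypes`, `paired_genes`, `n_decoys`).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  annotation <- mgc_annotation()
  clusters <- cluster_definitions(annotation)
  if (nrow(clusters) == 0) abort("generate_cohort: empty cluster set")
  cnv_catalog <- default_cnv_catalog(clusters)
  n <- cfg$n_accessions
  accs <- sprintf("acc_%04d", seq_len(n))

  genetic_groups <- c(
    "Germany" = 0.17, "CentralEurope" = 0.20, "NorthSweden" = 0.08,
    "SouthSweden" = 0.12, "Spain" = 0.12, "ItalyBalkanCaucasus" = 0.12,
    "Relict" = 0.03, "Asia" = 0.06, "USA" = 0.10, "WesternEurope" = 0.0
  )
  genetic_groups["WesternEurope"] <- 1 - sum(genetic_groups)
  meta <- tibble(
    accession = accs,
    group = sample(names(genetic_groups), n, replace = TRUE, prob = genetic_groups)
  )

  ## --- planted copy-number state -------------------------------------------
  mgc_genes <- annotation$gene_id[annotation$role != "noncoding"]
  effects <- event_effects()
  cn_true <- matrix(2, nrow = n, ncol = length(mgc_genes),
                    dimnames = list(accs, mgc_genes))

  events <- purrr::map_dfr(unique(cfg$pattern_freqs$cluster), function(cl) {
    ev <- cfg$pattern_freqs[cfg$pattern_freqs$cluster == cl, ]
    draw <- sample(
      c(ev$label, "REF"), n, replace = TRUE,
      prob = c(ev$freq, 1 - sum(ev$freq))
    )
    tibble(accession = accs, cluster = cl, label = draw)
  })
  for (i in seq_len(nrow(events))) {
    lab <- events$label[i]
    if (lab == "REF") next
    eff <- effects[[lab]]
    cn_true[events$accession[i], names(eff)] <- ifelse(eff == "LOSS", 0, 4)
  }

  dup_group <- sample(names(cfg$dup_group_freqs), n, replace = TRUE,
                      prob = cfg$dup_group_freqs)
  names(dup_group) <- accs
  cn_apparent <- cn_true
  pav_genes <- c("CYP705A2", "BARS1", "CYP705A3")
  for (g in names(cfg$dup_group_freqs)) {
    idx <- which(dup_group == g)
    if (length(idx) == 0) next
    lv <- cross_mapping_rd_levels(g)
    cn_apparent[idx, pav_genes] <- matrix(rep(lv, each = length(idx)), ncol = 3)
    cn_true[idx, pav_genes] <- switch(g,
      "PP-AA" = matrix(rep(c(2, 2, 2), each = length(idx)), ncol = 3),
      "PP-PP" = matrix(rep(c(4, 4, 2), each = length(idx)), ncol = 3),
      "AA-PP" = matrix(rep(c(0, 0, 0), each = length(idx)), ncol = 3),
      "AA-AA" = matrix(rep(c(0, 0, 0), each = length(idx)), ncol = 3)
    )
  }

  ## --- genome-wide TS/CYP complement ---------------------------------------
  ts_cyp <- NULL
  paired_genes <- character(0)
  if (cfg$ts_cyp) {
    ts_cyp <- simulate_ts_cyp_genome(cfg$n_ts, cfg$n_cyp)
    pairs0 <- find_ts_cyp_pairs(ts_cyp$ts, ts_cyp$cyp)
    paired_genes <- unique(c(pairs0$ts, pairs0$cyp))
    gw_genes <- c(ts_cyp$ts$gene_id, ts_cyp$cyp$gene_id)
    p_gene <- ifelse(gw_genes %in% paired_genes,
                     cfg$paired_variability, cfg$nonpaired_variability)
    gw_cn <- matrix(2, nrow = n, ncol = length(gw_genes),
                    dimnames = list(accs, gw_genes))
    carrier <- matrix(rbinom(n * length(gw_genes), 1,
                             rep(p_gene, each = n)) == 1,
                      nrow = n)
    # planted CNVs split between losses and gains
    gain <- matrix(rbinom(n * length(gw_genes), 1, 0.3) == 1, nrow = n)
    gw_cn[carrier & gain] <- 4
    gw_cn[carrier & !gain] <- 0
    cn_true <- cbind(cn_true, gw_cn)
    cn_apparent <- cbind(cn_apparent, gw_cn)
  }

  ## --- measurement tables ---------------------------------------------------
  all_genes <- colnames(cn_apparent)
  rd_mat <- cn_apparent + matrix(rnorm(length(cn_apparent), 0, cfg$sigma_rd),
                                 nrow = n)
  rd_mat[rd_mat < 0] <- 0
  rd <- dplyr::bind_cols(tibble(accession = accs), as_tibble(rd_mat))

  mlpa_accs <- sort(sample(accs, max(2, round(cfg$mlpa_fraction * n))))
  probe_eff <- rlnorm(length(mgc_genes), meanlog = 0, sdlog = 0.4)
  names(probe_eff) <- mgc_genes
  mlpa_mat <- sapply(mgc_genes, function(g) {
    probe_eff[g] * (cn_apparent[mlpa_accs, g] / 2) *
      rlnorm(length(mlpa_accs), 0, cfg$sigma_mlpa)
  })
  mlpa_raw <- dplyr::bind_cols(tibble(accession = mlpa_accs),
                               as_tibble(as.data.frame(mlpa_mat)))

  ddpcr_accs <- sort(sample(accs, max(2, round(cfg$ddpcr_fraction * n))))
  background <- 5
  control_net <- 100 * rlnorm(length(ddpcr_accs), 0, 0.05)
  cn_hat <- cn_apparent[ddpcr_accs, mgc_genes, drop = FALSE] +
    matrix(rnorm(length(ddpcr_accs) * length(mgc_genes), 0, cfg$sigma_ddpcr),
           nrow = length(ddpcr_accs))
  cn_hat[cn_hat < 0] <- 0
  dd_mat <- background + control_net * cn_hat / 2
  ddpcr <- dplyr::bind_cols(
    tibble(accession = ddpcr_accs),
    as_tibble(as.data.frame(dd_mat)),
    tibble(DCL1 = background + control_net)
  )
  attr(ddpcr, "background") <- background

  ## --- SNP genotypes at the paralog pair ------------------------------------
  pair_genes <- annotation[annotation$gene_id %in% c("CYP705A2", "BARS1"), ]
  n_div <- round(cfg$exon_length * cfg$duplicate_divergence)
  snps <- purrr::map_dfr(seq_len(nrow(pair_genes)), function(i) {
    ex <- pair_genes$exons[[i]]
    exonic_pos <- unlist(purrr::map2(ex$start, ex$end - 1, seq.int))
    target <- exonic_pos[seq_len(min(cfg$exon_length, length(exonic_pos)))]
    div_pos <- sort(sample(target, n_div))
    # background population SNPs: homozygous in a random minority of accessions
    bg_pos <- sort(sample(setdiff(target, div_pos), 4))
    gt <- matrix("0/0", nrow = n_div + 4, ncol = n,
                 dimnames = list(NULL, accs))
    for (g in c("PP-PP", "AA-PP")) {
      idx <- which(dup_group == g)
      if (length(idx) == 0) next
      det <- matrix(runif(n_div * length(idx)) < cfg$p_det, nrow = n_div)
      gt[seq_len(n_div), idx][det] <- if (g == "PP-PP") "0/1" else "1/1"
    }
    # AA-AA accessions have no coverage at either locus: all calls missing
    gt[, dup_group == "AA-AA"] <- "./."
    for (b in seq_along(bg_pos)) {
      af <- runif(1, 0.05, 0.3)
      hom <- runif(n) < af & dup_group != "AA-AA"
      gt[n_div + b, hom] <- "1/1"
    }
    site_pos <- c(div_pos, bg_pos)
    n_pos <- length(site_pos)
    tibble(
      chrom = pair_genes$chrom[i],
      pos = rep(site_pos, times = n),
      ref = "A",
      alt = "G",
      accession = rep(accs, each = n_pos),
      gt = as.vector(gt)
    )
  })
  # decoy records the biallelic/SNP filters must exclude: one multi-allelic
  # site and one indel, heterozygous-coded in every accession
  decoy_defs <- tibble(
    chrom = pair_genes$chrom[1],
    pos = pair_genes$exons[[1]]$start[1] + c(3, 7),
    ref = c("A", "AT"),
    alt = c("G,T", "A")
  )
  decoy_sites <- tidyr::expand_grid(decoy_defs, accession = accs)
  decoy_sites$gt <- "0/1"
  snps <- bind_rows(snps, decoy_sites)

  ## --- inversion calls ------------------------------------------------------
  inv_region <- thalianol_inversion_region(annotation)
  inverted <- runif(n) < cfg$inversion_freq
  sv_rows <- list()
  n_decoys <- 0
  for (i in seq_len(n)) {
    if (inverted[i]) {
      k <- sample(1:4, 1)
      starts <- inv_region$start + round(runif(k, -500, 500))
      ends <- inv_region$end + round(runif(k, -500, 500))
      scores <- c(runif(1, 36, 99), if (k > 1) runif(k - 1, 20, 99))
      sv_rows[[length(sv_rows) + 1]] <- tibble(
        accession = accs[i], chrom = inv_region$chrom,
        start = starts, end = ends, sv_type = "INV",
        score = round(scores), supporting_reads = sample(2:40, k, replace = TRUE)
      )
    }
    # decoys violating the length or score filters
    if (runif(1) < 0.3) {
      kind <- sample(3, 1)
      decoy <- switch(kind,
        tibble(start = inv_region$start, end = inv_region$start + 300,
               score = 80), # too short
        tibble(start = inv_region$start - 20000, end = inv_region$start + 40000,
               score = 80), # too long
        tibble(start = inv_region$start + 100, end = inv_region$end - 100,
               score = sample(5:35, 1)) # below score cutoff
      )
      n_decoys <- n_decoys + 1
      sv_rows[[length(sv_rows) + 1]] <- tibble(
        accession = accs[i], chrom = inv_region$chrom,
        start = decoy$start, end = decoy$end, sv_type = "INV",
        score = decoy$score, supporting_reads = sample(2:40, 1)
      )
    }
  }
  sv_calls <- bind_rows(sv_rows)

  ## --- phenotypes -----------------------------------------------------------
  planted_vars <- sprintf("planted_%02d", seq_len(cfg$n_planted_phenotypes))
  noise_vars <- sprintf("noise_%02d",
                        seq_len(cfg$n_phenotypes - cfg$n_planted_phenotypes))
  shift <- cfg$phenotype_effect * (dup_group == "PP-PP")
  pheno <- dplyr::bind_cols(
    tibble(accession = accs),
    as_tibble(setNames(
      purrr::map(planted_vars, ~ rnorm(n) + shift),
      planted_vars
    )),
    as_tibble(setNames(purrr::map(noise_vars, ~ rnorm(n)), noise_vars))
  )

  structure(
    list(
      config = cfg,
      annotation = annotation,
      clusters = clusters,
      cnv_catalog = cnv_catalog,
      ts_cyp = ts_cyp,
      accessions = accs,
      meta = meta,
      rd = rd,
      mlpa_raw = mlpa_raw,
      ddpcr = ddpcr,
      snps = snps,
      sv_calls = sv_calls,
      phenotypes = pheno,
      truth = list(
        cn_true = cn_true,
        cn_apparent = cn_apparent,
        events = events,
        dup_group = tibble(accession = accs, group = unname(dup_group)),
        inversion = tibble(accession = accs, inverted = inverted),
        planted_phenotypes = planted_vars,
        paired_genes = paired_genes,
        n_decoys = n_decoys
      )
    ),
    class = "mgc_cohort"
  )
}

#' The thalianol-cluster inversion region
#'
#' The interval spanning AT5G47950 and the two intervening genes RABA4C and
#' AT5G47970 — the segment whose inversion converts the reference-like
#' discontiguous cluster into the compact haplotype.
#'
#' @param annotation Gene tibble from [mgc_annotation()].
#' @return A one-row interval tibble.
#' @export
thalianol_inversion_region <- function(annotation = mgc_annotation()) {
  g <- annotation[annotation$gene_id %in% c("AT5G47950", "RABA4C", "AT5G47970"), ]
  tibble(chrom = g$chrom[1], start = min(g$start), end = max(g$end))
}

#' Planted genotype statuses of a synthetic cohort
#'
#' The REF/LOSS/GAIN status a noiseless mapping-based assay would report,
#' derived from the apparent copy-number level with the RD thresholds
#' (including the BARS1 offset). This is the reference truth for scoring
#' genotype recovery; the biological truth at the cryptic-duplication loci
#' lives in `truth$dup_group` and `truth$cn_true`.
#'
#' @param cohort An `mgc_cohort`.
#' @param thresholds Threshold list ([default_thresholds()]).
#' @return Long tibble: `accession`, `gene`, `status`.
#' @export
planted_statuses <- function(cohort, thresholds = default_thresholds()) {
  cn <- cohort$truth$cn_apparent
  long <- tibble(
    accession = rep(rownames(cn), times = ncol(cn)),
    gene = rep(colnames(cn), each = nrow(cn)),
    value = as.vector(cn)
  )
  off <- thresholds$rd_offset[long$gene]
  off[is.na(off)] <- 0
  long$status <- status_from_value(long$value,
                                   thresholds$rd_loss + off,
                                   thresholds$rd_gain + off)
  long[, c("accession", "gene", "status")]
}

#' @export
print.mgc_cohort <- function(x, ...) {
  cat("<mgc_cohort> ", length(x$accessions), " accessions, seed ",
      x$config$seed, "\n", sep = "")
  cat("  genes: ", ncol(x$truth$cn_true), " (",
      sum(!is.na(x$annotation$cluster)), " in clusters)\n", sep = "")
  cat("  SV calls: ", nrow(x$sv_calls), "; SNP records: ", nrow(x$snps),
      "\n", sep = "")
  invisible(x)
}

#' Write every cohort input to disk in its standard format
#'
#' Writes RD/MLPA/ddPCR matrices (TSV), gene models (GFF3), CNV catalog
#' (BED), SNP genotypes (VCF), inversion calls (BreakDancer-style TSV),
#' phenotypes and metadata (TSV) into `dir`. The generating seed is recorded
#' in every header that supports comments.
#'
#' @param cohort An `mgc_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed_line <- sprintf("seed=%d", cohort$config$seed)
  write_measurements(cohort$rd, file.path(dir, "rd.tsv"), header = seed_line)
  write_measurements(cohort$mlpa_raw, file.path(dir, "mlpa_raw.tsv"), header = seed_line)
  write_measurements(cohort$ddpcr, file.path(dir, "ddpcr.tsv"), header = seed_line)
  write_bed(cohort$cnv_catalog, file.path(dir, "cnv_regions.bed"))
  write_gene_models(cohort$annotation, file.path(dir, "genes.gff3"))
  write_snp_genotypes(cohort$snps, file.path(dir, "snps.vcf"), header = seed_line)
  write_sv_calls(cohort$sv_calls, file.path(dir, "sv_calls.tsv"))
  write_phenotypes(cohort$phenotypes, file.path(dir, "phenotypes.tsv"), header = seed_line)
  readr::write_tsv(cohort$meta, file.path(dir, "accessions.tsv"))
  invisible(dir)
}
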