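test_that("small-sample Wilcoxon matches exact enumeration", {
  # total separation of 3 vs 3: one extreme tail among C(6,3)=20 assignments,
  # two-sided p = 2/20
  w <- wilcoxon_ct(c(1, 2, 3), c(4, 5, 6))
  expect_true(w$exact)
  expect_equal(w$p_value, 0.1)
  expect_equal(w$statistic, 0)

  # random small samples against the enumeration oracle
  set.seed(13)
  for (i in 1:25) {
    nx <- sample(2:8, 1)
    ny <- sample(2:8, 1)
    x <- sample(1:1000, nx) / 10 # distinct values, no ties
    y <- sample(1001:2000, ny) / 10 + runif(ny)
    xy <- sample(c(x, y))
    x2 <- xy[seq_len(nx)]
    y2 <- xy[-seq_len(nx)]
    expect_equal(wilcoxon_ct(x2, y2)$p_value, oracle_wilcoxon_exact(x2, y2),
                 tolerance = 1e-10)
  }
})

test_that("identical or fully tied samples give p = 1", {
  expect_equal(wilcoxon_ct(c(5, 5, 5), c(5, 5))$p_value, 1)
  x <- c(1.2, 3.4, 5.6)
  expect_equal(wilcoxon_ct(x, x)$p_value, 1)
})

test_that("exact and approximate Wilcoxon p-values agree for moderate n", {
  set.seed(17)
  diffs <- vapply(1:20, function(i) {
    x <- rnorm(8)
    y <- rnorm(8, mean = runif(1, 0, 1.5))
    p_exact <- oracle_wilcoxon_exact(x, y)
    ht <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
    abs(p_exact - ht$p.value)
  }, numeric(1))
  # the continuity-corrected normal approximation tracks the exact null to
  # about 1e-2 in p for 8-vs-8 samples
  expect_lt(median(diffs), 1e-2)
  expect_lt(max(diffs), 2e-2)
})

test_that("a large planted shift is detected with overwhelming significance", {
  set.seed(29)
  x <- rnorm(100)
  y <- rnorm(100, mean = 1)
  expect_lt(wilcoxon_ct(x, y)$p_value, 1e-6)
})

test_that("Kruskal-Wallis H matches the hand-computed rank-sum value", {
  # groups {1,2},{3,4},{5,6}: ranks are the values themselves; no ties, so
  # H = 12/(N(N+1)) * sum(n_i * Rbar_i^2) - 3(N+1)
  #   = 12/42 * (2*1.5^2 + 2*3.5^2 + 2*5.5^2) - 21 = 32/7
  res <- kw_dunn_bh(c(1, 2, 3, 4, 5, 6), rep(c("a", "b", "c"), each = 2))
  expect_equal(res$omnibus$statistic, 32 / 7)
  expect_equal(res$omnibus$df, 2)

  # Dunn z for the same data, frozen from the pooled-rank formula:
  # se = sqrt((N(N+1)/12)(1/2+1/2)) = sqrt(3.5); mean ranks 1.5/3.5/5.5
  se <- sqrt(3.5)
  expect_equal(res$pairwise$z, c(-2, -4, -2) / se, tolerance = 1e-12)
  # BH over the pairwise family is monotone and >= raw
  expect_true(all(res$pairwise$p_adj >= res$pairwise$p_raw))
  o <- order(res$pairwise$p_raw)
  expect_true(all(diff(res$pairwise$p_adj[o]) >= -1e-12))
})

test_that("identical groups give a null omnibus and adjusted >= raw p-values", {
  set.seed(7)
  v <- rep(rnorm(6), 3)
  g <- rep(c("a", "b", "c"), each = 6)
  res <- kw_dunn_bh(v, g)
  expect_gt(res$omnibus$p_value, 0.9)
  expect_true(all(res$pairwise$p_adj >= res$pairwise$p_raw))
})

test_that("BH step-up reproduces the hand-computed adjustment", {
  # raw (0.01, 0.02, 0.03) -> min over j>=i of p_j * m / j = (0.03, 0.03, 0.03)
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3))
  # BH inside kw_dunn_bh agrees with the step-up formula applied directly
  set.seed(11)
  res <- kw_dunn_bh(rnorm(30), rep(c("a", "b", "c"), each = 10))
  m <- nrow(res$pairwise)
  o <- order(res$pairwise$p_raw, decreasing = TRUE)
  stepup <- cummin(res$pairwise$p_raw[o] * m / rev(seq_len(m)))
  expect_equal(res$pairwise$p_adj[o], pmin(1, stepup))
})

test_that("Kruskal-Wallis requires valid group structure", {
  expect_error(kw_dunn_bh(1:4, c("a", "a", "b", "b")), ">= 3 groups")
  expect_error(kw_dunn_bh(1:5, c("a", "a", "b", "b", "c")), ">= 2 observations")
})

test_that("two-group Kruskal-Wallis agrees with the Wilcoxon approximation", {
  # with k = 2 the KW statistic is the square of the Wilcoxon z, so the
  # p-values agree up to the continuity correction
  set.seed(19)
  x <- rnorm(30)
  y <- rnorm(30, 0.5)
  kw <- kruskal.test(c(x, y), rep(c("a", "b"), each = 30))
  w <- wilcoxon_ct(x, y)
  expect_lt(abs(kw$p.value - w$p_value), 0.01)
})

test_that("the phenotype scan recovers planted effects at a controlled error rate", {
  set.seed(43)
  n <- 100
  accs <- paste0("a", seq_len(n))
  groups <- tibble::tibble(accession = accs,
                           group = rep(c("PP-AA", "PP-PP"), each = n / 2))
  shift <- rep(c(0, 1.2), each = n / 2)
  pheno <- tibble::tibble(accession = accs)
  for (v in paste0("planted_", 1:10)) pheno[[v]] <- rnorm(n) + shift
  for (v in paste0("noise_", 1:100)) pheno[[v]] <- rnorm(n)
  res <- phenotype_scan(pheno, groups, alpha = 0.05)
  hits <- res$variable[res$significant]
  expect_true(all(paste0("planted_", 1:10) %in% hits))
  n_false <- sum(grepl("^noise_", hits))
  expect_lte(n_false, qbinom(0.995, 100, 0.05))
})

test_that("the all-noise scan keeps the type-I rate within binomial bounds", {
  set.seed(47)
  n <- 200
  accs <- paste0("a", seq_len(n))
  groups <- tibble::tibble(accession = accs,
                           group = rep(c("g1", "g2"), each = n / 2))
  pheno <- tibble::tibble(accession = accs)
  for (v in paste0("noise_", 1:100)) pheno[[v]] <- rnorm(n)
  res <- phenotype_scan(pheno, groups, alpha = 0.05)
  n_sig <- sum(res$significant)
  bounds <- qbinom(c(0.005, 0.995), 100, 0.05)
  expect_gte(n_sig, bounds[1])
  expect_lte(n_sig, bounds[2])
})

test_that("degenerate scan variables are skipped, constant variables not significant", {
  accs <- paste0("a", 1:10)
  groups <- tibble::tibble(accession = accs, group = rep(c("g1", "g2"), each = 5))
  pheno <- tibble::tibble(
    accession = accs,
    constant = rep(1, 10),
    sparse = c(1, NA, NA, NA, NA, 2, NA, NA, NA, NA)
  )
  expect_message(res <- phenotype_scan(pheno, groups), "skipped")
  expect_equal(attr(res, "skipped"), "sparse")
  expect_false(res$significant[res$variable == "constant"])
})
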