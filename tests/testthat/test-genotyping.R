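test_that("MLPA normalization forces per-probe medians of exactly 2", {
  raw <- tibble::tibble(
    accession = c("a1", "a2", "a3"),
    g1 = c(2, 4, 6),
    g2 = c(5, 5, 5)
  )
  norm <- normalize_mlpa(raw)
  expect_equal(norm$g1, c(1, 2, 3))
  expect_equal(norm$g2, c(2, 2, 2))

  # even n: median is the mean of the middle pair (here 5)
  raw4 <- tibble::tibble(accession = paste0("a", 1:4), g = c(1, 2, 8, 9))
  expect_equal(normalize_mlpa(raw4)$g, c(0.4, 0.8, 3.2, 3.6))

  # medians equal 2 to machine precision on arbitrary positive data
  set.seed(1)
  big <- tibble::tibble(accession = paste0("a", 1:101))
  for (g in paste0("g", 1:10)) big[[g]] <- rlnorm(101, 0, 1)
  out <- normalize_mlpa(big)
  for (g in paste0("g", 1:10)) {
    expect_equal(median(out[[g]]), 2, tolerance = 1e-15)
  }
})

test_that("MLPA probes with non-positive median are flagged unusable", {
  raw <- tibble::tibble(accession = c("a1", "a2", "a3"), g1 = c(0, 0, 5))
  expect_warning(out <- normalize_mlpa(raw), "non-positive median")
  expect_true(all(is.na(out$g1)))
})

test_that("ddPCR normalization matches the control-relative formula", {
  expect_equal(normalize_ddpcr(100, 100, 0), 2)
  expect_equal(normalize_ddpcr(0, 100, 0), 0)
  expect_equal(normalize_ddpcr(220, 100, 20), 5)
  expect_warning(out <- normalize_ddpcr(50, 10, 20), "control <= background")
  expect_true(is.na(out))
})

test_that("platform calls honour the exact <=/> boundary semantics", {
  th <- default_thresholds()
  rd <- tibble::tibble(
    accession = paste0("a", 1:4),
    THAS1 = c(1.0, 1.001, 3.4, 3.401)
  )
  out <- call_genotypes(rd, "RD", th)
  expect_equal(out$status, c("LOSS", "REF", "REF", "GAIN"))

  # BARS1: both thresholds lowered by 0.2
  bars <- tibble::tibble(
    accession = paste0("a", 1:5),
    BARS1 = c(0.8, 0.801, 3.2, 3.201, 3.3)
  )
  out_b <- call_genotypes(bars, "RD", th)
  expect_equal(out_b$status, c("LOSS", "REF", "REF", "GAIN", "GAIN"))

  mlpa <- tibble::tibble(accession = paste0("a", 1:4), g = c(1.0, 2.0, 3.0, 3.001))
  expect_equal(call_genotypes(mlpa, "MLPA", th)$status,
               c("LOSS", "REF", "REF", "GAIN"))

  dd <- tibble::tibble(accession = paste0("a", 1:4), g = c(0, 1.5, 2, 3.2))
  expect_equal(call_genotypes(dd, "DDPCR", th)$status,
               c("LOSS", "REF", "REF", "GAIN"))

  expect_error(
    call_genotypes(tibble::tibble(accession = "a", g = -1), "RD", th),
    "negative"
  )
})

test_that("missing measurements give NA status and borderline values are flagged", {
  rd <- tibble::tibble(accession = c("a1", "a2"), g = c(NA, 1.04))
  out <- call_genotypes(rd, "RD")
  expect_true(is.na(out$status[1]))
  expect_equal(out$status[2], "REF")
  expect_true(out$borderline[2]) # within 0.05 of the loss threshold
})

test_that("integration resolves agreement, conflict and priority correctly", {
  mk <- function(platform, status) {
    tibble::tibble(accession = "a1", gene = "g1", platform = platform,
                   value = 1, status = status, borderline = FALSE)
  }
  agree <- integrate_genotypes(mk("RD", "LOSS"), mk("MLPA", "LOSS"))
  expect_equal(agree$calls$status, "LOSS")
  expect_equal(agree$concordance$n_multi, 1)
  expect_equal(agree$concordance$n_discordant, 0)

  conflict <- integrate_genotypes(mk("RD", "REF"), mk("MLPA", "GAIN"))
  expect_equal(conflict$calls$status, "CONFLICT")
  expect_equal(conflict$concordance$n_discordant, 1)
  expect_equal(nrow(conflict$concordance$discordant), 1)

  prio <- integrate_genotypes(mk("RD", "REF"), mk("MLPA", "GAIN"), mk("DDPCR", "GAIN"),
                              policy = "priority")
  expect_equal(prio$calls$status, "GAIN")
  # still listed for review
  expect_equal(nrow(prio$concordance$discordant), 1)

  # NA platform calls are ignored, not conflicting
  na_call <- tibble::tibble(accession = "a1", gene = "g1", platform = "MLPA",
                            value = NA_real_, status = NA_character_,
                            borderline = FALSE)
  one <- integrate_genotypes(mk("RD", "LOSS"), na_call)
  expect_equal(one$calls$status, "LOSS")
  expect_equal(one$concordance$n_multi, 0)
})

test_that("integration is invariant to platform order", {
  set.seed(5)
  statuses <- c("REF", "LOSS", "GAIN")
  cells <- tidyr::expand_grid(accession = paste0("a", 1:6), gene = paste0("g", 1:4))
  calls <- purrr::map(c("RD", "MLPA", "DDPCR"), function(p) {
    dplyr::mutate(cells, platform = p, value = 1,
                  status = sample(statuses, dplyr::n(), replace = TRUE),
                  borderline = FALSE)
  })
  a <- integrate_genotypes(calls[[1]], calls[[2]], calls[[3]])
  b <- integrate_genotypes(calls[[3]], calls[[1]], calls[[2]])
  expect_equal(a$calls, b$calls)
  expect_equal(a$concordance$n_discordant, b$concordance$n_discordant)
})

test_that("concordance fraction matches the published arithmetic", {
  rep_ <- function(multi, conc) {
    list(n_multi = multi, n_concordant = conc, n_discordant = multi - conc,
         discordant = tibble::tibble())
  }
  expect_equal(round(concordance_fraction(rep_(1784, 1763)), 1), 98.8)
  expect_equal(concordance_fraction(rep_(10, 10)), 100)
  expect_equal(concordance_fraction(rep_(3, 1)), 100 / 3)
  expect_true(is.na(concordance_fraction(rep_(0, 0))))
})
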