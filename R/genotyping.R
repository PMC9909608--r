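#' Default genotype-calling thresholds
#'
#' The boundary semantics are exactly those used for the published genotype
#' assignments: a measurement less than or equal to the loss threshold is
#' called LOSS; a measurement strictly greater than the gain threshold is
#' called GAIN; everything in between is REF. Read-depth (RD) thresholds are
#' 1.0 / 3.4, lowered by 0.2 for BARS1 (whose mapped depth runs low because
#' the gene lacks its largest, repeat-containing intron in most accessions);
#' MLPA thresholds are 1.0 / 3.0 on median-normalized values. ddPCR calls use
#' normalized copy number < 1.5 for LOSS and > 3.0 for GAIN (the published
#' procedure states only CN = 0 -> LOSS and CN = 2 -> REF; the cutoffs adopted
#' here are consistent with the MLPA scale and are exposed for overriding).
#'
#' @param rd_offset Named numeric vector of per-gene additive offsets applied
#'   to both RD thresholds.
#' @param borderline_eps Half-width of the "borderline" flag window around
#'   each threshold; calls within it are flagged (never changed).
#' @return A list of thresholds consumed by [call_genotypes()].
#' @export
default_thresholds <- function(rd_offset = c(BARS1 = -0.2), borderline_eps = 0.05) {
  list(
    rd_loss = 1.0, rd_gain = 3.4, rd_offset = rd_offset,
    mlpa_loss = 1.0, mlpa_gain = 3.0,
    ddpcr_loss_max = 1.5, ddpcr_gain_min = 3.0,
    borderline_eps = borderline_eps
  )
}

#' Normalize raw MLPA peak intensities
#'
#' For each probe (gene column) separately, intensities are divided by the
#' median over all assayed samples and multiplied by 2, so that the median of
#' every normalized probe column equals exactly 2 (the diploid reference
#' level). Probes whose median is 0 (or undefined) cannot be normalized and
#' are set entirely missing, with a warning naming the probe.
#'
#' @param raw Wide measurement tibble (first column `accession`) of raw MLPA
#'   intensities.
#' @return A wide tibble of normalized values with the same shape.
#' @examples
#' raw <- tibble::tibble(accession = c("a1", "a2", "a3"), g1 = c(2, 4, 6))
#' normalize_mlpa(raw)
#' @export
normalize_mlpa <- function(raw) {
  stopifnot(names(raw)[1] == "accession")
  out <- raw
  for (g in names(raw)[-1]) {
    v <- raw[[g]]
    med <- median(v, na.rm = TRUE)
    if (!is.finite(med) || med <= 0) {
      warn(sprintf("normalize_mlpa: probe %s has non-positive median; set missing", g))
      out[[g]] <- NA_real_
    } else {
      out[[g]] <- 2 * v / med
    }
  }
  out
}

#' Normalize ddPCR concentrations against a control gene
#'
#' Computes copy number as `2 * (target - background) / (control -
#' background)`, floored at 0 — the target concentration relative to a
#' verified two-copy control gene (DCL1 in the published assays), after
#' subtracting the no-template-control background. Accessions whose control
#' concentration does not exceed the background cannot be normalized and
#' return `NA`.
#'
#' @param target,control Numeric vectors of measured concentrations
#'   (copies/ul), recycled to a common length.
#' @param background No-template-control concentration (scalar or vector).
#' @return Numeric vector of normalized copy numbers.
#' @examples
#' normalize_ddpcr(220, 100, background = 20) # 5
#' @export
normalize_ddpcr <- function(target, control, background = 0) {
  n <- max(length(target), length(control), length(background))
  target <- rep_len(target, n)
  control <- rep_len(control, n)
  background <- rep_len(background, n)
  ctrl_net <- control - background
  bad <- !is.na(ctrl_net) & ctrl_net <= 0
  if (any(bad)) {
    warn(sprintf("normalize_ddpcr: %d accession(s) with control <= background; set missing",
                 sum(bad)))
  }
  cn <- pmax(0, 2 * (target - background) / ctrl_net)
  cn[bad] <- NA_real_
  cn
}

# scalar/vector status assignment for one platform
status_from_value <- function(value, loss, gain) {
  dplyr::case_when(
    is.na(value) ~ NA_character_,
    value <= loss ~ "LOSS",
    value > gain ~ "GAIN",
    TRUE ~ "REF"
  )
}

#' Call REF/LOSS/GAIN genotypes from normalized measurements
#'
#' Applies the platform thresholds (see [default_thresholds()]) to a wide
#' measurement table. Boundary semantics: `<=` loss threshold gives LOSS,
#' strictly `>` gain threshold gives GAIN, otherwise REF. RD thresholds are
#' shifted by the per-gene offset where one is defined. Missing values give
#' `NA` status. Values within `borderline_eps` of a threshold are flagged in
#' the `borderline` column for review, mirroring the manual inspection of
#' near-threshold single-platform calls; flagged calls are never altered.
#'
#' @param values Wide tibble of normalized measurements (first column
#'   `accession`).
#' @param platform One of `"RD"`, `"MLPA"`, `"DDPCR"`.
#' @param thresholds Threshold list from [default_thresholds()].
#' @return Long tibble: `accession`, `gene`, `platform`, `value`, `status`,
#'   `borderline`.
#' @export
call_genotypes <- function(values, platform = c("RD", "MLPA", "DDPCR"),
                           thresholds = default_thresholds()) {
  platform <- match.arg(platform)
  stopifnot(names(values)[1] == "accession")
  long <- tidyr::pivot_longer(values, -"accession",
                              names_to = "gene", values_to = "value")
  if (any(long$value < 0, na.rm = TRUE)) {
    abort("call_genotypes: negative measurement values")
  }
  th <- thresholds
  if (platform == "RD") {
    off <- th$rd_offset[long$gene]
    off[is.na(off)] <- 0
    # rounding keeps offset thresholds exact at their printed precision
    # (3.4 - 0.2 must behave as 3.2, not 3.1999...)
    loss <- round(th$rd_loss + off, 9)
    gain <- round(th$rd_gain + off, 9)
  } else if (platform == "MLPA") {
    loss <- rep(th$mlpa_loss, nrow(long))
    gain <- rep(th$mlpa_gain, nrow(long))
  } else {
    # ddPCR loss cutoff is exclusive (< 1.5), handled by nudging the boundary
    loss <- rep(th$ddpcr_loss_max, nrow(long))
    gain <- rep(th$ddpcr_gain_min, nrow(long))
  }
  status <- if (platform == "DDPCR") {
    dplyr::case_when(
      is.na(long$value) ~ NA_character_,
      long$value < loss ~ "LOSS",
      long$value > gain ~ "GAIN",
      TRUE ~ "REF"
    )
  } else {
    status_from_value(long$value, loss, gain)
  }
  borderline <- !is.na(long$value) &
    (abs(long$value - loss) <= th$borderline_eps |
       abs(long$value - gain) <= th$borderline_eps)
  tibble(
    accession = long$accession,
    gene = long$gene,
    platform = platform,
    value = long$value,
    status = status,
    borderline = borderline
  )
}

#' Integrate per-platform genotype calls
#'
#' Combines the calls from one or more platforms into a final genotype per
#' accession and gene, with per-cell provenance and a concordance report.
#' Cells where all non-missing platform calls agree receive that status;
#' cells with conflicting calls receive `CONFLICT` under the default policy
#' (an auditable replacement for manual curation of discordant assignments),
#' or are resolved by platform priority ddPCR > MLPA > RD under
#' `policy = "priority"` — either way the cell is listed in the report.
#' The result is invariant to the order in which platforms are supplied.
#'
#' @param ... Long call tibbles from [call_genotypes()] (or one list of them).
#' @param policy `"conflict"` (default) or `"priority"`.
#' @return An object of class `cn_genotypes`: a list with `calls` (tibble
#'   `accession`, `gene`, `status`, `n_platforms`, `platforms`) and
#'   `concordance` (list with `n_multi`, `n_concordant`, `n_discordant`,
#'   `discordant` tibble).
#' @export
integrate_genotypes <- function(..., policy = c("conflict", "priority")) {
  policy <- match.arg(policy)
  inputs <- list(...)
  if (length(inputs) == 1 && !is.data.frame(inputs[[1]])) inputs <- inputs[[1]]
  all_calls <- bind_rows(inputs)
  stopifnot(all(c("accession", "gene", "platform", "status") %in% names(all_calls)))
  all_calls <- all_calls[!is.na(all_calls$status), , drop = FALSE]
  prio <- c(DDPCR = 1, MLPA = 2, RD = 3)

  per_cell <- all_calls %>%
    group_by(.data$accession, .data$gene) %>%
    summarise(
      n_platforms = n_distinct(.data$platform),
      platforms = paste(sort(unique(.data$platform)), collapse = ","),
      n_status = n_distinct(.data$status),
      agreed = first(.data$status[order(prio[.data$platform])]),
      detail = paste(
        paste0(.data$platform, ":", .data$status)[order(prio[.data$platform])],
        collapse = ";"
      ),
      .groups = "drop"
    )

  per_cell$status <- dplyr::if_else(
    per_cell$n_status > 1 & policy == "conflict",
    "CONFLICT",
    per_cell$agreed
  )

  discordant <- per_cell %>%
    filter(.data$n_status > 1) %>%
    select("accession", "gene", "detail")
  n_multi <- sum(per_cell$n_platforms >= 2)
  n_discordant <- sum(per_cell$n_status > 1 & per_cell$n_platforms >= 2)

  structure(
    list(
      calls = per_cell %>%
        select("accession", "gene", "status", "n_platforms", "platforms") %>%
        arrange(.data$accession, .data$gene),
      concordance = list(
        n_multi = n_multi,
        n_concordant = n_multi - n_discordant,
        n_discordant = n_discordant,
        discordant = discordant
      ),
      policy = policy
    ),
    class = "cn_genotypes"
  )
}

#' Percentage of multi-platform cells with fully concordant calls
#'
#' @param x A `cn_genotypes` object (or its `concordance` element).
#' @return Percentage in `[0, 100]`, or `NA` when no cell was genotyped by
#'   two or more platforms.
#' @export
concordance_fraction <- function(x) {
  cc <- if (inherits(x, "cn_genotypes")) x$concordance else x
  if (cc$n_multi == 0) {
    return(NA_real_)
  }
  100 * cc$n_concordant / cc$n_multi
}

#' @export
print.cn_genotypes <- function(x, ...) {
  cat("<cn_genotypes> ", n_distinct(x$calls$accession), " accessions x ",
      n_distinct(x$calls$gene), " genes\n", sep = "")
  cat("  policy: ", x$policy, "\n", sep = "")
  cf <- concordance_fraction(x)
  cat(sprintf(
    "  multi-platform cells: %d (%s concordant)\n",
    x$concordance$n_multi,
    ifelse(is.na(cf), "NA", sprintf("%.1f%%", cf))
  ))
  invisible(x)
}
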