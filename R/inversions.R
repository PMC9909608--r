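#' Filter raw structural-variant calls
#'
#' Retains calls whose length lies within `[min_len, max_len]` and whose
#' confidence score is strictly greater than `min_score` — the published
#' retention rule for inversion calls (0.5-50 kb, score > 35).
#'
#' @param calls SV call tibble (see [read_sv_calls()]).
#' @param min_len,max_len Inclusive length bounds in bp.
#' @param min_score Exclusive score threshold.
#' @return The retained subset of `calls`.
#' @export
filter_sv_calls <- function(calls, min_len = 500, max_len = 50000, min_score = 35) {
  len <- calls$end - calls$start
  calls[len >= min_len & len <= max_len & calls$score > min_score, , drop = FALSE]
}

# connected components under >=50% reciprocal overlap (transitive closure),
# via union-find; calls assumed same chromosome
overlap_components <- function(start, end, ro_min) {
  n <- length(start)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (n > 1) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        ov <- min(end[i], end[j]) - max(start[i], start[j])
        if (ov > 0 &&
            ov / (end[i] - start[i]) >= ro_min &&
            ov / (end[j] - start[j]) >= ro_min) {
          ri <- find(i)
          rj <- find(j)
          if (ri != rj) parent[ri] <- rj
        }
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

dedup_pass <- function(calls, ro_min) {
  if (nrow(calls) <= 1) {
    return(calls)
  }
  # deterministic processing order: descending score, then reads, then start
  calls <- calls[order(-calls$score, -calls$supporting_reads, calls$start, calls$end), ]
  comp <- overlap_components(calls$start, calls$end, ro_min)
  purrr::map_dfr(unique(comp), function(cid) {
    grp <- calls[comp == cid, , drop = FALSE]
    best <- grp[grp$score == max(grp$score), , drop = FALSE]
    best <- best[best$supporting_reads == max(best$supporting_reads), , drop = FALSE]
    if (nrow(best) == 1) {
      return(best)
    }
    # tie on score and reads: one variant with maximized coordinates
    merged <- best[1, , drop = FALSE]
    merged$start <- min(best$start)
    merged$end <- max(best$end)
    merged
  })
}

#' Minimize redundancy among overlapping SV calls
#'
#' Within each accession and chromosome, groups calls by transitive closure of
#' the reciprocal-overlap criterion (both overlap fractions at least
#' `ro_min`) and keeps, per group, the call with (i) the highest confidence
#' score, ties broken by (ii) the highest number of supporting reads;
#' remaining ties are replaced by a single call with maximized coordinates
#' (minimum start, maximum end) carrying the tied score and read count. The
#' procedure is run for `iterations` passes (two by default), regrouping the
#' survivors from scratch each pass so that merges created in pass one can be
#' resolved in pass two.
#'
#' @param calls Filtered SV call tibble; an `accession` column, when present,
#'   partitions the deduplication.
#' @param ro_min Reciprocal-overlap threshold (default 0.5).
#' @param iterations Number of passes (default 2).
#' @return The deduplicated call tibble.
#' @export
dedup_sv_calls <- function(calls, ro_min = 0.5, iterations = 2) {
  if (nrow(calls) == 0) {
    return(calls)
  }
  key_cols <- intersect(c("accession", "chrom"), names(calls))
  split_keys <- interaction(calls[key_cols], drop = TRUE)
  out <- purrr::map_dfr(split(calls, split_keys), function(grp) {
    for (k in seq_len(iterations)) grp <- dedup_pass(grp, ro_min)
    grp
  })
  rownames(out) <- NULL
  arrange(out, dplyr::across(any_of(c("accession", "chrom", "start"))))
}

#' Select calls overlapping a target region
#'
#' Retains calls with at least 1 bp of overlap with the target interval
#' (half-open semantics: a call ending exactly where the target starts does
#' not overlap).
#'
#' @param calls SV call tibble.
#' @param target One-row interval tibble.
#' @return The overlapping subset of `calls`.
#' @export
select_region <- function(calls, target) {
  validate_intervals(target, "select_region(target)")
  stopifnot(nrow(target) == 1)
  keep <- calls$chrom == target$chrom &
    calls$start < target$end & calls$end > target$start
  calls[keep, , drop = FALSE]
}

#' Per-accession inversion presence over a target region
#'
#' Runs the full call-processing chain (length/score filter, two-iteration
#' reciprocal-overlap deduplication, target-region selection) and reports for
#' each accession whether an inversion call survives — i.e. whether the
#' accession carries the rearranged (compact) version of the region rather
#' than the reference-like (discontiguous) one.
#'
#' @param calls Raw SV call tibble with an `accession` column.
#' @param target One-row interval tibble (the region of interest).
#' @param accessions Character vector of all assayed accessions (so that
#'   accessions with no surviving call are reported as not inverted).
#' @inheritParams filter_sv_calls
#' @inheritParams dedup_sv_calls
#' @return A tibble: `accession`, `inverted` (logical).
#' @export
inversion_presence <- function(calls, target, accessions,
                               min_len = 500, max_len = 50000, min_score = 35,
                               ro_min = 0.5, iterations = 2) {
  stopifnot("accession" %in% names(calls))
  kept <- calls %>%
    filter_sv_calls(min_len = min_len, max_len = max_len, min_score = min_score) %>%
    dedup_sv_calls(ro_min = ro_min, iterations = iterations) %>%
    select_region(target)
  tibble(
    accession = accessions,
    inverted = accessions %in% unique(kept$accession)
  )
}
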