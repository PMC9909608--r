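#' Construct a tibble of genomic intervals
#'
#' Intervals are 0-based, half-open `[start, end)` — the BED convention — and
#' are used for every region the package touches: cluster spans, CNV regions,
#' genes, exons and structural-variant calls. Conversion to and from 1-based
#' inclusive coordinates (GFF3) happens only in the readers and writers.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer-like vectors; `start < end` is required.
#' @return A tibble with columns `chrom`, `start`, `end`.
#' @examples
#' genomic_interval("chr5", 1000, 2000)
#' @export
genomic_interval <- function(chrom, start, end) {
  out <- tibble(
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end)
  )
  validate_intervals(out)
  out
}

#' Validate interval columns
#'
#' Checks that `start < end` for every record and that no coordinate is
#' missing. Called by every reader so coordinate-inverted records are rejected
#' at the I/O boundary.
#'
#' @param x A data frame with `chrom`, `start`, `end` columns.
#' @param context Label used in error messages (e.g. a file name).
#' @return `x`, invisibly, if valid.
#' @export
validate_intervals <- function(x, context = "interval") {
  required <- c("chrom", "start", "end")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "%s: missing column(s) %s",
      context, paste(missing_cols, collapse = ", ")
    ))
  }
  if (anyNA(x$start) || anyNA(x$end) || anyNA(x$chrom)) {
    abort(sprintf("%s: missing coordinates", context))
  }
  bad <- which(x$start >= x$end)
  if (length(bad) > 0) {
    abort(sprintf(
      "%s: start >= end at record(s) %s",
      context, paste(head(bad, 5), collapse = ", ")
    ))
  }
  invisible(x)
}

#' Reciprocal overlap of two interval sets
#'
#' For each row pair computes the overlap length divided by the length of each
#' interval — the standard criterion for merging structural-variant calls (two
#' calls "50% reciprocally overlap" when both fractions are at least 0.5).
#' Intervals on different chromosomes overlap by definition 0.
#'
#' @param a,b Data frames of intervals (`chrom`, `start`, `end`); rows are
#'   paired positionally and recycled if one has a single row.
#' @return A tibble with columns `frac_a` and `frac_b`, each in `[0, 1]`.
#' @examples
#' reciprocal_overlap(
#'   genomic_interval("c1", 0, 100),
#'   genomic_interval("c1", 50, 150)
#' )
#' @export
reciprocal_overlap <- function(a, b) {
  validate_intervals(a, "reciprocal_overlap(a)")
  validate_intervals(b, "reciprocal_overlap(b)")
  n <- max(nrow(a), nrow(b))
  if (nrow(a) == 1) a <- a[rep(1, n), ]
  if (nrow(b) == 1) b <- b[rep(1, n), ]
  if (nrow(a) != nrow(b)) {
    abort("reciprocal_overlap: row counts differ and neither is 1")
  }
  ov <- pmax(0, pmin(a$end, b$end) - pmax(a$start, b$start))
  ov[a$chrom != b$chrom] <- 0
  tibble(
    frac_a = ov / (a$end - a$start),
    frac_b = ov / (b$end - b$start)
  )
}

# Merge possibly overlapping intervals on one chromosome into disjoint runs.
merge_intervals <- function(start, end) {
  o <- order(start, end)
  start <- start[o]
  end <- end[o]
  ms <- numeric(0)
  me <- numeric(0)
  cur_s <- start[1]
  cur_e <- end[1]
  if (length(start) > 1) {
    for (i in 2:length(start)) {
      if (start[i] <= cur_e) {
        cur_e <- max(cur_e, end[i])
      } else {
        ms <- c(ms, cur_s)
        me <- c(me, cur_e)
        cur_s <- start[i]
        cur_e <- end[i]
      }
    }
  }
  list(start = c(ms, cur_s), end = c(me, cur_e))
}

#' Fraction of a target interval covered by a set of regions
#'
#' Computes the number of target bases falling inside the union of `regions`,
#' divided by the target length. Regions may overlap each other and extend past
#' the target; regions on other chromosomes are ignored; an empty region set
#' gives 0.
#'
#' @param target A one-row interval data frame.
#' @param regions An interval data frame (0 or more rows).
#' @return A single fraction in `[0, 1]`.
#' @examples
#' union_coverage(
#'   genomic_interval("c1", 0, 100),
#'   genomic_interval("c1", c(0, 25), c(50, 75))
#' )
#' @export
union_coverage <- function(target, regions) {
  validate_intervals(target, "union_coverage(target)")
  stopifnot(nrow(target) == 1)
  if (nrow(regions) == 0) {
    return(0)
  }
  validate_intervals(regions, "union_coverage(regions)")
  regions <- regions[regions$chrom == target$chrom, , drop = FALSE]
  if (nrow(regions) == 0) {
    return(0)
  }
  s <- pmax(regions$start, target$start)
  e <- pmin(regions$end, target$end)
  keep <- s < e
  if (!any(keep)) {
    return(0)
  }
  m <- merge_intervals(s[keep], e[keep])
  sum(m$end - m$start) / (target$end - target$start)
}
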