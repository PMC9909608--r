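# Independent brute-force oracles used to validate the package's interval
# arithmetic, SV deduplication and rank statistics. These deliberately use
# different algorithms (per-base counting, boolean-matrix closure, full
# enumeration) from the implementations they check.

# per-base union coverage of target by regions
oracle_union_coverage <- function(target, regions) {
  len <- target$end - target$start
  covered <- rep(FALSE, len)
  if (nrow(regions) > 0) {
    for (i in seq_len(nrow(regions))) {
      if (regions$chrom[i] != target$chrom) next
      s <- max(regions$start[i], target$start) - target$start + 1
      e <- min(regions$end[i], target$end) - target$start
      if (s <= e) covered[s:e] <- TRUE
    }
  }
  sum(covered) / len
}

# per-base reciprocal overlap of two single intervals
oracle_reciprocal <- function(a, b) {
  if (a$chrom != b$chrom) {
    return(c(0, 0))
  }
  bases_a <- seq.int(a$start, a$end - 1)
  ov <- sum(bases_a >= b$start & bases_a < b$end)
  c(ov / (a$end - a$start), ov / (b$end - b$start))
}

# literal re-implementation of the two-iteration dedup procedure:
# overlap closure by boolean matrix products, then rules (i)/(ii)/merge
oracle_dedup <- function(calls, ro_min = 0.5, iterations = 2) {
  one_pass <- function(cl) {
    n <- nrow(cl)
    if (n <= 1) return(cl)
    adj <- diag(TRUE, n)
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        fr <- oracle_reciprocal(cl[i, ], cl[j, ])
        if (fr[1] >= ro_min && fr[2] >= ro_min) adj[i, j] <- adj[j, i] <- TRUE
      }
    }
    repeat {
      nxt <- (adj %*% adj) > 0
      if (identical(nxt, adj)) break
      adj <- nxt
    }
    comp <- match(apply(adj, 1, paste, collapse = ""), unique(apply(adj, 1, paste, collapse = "")))
    out <- lapply(unique(comp), function(cid) {
      grp <- cl[comp == cid, , drop = FALSE]
      grp <- grp[grp$score == max(grp$score), , drop = FALSE]
      grp <- grp[grp$supporting_reads == max(grp$supporting_reads), , drop = FALSE]
      if (nrow(grp) > 1) {
        merged <- grp[1, , drop = FALSE]
        merged$start <- min(grp$start)
        merged$end <- max(grp$end)
        grp <- merged
      }
      grp
    })
    dplyr::bind_rows(out)
  }
  for (k in seq_len(iterations)) calls <- one_pass(calls)
  calls
}

# exact two-sided Wilcoxon rank-sum p-value by full enumeration of rank
# assignments (no ties assumed)
oracle_wilcoxon_exact <- function(x, y) {
  n <- length(x) + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  all_w <- apply(utils::combn(n, length(x)), 2, function(idx) {
    sum(idx) - length(x) * (length(x) + 1) / 2
  })
  mu <- length(x) * length(y) / 2
  min(1, mean(abs(all_w - mu) >= abs(w_obs - mu) - 1e-12))
}

# random SV call fixture on one chromosome
random_calls <- function(n, region_max = 100000) {
  start <- sample.int(region_max, n, replace = TRUE)
  len <- sample(500:20000, n, replace = TRUE)
  tibble::tibble(
    accession = "acc_1",
    chrom = "chr5",
    start = start,
    end = start + len,
    sv_type = "INV",
    score = sample(36:99, n, replace = TRUE),
    supporting_reads = sample(1:40, n, replace = TRUE)
  )
}

sort_calls <- function(x) {
  x <- x[order(x$start, x$end, x$score, x$supporting_reads),
         c("chrom", "start", "end", "score", "supporting_reads")]
  rownames(x) <- NULL
  tibble::as_tibble(x)
}
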