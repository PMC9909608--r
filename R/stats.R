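#' Wilcoxon rank-sum test with continuity correction
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test. For small samples
#' (`n_x + n_y <= 16`) without ties the exact null enumeration is used; in
#' all other cases the normal approximation with tie correction and
#' continuity correction is applied. Two samples that are completely tied
#' across both groups carry no rank information and return p = 1.
#'
#' @param x,y Numeric samples (each of length >= 1).
#' @return A list of class `wilcoxon_ct`: `statistic` (the rank-sum W for
#'   `x`), `p_value`, `n_x`, `n_y`, `exact` (logical).
#' @examples
#' wilcoxon_ct(c(1, 2, 3), c(4, 5, 6)) # exact two-sided p = 0.1
#' @export
wilcoxon_ct <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  stopifnot(length(x) >= 1, length(y) >= 1)
  if (length(unique(c(x, y))) == 1) {
    return(structure(
      list(statistic = length(x) * length(y) / 2, p_value = 1,
           n_x = length(x), n_y = length(y), exact = FALSE),
      class = "wilcoxon_ct"
    ))
  }
  ties <- any(duplicated(c(x, y)))
  use_exact <- (length(x) + length(y) <= 16) && !ties
  ht <- suppressWarnings(
    wilcox.test(x, y, exact = use_exact, correct = TRUE, alternative = "two.sided")
  )
  structure(
    list(
      statistic = unname(ht$statistic),
      p_value = min(1, ht$p.value),
      n_x = length(x), n_y = length(y),
      exact = use_exact
    ),
    class = "wilcoxon_ct"
  )
}

#' @export
print.wilcoxon_ct <- function(x, ...) {
  cat(sprintf(
    "Wilcoxon rank-sum (%s): W = %g, p = %.4g (n = %d, %d)\n",
    if (x$exact) "exact" else "normal approx., continuity-corrected",
    x$statistic, x$p_value, x$n_x, x$n_y
  ))
  invisible(x)
}

#' Kruskal-Wallis test with Dunn's post hoc comparisons and BH correction
#'
#' One-way rank-based analysis of variance: the Kruskal-Wallis omnibus test
#' (with tie correction, via [stats::kruskal.test()]) followed by Dunn's
#' pairwise z-tests on the pooled ranks, with Benjamini-Hochberg step-up
#' adjustment over the pairwise family. Dunn p-values are two-sided.
#'
#' @param values Numeric vector of observations.
#' @param groups Factor or character vector of group labels (>= 3 groups,
#'   each with >= 2 observations).
#' @return An object of class `kw_dunn`: list with `omnibus` (tibble
#'   `statistic`, `df`, `p_value`) and `pairwise` (tibble `group1`, `group2`,
#'   `z`, `p_raw`, `p_adj`).
#' @export
kw_dunn_bh <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- as.character(groups[ok])
  tab <- table(groups)
  if (length(tab) < 3) abort("kw_dunn_bh: need >= 3 groups")
  if (any(tab < 2)) abort("kw_dunn_bh: every group needs >= 2 observations")

  kw <- kruskal.test(values, factor(groups))

  n <- length(values)
  r <- rank(values)
  mean_ranks <- tapply(r, groups, mean)
  n_g <- tapply(r, groups, length)
  tie_sizes <- table(values)
  tie_term <- sum(tie_sizes^3 - tie_sizes) / (12 * (n - 1))
  labels <- names(mean_ranks)
  combs <- utils::combn(labels, 2)
  z <- apply(combs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    se <- sqrt((n * (n + 1) / 12 - tie_term) * (1 / n_g[[i]] + 1 / n_g[[j]]))
    (mean_ranks[[i]] - mean_ranks[[j]]) / se
  })
  p_raw <- 2 * pnorm(-abs(z))
  structure(
    list(
      omnibus = tibble(
        statistic = unname(kw$statistic),
        df = unname(kw$parameter),
        p_value = kw$p.value
      ),
      pairwise = tibble(
        group1 = combs[1, ],
        group2 = combs[2, ],
        z = unname(z),
        p_raw = unname(p_raw),
        p_adj = p.adjust(p_raw, method = "BH")
      )
    ),
    class = "kw_dunn"
  )
}

#' @export
print.kw_dunn <- function(x, ...) {
  cat(sprintf(
    "Kruskal-Wallis: H = %.4g, df = %d, p = %.4g\n",
    x$omnibus$statistic, x$omnibus$df, x$omnibus$p_value
  ))
  cat("Dunn's pairwise comparisons (BH-adjusted):\n")
  print(as.data.frame(x$pairwise))
  invisible(x)
}

#' Two-group scan across many phenotype/climate variables
#'
#' Runs [wilcoxon_ct()] per variable between two accession groups and flags
#' the variables with raw p below `alpha`. No multiple-testing correction is
#' applied by default — matching the published exploratory scan, which relied
#' on a structure-aware association analysis downstream for confirmation —
#' but Benjamini-Hochberg adjustment is available via `adjust = "BH"`.
#' Variables with fewer than 2 non-missing observations in either group are
#' skipped with a message.
#'
#' @param phenotypes Wide tibble: first column `accession`, one numeric
#'   column per variable.
#' @param groups Tibble `accession`, `group` with exactly two group labels
#'   among the scanned accessions.
#' @param alpha Significance level on the (adjusted, if any) p-value.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return An object of class `phenotype_scan`: tibble with one row per
#'   tested variable (`variable`, `n_1`, `n_2`, `statistic`, `p_value`,
#'   `p_adj`, `significant`), with the skipped variables in
#'   `attr(, "skipped")`.
#' @export
phenotype_scan <- function(phenotypes, groups, alpha = 0.05,
                           adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(names(phenotypes)[1] == "accession")
  labs <- unique(groups$group)
  if (length(labs) != 2) abort("phenotype_scan: need exactly two group labels")
  merged <- inner_join(phenotypes, groups, by = "accession")
  vars <- setdiff(names(phenotypes), "accession")
  rows <- purrr::map(vars, function(v) {
    x <- merged[[v]][merged$group == labs[1]]
    y <- merged[[v]][merged$group == labs[2]]
    x <- x[!is.na(x)]
    y <- y[!is.na(y)]
    if (length(x) < 2 || length(y) < 2) {
      return(NULL)
    }
    wt <- wilcoxon_ct(x, y)
    tibble(variable = v, n_1 = length(x), n_2 = length(y),
           statistic = wt$statistic, p_value = wt$p_value)
  })
  skipped <- vars[vapply(rows, is.null, logical(1))]
  if (length(skipped) > 0) {
    inform(sprintf("phenotype_scan: skipped %d variable(s) with < 2 observations per group",
                   length(skipped)))
  }
  out <- bind_rows(rows)
  out$p_adj <- if (adjust == "BH") p.adjust(out$p_value, "BH") else out$p_value
  out$significant <- out$p_adj < alpha
  attr(out, "skipped") <- skipped
  attr(out, "alpha") <- alpha
  class(out) <- c("phenotype_scan", class(out))
  out
}
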