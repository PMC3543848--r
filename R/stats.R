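## Hypothesis tests for comparing strategies and strata: exact and
## chi-square McNemar for paired retrieval tables, Fisher's exact test for
## independent comparisons.

#' Paired retrieval (McNemar) table
#'
#' For two searches run over the same reference set of records: `a` records
#' retrieved by both, `b` by the first only, `c` by the second only, `d` by
#' neither.
#'
#' @param b,c discordant counts (retrieved by one search only).
#' @param a,d concordant counts (optional; default 0).
#' @return object of class `paired_table`.
#' @export
paired_table <- function(b, c, a = 0, d = 0) {
  for (v in list(a, b, c, d))
    if (!is_count(v)) stop2("all cell counts must be non-negative integers")
  structure(list(a = a, b = b, c = c, d = d), class = "paired_table")
}

#' McNemar test for paired retrieval comparisons
#'
#' Tests whether two searches over the same records differ in what they
#' retrieve, using only the discordant counts `b` and `c`.  The exact
#' variant doubles the smaller binomial tail of `min(b, c)` given `b + c`
#' trials with success probability 1/2, capped at 1.  The chi-square
#' variant refers `(b - c)^2 / (b + c)` to a chi-square distribution with
#' 1 degree of freedom (no continuity correction).  `"auto"` uses the
#' exact variant when `b + c < 25`.  A degenerate table with `b + c = 0`
#' returns p = 1 and is flagged.
#'
#' @param table a [paired_table()], or the count `b` when `b` and `c` are
#'   given directly.
#' @param c count for the second search's exclusive retrievals (when
#'   `table` is a bare count).
#' @param variant `"auto"`, `"exact"` or `"chi2"`.
#' @return list of class `hedge_test` with elements `method`, `statistic`
#'   (chi-square variant only), `p.value`, `b`, `c`, `variant`,
#'   `degenerate`.
#' @examples
#' mcnemar_retrieval(1880, 222)          # chi2 = 1307.8, p < 0.001
#' mcnemar_retrieval(8, 2, variant = "exact")
#' @export
mcnemar_retrieval <- function(table, c = NULL,
                              variant = c("auto", "exact", "chi2")) {
  variant <- match.arg(variant)
  if (inherits(table, "paired_table")) {
    b <- table$b; cc <- table$c
  } else {
    if (is.null(c)) stop2("supply a paired_table or both b and c")
    b <- table; cc <- c
  }
  if (!is_count(b) || !is_count(cc))
    stop2("discordant counts must be non-negative integers")
  n <- b + cc
  if (n == 0) {
    return(structure(list(method = "McNemar (degenerate)",
                          statistic = NA_real_, p.value = 1,
                          b = b, c = cc, variant = variant,
                          degenerate = TRUE), class = "hedge_test"))
  }
  if (variant == "auto") variant <- if (n < 25) "exact" else "chi2"
  if (variant == "exact") {
    p <- min(1, 2 * stats::pbinom(min(b, cc), n, 0.5))
    out <- list(method = "Exact McNemar test (two-sided binomial)",
                statistic = NA_real_, p.value = p, b = b, c = cc,
                variant = "exact", degenerate = FALSE)
  } else {
    stat <- (b - cc)^2 / n
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    out <- list(method = "McNemar chi-square test (1 df)",
                statistic = stat, p.value = p, b = b, c = cc,
                variant = "chi2", degenerate = FALSE)
  }
  structure(out, class = "hedge_test")
}

#' Fisher's exact test for independent 2x2 comparisons
#'
#' Two-sided p-value obtained by summing the hypergeometric probabilities
#' of all tables at least as extreme as the observed one (the convention of
#' standard exact implementations); delegates to [stats::fisher.test()].
#' Used for comparing retrieval proportions across independent strata
#' (e.g. publication-year periods).
#'
#' @param table a 2x2 matrix of non-negative counts, or a length-4 vector
#'   `c(x11, x21, x12, x22)` filled column-wise.
#' @return list of class `hedge_test` with `method`, `p.value`,
#'   `estimate` (odds ratio).
#' @examples
#' fisher_independent(matrix(c(5, 0, 0, 5), 2))
#' @export
fisher_independent <- function(table) {
  if (!is.matrix(table)) table <- matrix(as.numeric(table), 2, 2)
  if (!all(dim(table) == c(2, 2)))
    stop2("`table` must be a 2x2 count matrix")
  if (any(table < 0) || any(table != floor(table)))
    stop2("cell counts must be non-negative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop2("all margins of the 2x2 table must be positive")
  ft <- stats::fisher.test(table, alternative = "two.sided")
  structure(list(method = "Fisher's exact test (two-sided)",
                 statistic = NA_real_, p.value = ft$p.value,
                 estimate = unname(ft$estimate), degenerate = FALSE),
            class = "hedge_test")
}

#' @export
print.hedge_test <- function(x, ...) {
  cat(x$method, "\n")
  if (!is.na(x$statistic %||% NA))
    cat("  statistic =", format(x$statistic, digits = 6), "\n")
  cat("  p-value =", format.pval(x$p.value, digits = 4), "\n")
  if (isTRUE(x$degenerate))
    cat("  (degenerate table: no discordant pairs)\n")
  invisible(x)
}
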