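## Retrieval diagnostics against the dual gold standard: sensitivity
## (overall and within-database), precision, number needed to read.

#' Sensitivity (recall) of a retrieval, in percent
#'
#' The proportion of relevant records retrieved, times 100.  With the full
#' gold-standard denominator this is overall sensitivity; with the
#' internal (within-database) denominator it is within-database
#' sensitivity.
#'
#' @param n_relevant_retrieved relevant records retrieved.
#' @param n_relevant_total relevant records in the reference set (> 0).
#' @return percentage in `[0, 100]`, unrounded.
#' @examples
#' sensitivity(3150, 4067)  # overall
#' sensitivity(3150, 3846)  # within-database
#' @export
sensitivity <- function(n_relevant_retrieved, n_relevant_total) {
  if (!is_count(n_relevant_retrieved) || !is_count(n_relevant_total))
    stop2("counts must be single non-negative integers")
  if (n_relevant_total == 0) stop2("sensitivity denominator must be > 0")
  if (n_relevant_retrieved > n_relevant_total)
    stop2("retrieved relevant count exceeds the reference set size")
  100 * n_relevant_retrieved / n_relevant_total
}

#' Precision (positive predictive value) of a retrieval, in percent
#'
#' The proportion of retrieved records that are relevant, times 100.
#' A retrieval of zero records has undefined precision and returns
#' `NA_real_` (distinct from a precision of 0).
#'
#' @param n_relevant_retrieved relevant records retrieved.
#' @param n_retrieved total records retrieved.
#' @return percentage in `[0, 100]`, or `NA_real_` when nothing was
#'   retrieved.
#' @examples
#' precision(3150, 3577)
#' @export
precision <- function(n_relevant_retrieved, n_retrieved) {
  if (!is_count(n_relevant_retrieved) || !is_count(n_retrieved))
    stop2("counts must be single non-negative integers")
  if (n_relevant_retrieved > n_retrieved)
    stop2("relevant retrieved count exceeds total retrieved count")
  if (n_retrieved == 0) return(NA_real_)
  100 * n_relevant_retrieved / n_retrieved
}

#' Number needed to read
#'
#' How many retrieved records must be screened to find one relevant record:
#' `100 / precision`.  Always >= 1; equals 1 exactly when precision is
#' 100%.  Undefined (`NA_real_`) when precision is 0 or missing.
#'
#' @param precision_pct precision in percent.
#' @return ratio >= 1, or `NA_real_`.
#' @examples
#' nnr(precision(3150, 3577))
#' @export
nnr <- function(precision_pct) {
  if (length(precision_pct) != 1 || !is.numeric(precision_pct))
    stop2("`precision_pct` must be a single number")
  if (is.na(precision_pct) || precision_pct <= 0) return(NA_real_)
  if (precision_pct > 100) stop2("precision cannot exceed 100%")
  100 / precision_pct
}

#' Performance of one retrieval against the dual gold standard
#'
#' Counts are computed by set intersection; overall sensitivity divides the
#' relevant records retrieved by the size of the full gold-standard set,
#' within-database sensitivity by the size of the internal set.  Because a
#' search cannot retrieve what the database lacks, overall sensitivity is
#' capped at `100 * |internal| / |full|`.
#'
#' @param retrieval a [retrieval_set()] or character vector of doc_ids.
#' @param gold a [gold_standard()].
#' @param x the [corpus()] (or [corpus_index()]) searched; used to validate
#'   that the retrieval and the gold standard refer to it.
#' @param label row label; defaults to the retrieval set's label.
#' @return a one-row data.frame of class `performance_row` with columns
#'   `label`, `n_retrieved`, `n_relevant_retrieved`, `sensitivity_full`,
#'   `sensitivity_internal`, `precision`, `nnr` (percentages unrounded).
#' @export
evaluate_performance <- function(retrieval, gold, x = NULL, label = NULL) {
  ids <- if (inherits(retrieval, "retrieval_set")) retrieval$doc_ids
         else unique(as.character(retrieval))
  label <- label %||%
    (if (inherits(retrieval, "retrieval_set")) retrieval$label else "query")
  stopifnot(inherits(gold, "gold_standard"))
  if (!is.null(x)) {
    all_ids <- as_index(x)$ids
    if (!all(ids %in% all_ids))
      stop2("retrieval contains doc_ids absent from the corpus")
    if (!all(gold$internal_set %in% all_ids))
      stop2("gold standard internal set is not contained in the corpus")
  }
  k <- length(intersect(ids, gold$full_set))
  row <- data.frame(
    label = label,
    n_retrieved = length(ids),
    n_relevant_retrieved = k,
    sensitivity_full = sensitivity(k, length(gold$full_set)),
    sensitivity_internal = sensitivity(k, length(gold$internal_set)),
    precision = precision(k, length(ids)),
    nnr = nnr(precision(k, length(ids))),
    stringsAsFactors = FALSE)
  class(row) <- c("performance_row", class(row))
  row
}

#' Performance counts to a row, without a corpus
#'
#' Convenience for recomputing published table rows from their printed
#' integer counts.
#'
#' @param n_relevant_retrieved,n_retrieved retrieval counts.
#' @param n_full,n_internal gold-standard denominators.
#' @param label row label.
#' @return a `performance_row` (see [evaluate_performance()]).
#' @export
performance_from_counts <- function(n_relevant_retrieved, n_retrieved,
                                    n_full, n_internal, label = "query") {
  row <- data.frame(
    label = label,
    n_retrieved = n_retrieved,
    n_relevant_retrieved = n_relevant_retrieved,
    sensitivity_full = sensitivity(n_relevant_retrieved, n_full),
    sensitivity_internal = sensitivity(n_relevant_retrieved, n_internal),
    precision = precision(n_relevant_retrieved, n_retrieved),
    nnr = nnr(precision(n_relevant_retrieved, n_retrieved)),
    stringsAsFactors = FALSE)
  class(row) <- c("performance_row", class(row))
  row
}

#' Performance table for a set of queries
#'
#' Evaluates each query against the corpus and returns one row per query,
#' sorted by overall sensitivity (descending); ties are broken by
#' precision (descending), then label.
#'
#' @param queries character vector of query strings, or a list of
#'   [retrieval_set()]s.
#' @param x a [corpus()] or [corpus_index()].
#' @param gold a [gold_standard()].
#' @return data.frame of performance rows.
#' @export
performance_table <- function(queries, x, gold) {
  if (length(queries) == 0) stop2("at least one query is required")
  idx <- as_index(x)
  sets <- if (is.character(queries))
    lapply(queries, evaluate_query, x = idx)
  else queries
  rows <- do.call(rbind, lapply(sets, evaluate_performance, gold = gold))
  o <- order(-rows$sensitivity_full,
             -ifelse(is.na(rows$precision), -Inf, rows$precision),
             rows$label)
  rows <- rows[o, , drop = FALSE]
  rownames(rows) <- NULL
  rows
}

#' Round a performance table for presentation
#'
#' Internal computation keeps full precision; presentation rounds half-up.
#' Profile `"table1"` rounds percentages to 1 decimal and NNR to 1 decimal
#' (single-query reporting); `"table23"` rounds percentages to 2 decimals
#' (cumulative strategy reporting).
#'
#' @param tab a data.frame of performance rows.
#' @param profile `"table1"` or `"table23"`.
#' @return the rounded data.frame.
#' @export
format_performance <- function(tab, profile = c("table1", "table23")) {
  profile <- match.arg(profile)
  digits <- if (profile == "table1") 1 else 2
  for (col in intersect(c("sensitivity_full", "sensitivity_internal",
                          "precision"), names(tab)))
    tab[[col]] <- round_half_up(tab[[col]], digits)
  if ("nnr" %in% names(tab))
    tab$nnr <- round_half_up(tab$nnr, 1)
  tab
}

#' Export a performance table as TSV/CSV
#'
#' Columns are emitted in the canonical order: label, relevant retrieved,
#' total retrieved, overall sensitivity, within-database sensitivity,
#' precision, NNR (dropping columns absent from `tab`).
#'
#' @param tab data.frame of performance rows.
#' @param path output file.
#' @param sep field separator (`"\t"` or `","`).
#' @return `path`, invisibly.
#' @export
write_performance <- function(tab, path, sep = "\t") {
  ord <- intersect(c("label", "n_relevant_retrieved", "n_retrieved",
                     "sensitivity_full", "sensitivity_internal",
                     "precision", "nnr", "new_relevant", "new_retrieved"),
                   names(tab))
  utils::write.table(tab[, ord, drop = FALSE], path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
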