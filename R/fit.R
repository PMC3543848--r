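## The package's modelling surface: fit a search strategy to a labelled
## corpus and present it through the usual print/summary/predict/plot
## generics.

#' Fit a boolean search strategy to a labelled corpus
#'
#' Evaluates a pool of candidate Ovid-dialect queries against a labelled
#' corpus and assembles a combined strategy.  With
#' `objective = "sensitivity"` the strategy is the sensitivity-maximizing
#' OR-chain (queries added in order of marginal relevant-records gain until
#' the gain is zero).  With `objective = "balanced"` the
#' sensitivity/precision Pareto frontier of query combinations is explored
#' and the best trade-off under `criterion` is selected; when
#' `not_terms` are supplied the selected strategy is additionally refined
#' with a NOT-exclusion clause of terms frequent among its irrelevant
#' retrievals.
#'
#' @param x a [corpus()] with relevance labels.
#' @param queries character vector of candidate query strings.
#' @param gold optional [gold_standard()]; derived from the corpus labels
#'   when `NULL`.
#' @param objective `"sensitivity"` or `"balanced"`.
#' @param criterion trade-off rule for `"balanced"` (see
#'   [best_tradeoff()]).
#' @param exhaustive_cap pool size up to which subset exploration is
#'   exhaustive (see [enumerate_frontier()] and [maximize_sensitivity()]).
#' @param not_terms optional character vector of candidate NOT-exclusion
#'   patterns (see [not_refinement()]).
#' @param ... further arguments passed to [not_refinement()]
#'   (`min_freq_irrelevant`, `max_freq_relevant`).
#' @return an object of class `hedge_fit` with components `strategy`
#'   (a `search_strategy`), `table` (cumulative performance rows),
#'   `performance` (final row), `frontier` (for `"balanced"`), `objective`,
#'   `criterion`, `gold`, and `call`.
#' @seealso [maximize_sensitivity()], [enumerate_frontier()],
#'   [best_tradeoff()], [not_refinement()]
#' @export
hedge_fit <- function(x, queries, gold = NULL,
                      objective = c("sensitivity", "balanced"),
                      criterion = c("distance", "f1", "knee"),
                      exhaustive_cap = 12, not_terms = NULL, ...) {
  objective <- match.arg(objective)
  criterion <- match.arg(criterion)
  stopifnot(inherits(x, "corpus"))
  gold <- gold %||% gold_from_corpus(x)
  idx <- corpus_index(x)
  pool <- build_pool(queries, idx, gold)
  frontier <- NULL
  refinement <- NULL
  if (objective == "sensitivity") {
    mode <- if (length(queries) <= exhaustive_cap) "exhaustive" else "greedy"
    sel <- maximize_sensitivity(pool, mode = mode, K = exhaustive_cap)
    strategy <- as_strategy(sel)
  } else {
    frontier <- enumerate_frontier(pool, cap = exhaustive_cap)
    chosen <- best_tradeoff(frontier, criterion)
    sel <- strsplit(chosen$subset_labels, " | ", fixed = TRUE)[[1]]
    ## order the chosen subset by marginal gain for cumulative reporting
    sel <- {
      sub <- candidate_pool(pool$sets[sel], gold)
      ord <- greedy_order(sub)
      c(ord, setdiff(sel, ord))
    }
    strategy <- as_strategy(sel)
    if (!is.null(not_terms)) {
      refinement <- not_refinement(strategy, idx, gold, not_terms, ...)
      strategy <- refinement$strategy
    }
  }
  tab <- cumulative_or_table(candidate_pool(pool$sets[sel], gold))
  res <- evaluate_strategy(strategy, idx)
  final <- res$cumulative[[length(res$cumulative)]]
  if (!is.null(refinement) && length(refinement$selected_terms))
    final <- res$sets[[length(res$sets)]]
  performance <- evaluate_performance(final, gold,
                                      label = "combined strategy")
  structure(list(strategy = strategy, table = tab,
                 performance = performance, frontier = frontier,
                 refinement = refinement, objective = objective,
                 criterion = if (objective == "balanced") criterion else NA,
                 pool_labels = pool$labels, gold = gold,
                 call = match.call()),
            class = "hedge_fit")
}

#' @export
print.hedge_fit <- function(x, ...) {
  cat("Boolean search strategy fit (objective: ", x$objective,
      if (!is.na(x$criterion)) paste0(", criterion: ", x$criterion), ")\n",
      sep = "")
  cat("Candidate pool: ", length(x$pool_labels), " queries; strategy: ",
      length(x$strategy$lines), " lines\n\n", sep = "")
  p <- format_performance(x$performance, "table23")
  cat(sprintf(paste0("Relevant retrieved: %d of %d retrieved\n",
                     "Overall sensitivity: %.2f%%  ",
                     "Within-database sensitivity: %.2f%%  ",
                     "Precision: %.2f%%\n"),
              p$n_relevant_retrieved, p$n_retrieved,
              p$sensitivity_full, p$sensitivity_internal, p$precision))
  invisible(x)
}

#' @export
summary.hedge_fit <- function(object, ...) {
  structure(list(fit = object,
                 table = format_performance(object$table, "table23")),
            class = "summary.hedge_fit")
}

#' @export
print.summary.hedge_fit <- function(x, ...) {
  print(x$fit)
  cat("\nCumulative performance by strategy line:\n")
  tab <- x$table
  tab$label <- substr(tab$label, 1, 48)
  print(tab[, c("label", "n_relevant_retrieved", "n_retrieved",
                "sensitivity_full", "sensitivity_internal", "precision")],
        row.names = TRUE)
  if (!is.null(x$fit$refinement) &&
      length(x$fit$refinement$selected_terms)) {
    cat("\nNOT refinement (", paste(x$fit$refinement$selected_terms,
                                    collapse = ", "), "): ",
        sprintf("precision %+0.2f, overall sensitivity %+0.2f\n",
                x$fit$refinement$delta["precision"],
                x$fit$refinement$delta["sensitivity_full"]), sep = "")
  }
  invisible(x)
}

#' Apply a fitted strategy to a (new) corpus
#'
#' @param object a `hedge_fit`.
#' @param newdata a [corpus()] or [corpus_index()]; defaults to refusing —
#'   the fit stores no corpus.
#' @param type `"retrieval"` returns the final [retrieval_set()];
#'   `"logical"` a named logical vector over the corpus.
#' @param ... ignored.
#' @return see `type`.
#' @export
predict.hedge_fit <- function(object, newdata, type = c("retrieval",
                                                        "logical"), ...) {
  type <- match.arg(type)
  idx <- as_index(newdata)
  res <- evaluate_strategy(object$strategy, idx)
  ## the final line of a NOT-refined strategy is the strategy itself;
  ## otherwise the strategy is the cumulative union of its lines
  last_node <- object$strategy$nodes[[length(object$strategy$nodes)]]
  final <- if (max_lineref(last_node) > 0)
    res$sets[[length(res$sets)]]
  else res$cumulative[[length(res$cumulative)]]
  if (type == "retrieval") return(final)
  out <- stats::setNames(idx$ids %in% final$doc_ids, idx$ids)
  out
}

#' Plot the sensitivity/precision trade-off of a fit
#'
#' For balanced fits, plots the explored Pareto frontier with the selected
#' point highlighted; for sensitivity-maximizing fits, plots the
#' cumulative sensitivity/precision path as lines are added.
#'
#' @param x a `hedge_fit`.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.hedge_fit <- function(x, ...) {
  if (!is.null(x$frontier)) {
    pts <- x$frontier$points
    graphics::plot(pts$sensitivity_full, pts$precision,
                   xlab = "Overall sensitivity (%)",
                   ylab = "Precision (%)",
                   main = "Sensitivity/precision frontier", ...)
    p <- x$performance
    graphics::points(p$sensitivity_full, p$precision, pch = 19, col = 2)
  } else {
    tab <- x$table
    graphics::plot(tab$sensitivity_full, tab$precision, type = "b",
                   xlab = "Cumulative overall sensitivity (%)",
                   ylab = "Cumulative precision (%)",
                   main = "Cumulative OR path", ...)
  }
  invisible(x)
}
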