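## Strategy construction: sensitivity-maximizing OR-chains (greedy and
## exhaustive), the sensitivity/precision Pareto frontier with a pluggable
## best-trade-off rule, and NOT-exclusion refinement.

#' Candidate pool of evaluated queries
#'
#' @param sets named list mapping query labels to retrieved doc_id vectors,
#'   or a list of [retrieval_set()]s.
#' @param gold a [gold_standard()].
#' @return object of class `candidate_pool`.
#' @export
candidate_pool <- function(sets, gold) {
  stopifnot(inherits(gold, "gold_standard"))
  if (length(sets) == 0) stop2("pool must contain at least one query")
  if (inherits(sets[[1]], "retrieval_set")) {
    labels <- vapply(sets, function(s) s$label, character(1))
    sets <- lapply(sets, function(s) s$doc_ids)
    names(sets) <- labels
  }
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop2("every pool query needs a label")
  if (anyDuplicated(names(sets)))
    stop2("pool labels must be unique")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  structure(list(labels = names(sets), sets = sets, gold = gold),
            class = "candidate_pool")
}

#' @export
print.candidate_pool <- function(x, ...) {
  cat("<candidate_pool> ", length(x$labels), " queries; gold full ",
      length(x$gold$full_set), " / internal ",
      length(x$gold$internal_set), "\n", sep = "")
  invisible(x)
}

#' Build a candidate pool by evaluating query strings on a corpus
#'
#' @param queries character vector of Ovid-dialect query strings.
#' @param x a [corpus()] or [corpus_index()].
#' @param gold a [gold_standard()]; derived from corpus labels when `NULL`.
#' @return a [candidate_pool()].
#' @export
build_pool <- function(queries, x, gold = NULL) {
  idx <- as_index(x)
  if (is.null(gold)) {
    if (!inherits(x, "corpus"))
      stop2("`gold` is required when `x` is a prebuilt index")
    gold <- gold_from_corpus(x)
  }
  sets <- lapply(queries, function(q) evaluate_query(q, idx)$doc_ids)
  names(sets) <- queries
  candidate_pool(sets, gold)
}

pool_precision <- function(pool, label) {
  s <- pool$sets[[label]]
  if (length(s) == 0) return(NA_real_)
  100 * length(intersect(s, pool$gold$full_set)) / length(s)
}

#' Cumulative performance of incrementally OR-ed queries
#'
#' Row k reports the union of queries 1..k: cumulative counts, overall and
#' within-database sensitivity, precision, NNR, plus the marginal gain of
#' line k (`new_relevant`, `new_retrieved`).
#'
#' @param queries ordered character vector of query strings (evaluated on
#'   `x`), or a list of [retrieval_set()]s, or a [candidate_pool()] (taken
#'   in label order).
#' @param gold a [gold_standard()]; taken from the pool when `queries` is a
#'   pool.
#' @param x a [corpus()] / [corpus_index()], needed only when `queries` are
#'   strings.
#' @return data.frame of cumulative performance rows.
#' @export
cumulative_or_table <- function(queries, gold = NULL, x = NULL) {
  if (inherits(queries, "candidate_pool")) {
    gold <- queries$gold
    sets <- queries$sets
    labels <- queries$labels
  } else if (is.character(queries)) {
    if (is.null(x)) stop2("a corpus is required to evaluate query strings")
    idx <- as_index(x)
    sets <- lapply(queries, function(q) evaluate_query(q, idx)$doc_ids)
    labels <- queries
  } else {
    labels <- vapply(queries, function(s) s$label, character(1))
    sets <- lapply(queries, function(s) s$doc_ids)
  }
  stopifnot(inherits(gold, "gold_standard"))
  rows <- vector("list", length(sets))
  cum <- character(0)
  for (k in seq_along(sets)) {
    prev_n <- length(cum)
    prev_rel <- length(intersect(cum, gold$full_set))
    cum <- union(cum, sets[[k]])
    row <- evaluate_performance(cum, gold, label = labels[k])
    row$new_retrieved <- row$n_retrieved - prev_n
    row$new_relevant <- row$n_relevant_retrieved - prev_rel
    rows[[k]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

greedy_order <- function(pool, labels = pool$labels) {
  full <- pool$gold$full_set
  rel_sets <- lapply(pool$sets[labels], intersect, y = full)
  covered <- character(0)
  chosen <- character(0)
  remaining <- labels
  while (length(remaining)) {
    gain <- vapply(remaining, function(l)
      length(setdiff(rel_sets[[l]], covered)), integer(1))
    best <- max(gain)
    if (best == 0) break
    cand <- remaining[gain == best]
    if (length(cand) > 1) {
      prec <- vapply(cand, function(l) pool_precision(pool, l), numeric(1))
      prec[is.na(prec)] <- -Inf
      cand <- cand[order(-prec, cand)]
    }
    pick <- cand[1]
    chosen <- c(chosen, pick)
    covered <- union(covered, rel_sets[[pick]])
    remaining <- setdiff(remaining, pick)
  }
  chosen
}

subset_counts <- function(pool, labels) {
  u <- unique(unlist(pool$sets[labels], use.names = FALSE))
  c(rel = length(intersect(u, pool$gold$full_set)), tot = length(u))
}

#' Select a sensitivity-maximizing query combination
#'
#' Greedy mode repeatedly adds the query with the largest marginal gain in
#' relevant records retrieved (ties broken by higher single-query
#' precision, then label order) until the marginal gain is zero.  For pure
#' union coverage run to zero marginal gain this attains the exhaustive
#' maximum.  Exhaustive mode enumerates every non-empty subset of a pool
#' of at most `K` queries and returns the subset with the largest relevant
#' count, smallest total retrieved among the maxima (then lexicographically
#' first label set); the returned order is the greedy inclusion order
#' within the chosen subset, for cumulative reporting.
#'
#' @param pool a [candidate_pool()].
#' @param mode `"greedy"` or `"exhaustive"`.
#' @param K subset-size cap for exhaustive mode (default 12).
#' @return character vector of selected query labels, in inclusion order.
#' @export
maximize_sensitivity <- function(pool, mode = c("greedy", "exhaustive"),
                                 K = 12) {
  stopifnot(inherits(pool, "candidate_pool"))
  mode <- match.arg(mode)
  if (mode == "greedy") return(greedy_order(pool))
  m <- length(pool$labels)
  if (m > K)
    stop2("exhaustive mode is capped at K = ", K,
          " queries (pool has ", m, "); use mode = \"greedy\"")
  best <- NULL
  for (mask in seq_len(2^m - 1)) {
    labels <- pool$labels[bitwAnd(mask, 2^(seq_len(m) - 1)) > 0]
    ct <- subset_counts(pool, labels)
    if (is.null(best) ||
        ct["rel"] > best$rel ||
        (ct["rel"] == best$rel && ct["tot"] < best$tot) ||
        (ct["rel"] == best$rel && ct["tot"] == best$tot &&
         paste(sort(labels), collapse = "\r") <
         paste(sort(best$labels), collapse = "\r"))) {
      best <- list(labels = labels, rel = ct["rel"], tot = ct["tot"])
    }
  }
  sub <- candidate_pool(pool$sets[best$labels], pool$gold)
  ord <- greedy_order(sub)
  c(ord, setdiff(best$labels, ord))
}

pareto_filter <- function(df) {
  ## keep mutually non-dominated (sensitivity_full, precision) points
  o <- order(-df$sensitivity_full, -df$precision)
  df <- df[o, , drop = FALSE]
  keep <- logical(nrow(df))
  best_prec <- -Inf
  for (i in seq_len(nrow(df))) {
    p <- df$precision[i]
    if (is.na(p)) p <- -Inf
    if (p > best_prec) {
      keep[i] <- TRUE
      best_prec <- p
    } else if (p == best_prec &&
               i > 1 && df$sensitivity_full[i] == df$sensitivity_full[i - 1]) {
      ## equal point: non-dominated, but drop metric duplicates
      keep[i] <- FALSE
    }
  }
  df <- df[keep, , drop = FALSE]
  rownames(df) <- NULL
  df
}

frontier_row <- function(pool, labels) {
  u <- unique(unlist(pool$sets[labels], use.names = FALSE))
  k <- length(intersect(u, pool$gold$full_set))
  data.frame(
    subset_labels = paste(labels, collapse = " | "),
    n_queries = length(labels),
    n_relevant_retrieved = k,
    n_retrieved = length(u),
    sensitivity_full = 100 * k / length(pool$gold$full_set),
    sensitivity_internal = 100 * k / length(pool$gold$internal_set),
    precision = if (length(u)) 100 * k / length(u) else NA_real_,
    stringsAsFactors = FALSE)
}

#' Enumerate the sensitivity/precision Pareto frontier of query subsets
#'
#' Explores OR-combinations of pool queries and returns the non-dominated
#' points of the overall-sensitivity x precision plane (the scatter whose
#' upper-right hull is the achievable trade-off).  Pools of at most `cap`
#' queries are enumerated exhaustively (every non-empty subset); larger
#' pools are explored by a deterministic beam search over add-one
#' expansions seeded by the greedy sensitivity ordering.
#'
#' @param pool a [candidate_pool()].
#' @param cap exhaustive-enumeration cap (default 12).
#' @param beam beam width for larger pools (default 32).
#' @return object of class `frontier`: list with `points` (data.frame of
#'   non-dominated rows, sorted by sensitivity descending) and `explored`
#'   (number of subsets examined).
#' @export
enumerate_frontier <- function(pool, cap = 12, beam = 32) {
  stopifnot(inherits(pool, "candidate_pool"))
  m <- length(pool$labels)
  rows <- list()
  explored <- 0L
  if (m <= cap) {
    for (mask in seq_len(2^m - 1)) {
      labels <- pool$labels[bitwAnd(mask, 2^(seq_len(m) - 1)) > 0]
      rows[[length(rows) + 1L]] <- frontier_row(pool, labels)
      explored <- explored + 1L
    }
  } else {
    states <- lapply(pool$labels, function(l) l)
    seen <- new.env(parent = emptyenv())
    for (depth in seq_len(m)) {
      scored <- lapply(states, function(lbls) frontier_row(pool, lbls))
      rows <- c(rows, scored)
      explored <- explored + length(scored)
      if (depth == m) break
      ## expand each state by each unused query, dedupe by subset
      expansions <- list()
      for (s in states) {
        for (l in setdiff(pool$labels, s)) {
          key <- paste(sort(c(s, l)), collapse = "\r")
          if (is.null(seen[[key]])) {
            seen[[key]] <- TRUE
            expansions[[length(expansions) + 1L]] <- c(s, l)
          }
        }
      }
      if (length(expansions) == 0) break
      sc <- do.call(rbind, lapply(expansions, frontier_row, pool = pool))
      ## keep the best by sensitivity and the best by precision so both
      ## ends of the trade-off stay explored
      o_sens <- order(-sc$sensitivity_full, -sc$precision, sc$subset_labels)
      o_prec <- order(-ifelse(is.na(sc$precision), -Inf, sc$precision),
                      -sc$sensitivity_full, sc$subset_labels)
      take <- unique(c(o_sens[seq_len(min(ceiling(beam / 2), nrow(sc)))],
                       o_prec[seq_len(min(ceiling(beam / 2), nrow(sc)))]))
      states <- expansions[take]
    }
  }
  all_rows <- do.call(rbind, rows)
  pts <- pareto_filter(all_rows)
  structure(list(points = pts, explored = explored,
                 gold = pool$gold), class = "frontier")
}

#' @export
print.frontier <- function(x, ...) {
  cat("<frontier> ", nrow(x$points), " non-dominated points (",
      x$explored, " subsets explored)\n", sep = "")
  print(format_performance(
    x$points[, c("subset_labels", "sensitivity_full", "precision")],
    "table23"))
  invisible(x)
}

#' Pick the best sensitivity/precision trade-off on a frontier
#'
#' Criteria: `"distance"` (default) minimizes the Euclidean distance to the
#' ideal point (100, 100) on the overall-sensitivity x precision plane;
#' `"f1"` maximizes the harmonic mean of the two; `"knee"` maximizes the
#' perpendicular distance to the chord joining the frontier's endpoints.
#' Ties go to the higher-sensitivity point.
#'
#' @param frontier a `frontier` object or a data.frame with columns
#'   `sensitivity_full` and `precision`.
#' @param criterion `"distance"`, `"f1"` or `"knee"`.
#' @return the selected frontier row (one-row data.frame) with an added
#'   `criterion_value` column.
#' @export
best_tradeoff <- function(frontier, criterion = c("distance", "f1", "knee")) {
  criterion <- match.arg(criterion)
  pts <- if (inherits(frontier, "frontier")) frontier$points else frontier
  if (!is.data.frame(pts) || nrow(pts) == 0)
    stop2("frontier must contain at least one point")
  s <- pts$sensitivity_full
  p <- pts$precision
  score <- switch(criterion,
    distance = -sqrt((100 - s)^2 + (100 - p)^2),
    f1 = ifelse(s + p > 0, 2 * s * p / (s + p), 0),
    knee = {
      if (nrow(pts) < 3) {
        ## with <= 2 points the chord is degenerate; fall back to distance
        -sqrt((100 - s)^2 + (100 - p)^2)
      } else {
        o <- order(s)
        x1 <- s[o][1]; y1 <- p[o][1]
        x2 <- s[o][length(s)]; y2 <- p[o][length(s)]
        abs((y2 - y1) * s - (x2 - x1) * p + x2 * y1 - y2 * x1) /
          sqrt((y2 - y1)^2 + (x2 - x1)^2)
      }
    })
  score[is.na(score)] <- -Inf
  best <- which(score == max(score))
  if (length(best) > 1) best <- best[which.max(s[best])]
  out <- pts[best, , drop = FALSE]
  out$criterion_value <- if (criterion == "distance") -score[best]
                         else score[best]
  rownames(out) <- NULL
  out
}

#' Refine a strategy with a NOT-exclusion clause
#'
#' Selects exclusion terms that are frequent among the irrelevant records a
#' strategy retrieves and rare among the relevant ones, appends
#' `(or/1-K) not (term1 or term2 ...).af.` as a final line, and reports the
#' precision gain and sensitivity cost.  Terms must be bare patterns
#' (no field code); they are evaluated over all searchable fields.
#'
#' @param strategy a `search_strategy` or character vector of query lines.
#' @param x a [corpus()] or [corpus_index()].
#' @param gold a [gold_standard()].
#' @param candidate_terms character vector of candidate exclusion patterns
#'   (e.g. `c("stent*", "veterinar*")`).
#' @param min_freq_irrelevant minimum fraction of the strategy's irrelevant
#'   retrieved records a term must appear in (default 0.02).
#' @param max_freq_relevant maximum fraction of the relevant retrieved
#'   records the term may appear in (default 0.002).
#' @return list with `strategy` (refined; unchanged when no term
#'   qualifies), `selected_terms`, `term_stats` (per-candidate frequencies),
#'   `before` and `after` performance rows, and `delta` (named numeric:
#'   `precision`, `sensitivity_full`, `sensitivity_internal`).
#' @export
not_refinement <- function(strategy, x, gold, candidate_terms,
                           min_freq_irrelevant = 0.02,
                           max_freq_relevant = 0.002) {
  if (is.character(strategy)) strategy <- as_strategy(strategy)
  stopifnot(inherits(strategy, "search_strategy"),
            inherits(gold, "gold_standard"))
  if (any(grepl("\\.\\s*(af|mp|ab|ti|sh)\\s*\\.", candidate_terms)))
    stop2("candidate exclusion terms must be bare patterns without field codes")
  idx <- as_index(x)
  res <- evaluate_strategy(strategy, idx)
  S <- res$cumulative[[length(res$cumulative)]]$doc_ids
  R <- intersect(S, gold$full_set)
  I <- setdiff(S, gold$full_set)
  stats <- do.call(rbind, lapply(candidate_terms, function(t) {
    hit <- evaluate_query(paste0(t, ".af."), idx)$doc_ids
    data.frame(
      term = t,
      freq_irrelevant = if (length(I)) length(intersect(hit, I)) / length(I)
                        else 0,
      freq_relevant = if (length(R)) length(intersect(hit, R)) / length(R)
                      else 0,
      stringsAsFactors = FALSE)
  }))
  sel <- stats$term[stats$freq_irrelevant >= min_freq_irrelevant &
                    stats$freq_relevant <= max_freq_relevant]
  before <- evaluate_performance(S, gold, label = "before NOT refinement")
  if (length(sel) == 0) {
    delta <- c(precision = 0, sensitivity_full = 0, sensitivity_internal = 0)
    return(list(strategy = strategy, selected_terms = character(0),
                term_stats = stats, before = before, after = before,
                delta = delta))
  }
  K <- length(strategy$lines)
  clause <- paste0("(or/1-", K, ") not (",
                   paste(sel, collapse = " or "), ").af.")
  refined <- as_strategy(c(strategy$lines, clause))
  res2 <- evaluate_strategy(refined, idx)
  S2 <- res2$sets[[K + 1L]]$doc_ids
  after <- evaluate_performance(S2, gold, label = clause)
  delta <- c(
    precision = after$precision - before$precision,
    sensitivity_full = after$sensitivity_full - before$sensitivity_full,
    sensitivity_internal =
      after$sensitivity_internal - before$sensitivity_internal)
  list(strategy = refined, selected_terms = sel, term_stats = stats,
       before = before, after = after, delta = delta)
}

#' Export frontier points for re-plotting
#'
#' @param frontier a `frontier` object.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_frontier <- function(frontier, path) {
  stopifnot(inherits(frontier, "frontier"))
  utils::write.csv(frontier$points[, c("subset_labels", "sensitivity_full",
                                       "sensitivity_internal", "precision")],
                   path, row.names = FALSE)
  invisible(path)
}
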