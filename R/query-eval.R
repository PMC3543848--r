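## Boolean retrieval over a local corpus: tokenized field index, wildcard
## pattern matching, proximity windows, field scopes and strategy-line
## references.

## Field scopes over the local data model.  af covers every searchable
## field stored on a record (title, abstract, subject headings,
## publication type, accession numbers); the live OvidSP .af. also covers
## fields this model does not carry (e.g. manufacturer names), a documented
## divergence.  mp = title + abstract + subject headings; by construction
## af >= mp >= ab,ti >= ab|ti.
scope_ftypes <- function(code) {
  switch(code,
         ti = "ti", ab = "ab", ab_ti = c("ab", "ti"),
         sh = "sh", mp = c("ti", "ab", "sh"),
         af = c("ti", "ab", "sh", "pt", "an"),
         stop2("unknown field code: ", code))
}

#' Build a token index over a corpus
#'
#' Tokenizes every searchable field of every record (lowercase; hyphens and
#' punctuation are token boundaries) into a flat positional index.  Each
#' field instance (the title, the abstract, each subject heading, the
#' publication type, each accession) is a separate token sequence: phrases
#' and proximity windows never cross field-instance boundaries.
#'
#' Build the index once and pass it to [evaluate_query()] /
#' [evaluate_strategy()] when evaluating many queries against one corpus.
#'
#' @param x a [corpus()].
#' @return an object of class `corpus_index`.
#' @export
corpus_index <- function(x) {
  stopifnot(inherits(x, "corpus"))
  tok_l <- list()
  inst_doc <- integer(0)
  inst_type <- character(0)
  k <- 0L
  add <- function(doc, type, text, pre_tokenized = FALSE) {
    toks <- if (pre_tokenized) text else tokenize1(text)
    if (length(toks) == 0) return()
    k <<- k + 1L
    tok_l[[k]] <<- toks
    inst_doc[k] <<- doc
    inst_type[k] <<- type
  }
  for (d in seq_along(x$records)) {
    r <- x$records[[d]]
    add(d, "ti", r$title)
    add(d, "ab", r$abstract)
    for (h in r$subject_headings) add(d, "sh", h)
    add(d, "pt", r$pub_type)
    for (a in r$accessions) add(d, "an", tolower(a), pre_tokenized = TRUE)
  }
  lens <- lengths(tok_l)
  structure(list(
    tokens = unlist(tok_l) %||% character(0),
    iid = rep.int(seq_len(k), lens),
    pos = unlist(lapply(lens, seq_len)) %||% integer(0),
    inst_doc = inst_doc,
    inst_type = inst_type,
    inst_len = as.integer(lens),
    n_docs = length(x$records),
    ids = doc_ids(x)
  ), class = "corpus_index")
}

## wildcard pattern token -> anchored regex; NULL when the token is literal
pattern_regex <- function(tok) {
  if (!grepl("[*?#$]", tok)) return(NULL)
  esc <- gsub("([.\\\\+^\\[\\]()|{}])", "\\\\\\1", tok, perl = TRUE)
  esc <- gsub("*", ".*", esc, fixed = TRUE)
  esc <- gsub("$", ".*", esc, fixed = TRUE)
  esc <- gsub("?", ".?", esc, fixed = TRUE)
  esc <- gsub("#", ".", esc, fixed = TRUE)
  paste0("^", esc, "$")
}

## logical vector over idx$tokens, cached per evaluation
match_token <- function(idx, tok, cache) {
  hit <- cache[[tok]]
  if (!is.null(hit)) return(hit)
  rx <- pattern_regex(tok)
  m <- if (is.null(rx)) idx$tokens == tok else grepl(rx, idx$tokens, perl = TRUE)
  cache[[tok]] <- m
  m
}

## occurrences of a phrase (exact in-order adjacency) within allowed field
## instances; returns data.frame(iid, start, end) of token windows
term_spans <- function(idx, tokens, ftypes, cache, exact_instance = FALSE) {
  K <- length(tokens)
  N <- length(idx$tokens)
  if (N == 0L || K == 0L)
    return(data.frame(iid = integer(0), start = integer(0),
                      end = integer(0)))
  ok_inst <- idx$inst_type %in% ftypes
  if (exact_instance) ok_inst <- ok_inst & idx$inst_len == K
  cand <- which(match_token(idx, tokens[1], cache) & ok_inst[idx$iid])
  if (exact_instance && length(cand)) cand <- cand[idx$pos[cand] == 1L]
  if (K > 1L) {
    for (k in 2L:K) {
      if (length(cand) == 0L) break
      nxt <- cand + (k - 1L)
      keep <- nxt <= N
      keep[keep] <- idx$iid[nxt[keep]] == idx$iid[cand[keep]]
      mk <- match_token(idx, tokens[k], cache)
      keep[keep] <- mk[nxt[keep]]
      cand <- cand[keep]
    }
  }
  data.frame(iid = idx$iid[cand], start = idx$pos[cand],
             end = idx$pos[cand] + K - 1L)
}

## spans of a term-like subtree (term / adj / or-of-term-like / field)
node_spans <- function(node, idx, scope, cache) {
  switch(node$kind,
    term = term_spans(idx, node$tokens, scope_ftypes(scope), cache,
                      exact_instance = (scope == "sh")),
    field = node_spans(node$children[[1L]], idx, node$code, cache),
    or = {
      parts <- lapply(node$children, node_spans, idx = idx, scope = scope,
                      cache = cache)
      unique(do.call(rbind, parts))
    },
    adj = {
      a <- node_spans(node$children[[1L]], idx, scope, cache)
      b <- node_spans(node$children[[2L]], idx, scope, cache)
      if (nrow(a) == 0L || nrow(b) == 0L)
        return(a[0, , drop = FALSE])
      names(b) <- c("iid", "start2", "end2")
      m <- merge(a, b, by = "iid")
      if (nrow(m) == 0L) return(a[0, , drop = FALSE])
      ## proximity in either order: at most n-1 intervening tokens between
      ## the two matched windows (overlap counts as adjacent)
      gap <- pmax(m$start2 - m$end - 1L, m$start - m$end2 - 1L)
      m <- m[gap <= node$n - 1L, , drop = FALSE]
      if (nrow(m) == 0L) return(a[0, , drop = FALSE])
      unique(data.frame(iid = m$iid,
                        start = pmin(m$start, m$start2),
                        end = pmax(m$end, m$end2)))
    },
    stop2("operator '", node$kind,
          "' is not allowed inside a proximity expression"))
}

## evaluate a query tree to a set of document indices
eval_node <- function(node, idx, scope, context, cache) {
  switch(node$kind,
    term = ,
    adj = {
      sp <- node_spans(node, idx, scope, cache)
      sort(unique(idx$inst_doc[sp$iid]))
    },
    field = eval_node(node$children[[1L]], idx, node$code, context, cache),
    or = sort(unique(unlist(lapply(node$children, eval_node, idx = idx,
                                   scope = scope, context = context,
                                   cache = cache)))),
    and = {
      sets <- lapply(node$children, eval_node, idx = idx, scope = scope,
                     context = context, cache = cache)
      Reduce(intersect, sets)
    },
    not = setdiff(
      eval_node(node$children[[1L]], idx, scope, context, cache),
      eval_node(node$children[[2L]], idx, scope, context, cache)),
    lineref = {
      if (node$to > length(context))
        stop2("line reference or/", node$from, "-", node$to,
              " points past the available ", length(context),
              " resolved line(s)")
      sort(unique(unlist(context[seq(node$from, node$to)])))
    },
    stop2("unknown node kind: ", node$kind))
}

#' A set of documents retrieved by one query or strategy
#'
#' @param label query text or strategy line label.
#' @param ids character vector of retrieved doc_ids.
#' @return object of class `retrieval_set`.
#' @export
retrieval_set <- function(label, ids) {
  structure(list(label = label, doc_ids = unique(as.character(ids))),
            class = "retrieval_set")
}

#' @export
print.retrieval_set <- function(x, ...) {
  cat("<retrieval_set> ", x$label, ": ", length(x$doc_ids),
      " records\n", sep = "")
  invisible(x)
}

#' @export
length.retrieval_set <- function(x) length(x$doc_ids)

as_index <- function(x) {
  if (inherits(x, "corpus_index")) x
  else if (inherits(x, "corpus")) corpus_index(x)
  else stop2("expected a corpus or corpus_index")
}

#' Evaluate a query against a corpus
#'
#' A document matches a term pattern in scope F iff the pattern matches the
#' tokenized text of any field instance in F; `or` is set union, `and`
#' intersection, `not` set difference, and `adjN` requires the two operand
#' windows in the same field instance with at most N-1 intervening tokens,
#' in either order.  `*`/`$` match any trailing characters, `?` zero or one
#' character, `#` exactly one.  Matching is case- and hyphen-insensitive.
#' Queries without an explicit field code are evaluated in the `.mp.`
#' scope (title, abstract, subject headings), the interface default.
#'
#' @param query an `ovid_query` tree or a query string.
#' @param x a [corpus()] or prebuilt [corpus_index()].
#' @param context list of previously resolved line retrieval sets
#'   (character doc_id vectors or `retrieval_set`s) for `or/a-b` references.
#' @param default_scope field scope applied to unscoped terms.
#' @return a [retrieval_set()].
#' @export
evaluate_query <- function(query, x, context = NULL, default_scope = "mp") {
  if (is.character(query)) query <- parse_query(query)
  stopifnot(inherits(query, "ovid_query"))
  idx <- as_index(x)
  ctx <- lapply(context %||% list(), function(s) {
    ids <- if (inherits(s, "retrieval_set")) s$doc_ids else as.character(s)
    match(ids, idx$ids)
  })
  if (max_lineref(query) > length(ctx))
    stop2("query references strategy line ", max_lineref(query),
          " but only ", length(ctx), " line(s) are resolved")
  cache <- new.env(parent = emptyenv())
  docs <- eval_node(query, idx, default_scope, ctx, cache)
  retrieval_set(serialize_query(query), idx$ids[docs])
}

## Strategies -----------------------------------------------------------

#' Construct a search strategy from query strings
#'
#' A strategy is an ordered, densely numbered list of query lines; a line
#' may reference the union of earlier lines with `or/a-b`.
#'
#' @param lines character vector of Ovid-dialect query strings, in order.
#' @return an object of class `search_strategy`.
#' @export
as_strategy <- function(lines) {
  lines <- as.character(lines)
  if (!length(lines)) stop2("a strategy needs at least one line")
  nodes <- lapply(lines, parse_query)
  for (k in seq_along(nodes)) {
    if (max_lineref(nodes[[k]]) >= k)
      stop2("line ", k, " references line ", max_lineref(nodes[[k]]),
            ": only earlier lines may be referenced")
  }
  structure(list(lines = lines, nodes = nodes), class = "search_strategy")
}

#' @export
length.search_strategy <- function(x) length(x$lines)

#' @export
print.search_strategy <- function(x, ...) {
  cat("<search_strategy> ", length(x$lines), " lines\n", sep = "")
  for (k in seq_along(x$lines))
    cat(sprintf("%3d  %s\n", k, x$lines[k]))
  invisible(x)
}

#' Read a strategy file
#'
#' Plain text, one query per line, optionally prefixed with its line
#' number (separated by a tab, period, parenthesis or whitespace);
#' `#` starts a comment; blank lines are ignored.  When line numbers are
#' present they must be dense from 1 in order.
#'
#' @param path file path.
#' @return a `search_strategy`.
#' @export
read_strategy <- function(path) {
  if (!file.exists(path)) stop2("cannot read strategy file: ", path)
  raw <- readLines(path, warn = FALSE, encoding = "UTF-8")
  raw <- sub("#.*$", "", raw)
  raw <- trimws(raw)
  raw <- raw[nzchar(raw)]
  nums <- rep(NA_integer_, length(raw))
  texts <- raw
  m <- regmatches(raw, regexec("^([0-9]+)[.)\t ]\\s*(\\S.*)$", raw))
  for (i in seq_along(raw)) {
    if (length(m[[i]]) == 3) {
      nums[i] <- as.integer(m[[i]][2])
      texts[i] <- m[[i]][3]
    }
  }
  if (all(!is.na(nums)) && !identical(nums, seq_along(raw)))
    stop2("strategy line numbers must be dense from 1; got: ",
          paste(nums, collapse = ", "))
  as_strategy(texts)
}

#' Write a strategy file
#'
#' @param strategy a `search_strategy`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_strategy <- function(strategy, path) {
  stopifnot(inherits(strategy, "search_strategy"))
  writeLines(paste0(seq_along(strategy$lines), "\t", strategy$lines), path)
  invisible(path)
}

#' Evaluate every line of a strategy against a corpus
#'
#' Line k is evaluated with lines 1..k-1 resolvable through `or/a-b`
#' references; the cumulative union over lines 1..k is also returned for
#' reporting.
#'
#' @param strategy a `search_strategy` or character vector of query lines.
#' @param x a [corpus()] or [corpus_index()].
#' @param default_scope scope for unscoped terms (default `"mp"`).
#' @return a list of class `strategy_result` with elements `strategy`,
#'   `sets` (per-line [retrieval_set()]s) and `cumulative` (cumulative
#'   union retrieval sets).
#' @export
evaluate_strategy <- function(strategy, x, default_scope = "mp") {
  if (is.character(strategy)) strategy <- as_strategy(strategy)
  stopifnot(inherits(strategy, "search_strategy"))
  idx <- as_index(x)
  n <- length(strategy$lines)
  sets <- vector("list", n)
  cum <- vector("list", n)
  ctx <- list()
  cache <- new.env(parent = emptyenv())
  cum_ids <- character(0)
  for (k in seq_len(n)) {
    docs <- eval_node(strategy$nodes[[k]], idx, default_scope,
                      lapply(ctx, function(ids) match(ids, idx$ids)), cache)
    ids <- idx$ids[docs]
    sets[[k]] <- retrieval_set(strategy$lines[k], ids)
    ctx[[k]] <- ids
    cum_ids <- union(cum_ids, ids)
    cum[[k]] <- retrieval_set(paste0("lines 1-", k), cum_ids)
  }
  structure(list(strategy = strategy, sets = sets, cumulative = cum),
            class = "strategy_result")
}

#' @export
print.strategy_result <- function(x, ...) {
  n <- length(x$sets)
  cat("<strategy_result> ", n, " lines; final cumulative retrieval: ",
      length(x$cumulative[[n]]$doc_ids), " records\n", sep = "")
  invisible(x)
}
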