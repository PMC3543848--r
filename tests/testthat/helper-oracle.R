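# Independent brute-force retrieval oracle: a naive per-document
# sliding-window matcher over normalized token lists.  Shares only the
# query parser with the package; evaluation logic is written from scratch
# so engine defects cannot hide in a shared code path.

oracle_tokenize <- function(x) {
  x <- gsub("[^a-z0-9]+", " ", tolower(x))
  parts <- strsplit(trimws(x), " +")[[1]]
  parts[nzchar(parts)]
}

# one document -> list of field instances: list(type=, toks=)
oracle_fields <- function(rec) {
  out <- list()
  add <- function(type, txt) {
    toks <- oracle_tokenize(txt)
    if (length(toks)) out[[length(out) + 1L]] <<- list(type = type,
                                                      toks = toks)
  }
  add("ti", rec$title)
  add("ab", rec$abstract)
  for (h in rec$subject_headings) add("sh", h)
  add("pt", rec$pub_type)
  for (a in rec$accessions) add("an", a)
  out
}

oracle_tok_rx <- function(pat) {
  chars <- strsplit(pat, "")[[1]]
  rx <- vapply(chars, function(ch) {
    if (ch %in% c("*", "$")) ".*"
    else if (ch == "?") ".?"
    else if (ch == "#") "."
    else if (grepl("[a-z0-9]", ch)) ch
    else paste0("\\", ch)
  }, character(1))
  paste0("^", paste(rx, collapse = ""), "$")
}

# memoized per (pattern, token) pair: corpora reuse a small vocabulary,
# so caching keeps the brute-force oracle usable on 200-document corpora
.oracle_memo <- new.env(parent = emptyenv())
oracle_tok_match <- function(pat, tok) {
  key <- paste0(pat, "\r", tok)
  hit <- .oracle_memo[[key]]
  if (is.null(hit)) {
    hit <- grepl(oracle_tok_rx(pat), tok)
    .oracle_memo[[key]] <- hit
  }
  hit
}

# all windows (start, end) where a phrase matches a token vector
oracle_phrase_windows <- function(pattern, toks) {
  K <- length(pattern)
  wins <- list()
  if (length(toks) < K) return(wins)
  for (s in seq_len(length(toks) - K + 1)) {
    ok <- TRUE
    for (k in seq_len(K)) {
      if (!oracle_tok_match(pattern[k], toks[s + k - 1])) { ok <- FALSE; break }
    }
    if (ok) wins[[length(wins) + 1L]] <- c(s, s + K - 1)
  }
  wins
}

oracle_scope_types <- function(code) {
  switch(code, ti = "ti", ab = "ab", ab_ti = c("ab", "ti"), sh = "sh",
         mp = c("ti", "ab", "sh"), af = c("ti", "ab", "sh", "pt", "an"))
}

# windows of a term-like node within one field instance
oracle_windows <- function(node, field, scope) {
  if (node$kind == "field") {
    return(oracle_windows(node$children[[1]], field, node$code))
  }
  if (!(field$type %in% oracle_scope_types(scope))) return(list())
  if (node$kind == "term") {
    if (scope == "sh") {
      if (length(field$toks) != length(node$tokens)) return(list())
      w <- oracle_phrase_windows(node$tokens, field$toks)
      return(Filter(function(z) z[1] == 1, w))
    }
    return(oracle_phrase_windows(node$tokens, field$toks))
  }
  if (node$kind == "or") {
    return(do.call(c, lapply(node$children, oracle_windows,
                             field = field, scope = scope)))
  }
  if (node$kind == "adj") {
    wa <- oracle_windows(node$children[[1]], field, scope)
    wb <- oracle_windows(node$children[[2]], field, scope)
    out <- list()
    for (a in wa) for (b in wb) {
      gap <- max(b[1] - a[2] - 1, a[1] - b[2] - 1)
      if (gap <= node$n - 1)
        out[[length(out) + 1L]] <- c(min(a[1], b[1]), max(a[2], b[2]))
    }
    return(out)
  }
  stop("oracle: operator not allowed in proximity context: ", node$kind)
}

# does one document match a query tree?
oracle_doc_match <- function(node, fields, scope, ctx_match) {
  switch(node$kind,
    term = ,
    adj = any(vapply(fields, function(f)
      length(oracle_windows(node, f, scope)) > 0, logical(1))),
    field = oracle_doc_match(node$children[[1]], fields, node$code,
                             ctx_match),
    or = any(vapply(node$children, oracle_doc_match, logical(1),
                    fields = fields, scope = scope, ctx_match = ctx_match)),
    and = all(vapply(node$children, oracle_doc_match, logical(1),
                     fields = fields, scope = scope,
                     ctx_match = ctx_match)),
    not = oracle_doc_match(node$children[[1]], fields, scope, ctx_match) &&
      !oracle_doc_match(node$children[[2]], fields, scope, ctx_match),
    lineref = any(ctx_match[seq(node$from, node$to)]),
    stop("oracle: unknown node ", node$kind))
}

# full oracle: query (string or tree) x corpus -> character doc_ids;
# context: list of doc_id vectors for earlier strategy lines
oracle_retrieve <- function(query, corp, context = list(),
                            default_scope = "mp") {
  node <- if (is.character(query)) parse_query(query) else query
  ids <- vapply(corp$records, function(r) r$doc_id, character(1))
  hits <- vapply(seq_along(corp$records), function(i) {
    ctx_match <- vapply(context, function(s) ids[i] %in% s, logical(1))
    oracle_doc_match(node, oracle_fields(corp$records[[i]]),
                     default_scope, ctx_match)
  }, logical(1))
  ids[hits]
}
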