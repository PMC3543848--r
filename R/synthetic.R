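## Synthetic corpora and retrieval matrices with known ground truth, so
## that the query engine, metrics and optimizers are testable end-to-end
## without access to any live bibliographic database.

#' Configuration for the synthetic corpus generator
#'
#' Defaults emulate the study conditions of a two-database off-label
#' retrieval gold standard: about 60% of records relevant (full set),
#' about 94.6% of relevant records retrievable in the target database
#' (internal set), and roughly 90% of relevant records published in the
#' recent period (2001-2011) versus the early period (1988-2000).
#'
#' @param n_docs number of logical documents before duplication.
#' @param prevalence fraction of relevant records (default 4067/6785).
#' @param internal_fraction fraction of relevant records indexed in the
#'   target database (default 3846/4067).
#' @param year_distribution named numeric vector of year probabilities
#'   (names are years); default spreads 9.5% uniformly over 1988-2000 and
#'   90.5% over 2001-2011.
#' @param query_specs list of specs `list(query =, sensitivity =,
#'   precision =)`: each planted query reaches the target within-database
#'   sensitivity and precision.  Default: a single
#'   `"off label*.af."`-style spec at sensitivity 0.819, precision 0.881.
#' @param duplicate_rate fraction of documents cloned once into a
#'   duplicate pair (default 0).
#' @param n_triplicates number of documents cloned twice (default 0).
#' @param mode `"exact"` plants matches by deterministic assignment to hit
#'   the target counts exactly (hypergeometric sampling of which documents
#'   carry the match); `"bernoulli"` plants independently per document for
#'   statistical property tests.
#' @param seed integer seed; all generator randomness flows through it.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n_docs,
                             prevalence = 4067 / 6785,
                             internal_fraction = 3846 / 4067,
                             year_distribution = NULL,
                             query_specs = list(list(
                               query = "off label*.af.",
                               sensitivity = 0.819,
                               precision = 0.881)),
                             duplicate_rate = 0,
                             n_triplicates = 0,
                             mode = c("exact", "bernoulli"),
                             seed = 1L) {
  mode <- match.arg(mode)
  if (!is_count(n_docs) || n_docs < 2) stop2("`n_docs` must be >= 2")
  for (p in c(prevalence, internal_fraction, duplicate_rate))
    if (!is.numeric(p) || p < 0 || p > 1)
      stop2("probabilities must lie in [0, 1]")
  if (is.null(year_distribution)) {
    early <- 1988:2000
    late <- 2001:2011
    year_distribution <- c(
      stats::setNames(rep(0.095 / length(early), length(early)), early),
      stats::setNames(rep(0.905 / length(late), length(late)), late))
  }
  if (abs(sum(year_distribution) - 1) > 1e-6)
    stop2("`year_distribution` probabilities must sum to 1")
  for (qs in query_specs) {
    if (!all(c("query", "sensitivity", "precision") %in% names(qs)))
      stop2("each query spec needs `query`, `sensitivity`, `precision`")
    parse_query(qs$query)
    if (qs$sensitivity < 0 || qs$sensitivity > 1 ||
        qs$precision <= 0 || qs$precision > 1)
      stop2("query spec targets must satisfy 0 <= sensitivity <= 1, ",
            "0 < precision <= 1")
  }
  structure(list(n_docs = as.integer(n_docs), prevalence = prevalence,
                 internal_fraction = internal_fraction,
                 year_distribution = year_distribution,
                 query_specs = query_specs,
                 duplicate_rate = duplicate_rate,
                 n_triplicates = as.integer(n_triplicates),
                 mode = mode, seed = as.integer(seed)),
            class = "generator_config")
}

## instantiate a plantable query tree into (field target, token sequence).
## Only term / adjN-of-terms / field shapes are plantable.
instantiate_query <- function(node, target = "ti") {
  switch(node$kind,
    field = {
      tgt <- switch(node$code, ab = "ab", sh = "sh", "ti")
      instantiate_query(node$children[[1L]], tgt)
    },
    term = {
      toks <- vapply(node$tokens, function(tk) {
        tk <- gsub("[*$?]", "", tk)
        tk <- gsub("#", "x", tk, fixed = TRUE)
        tk
      }, character(1))
      if (any(!nzchar(toks)))
        stop2("cannot plant a pattern consisting only of wildcards")
      list(target = target, tokens = unname(toks))
    },
    adj = {
      l <- instantiate_query(node$children[[1L]], target)
      r <- instantiate_query(node$children[[2L]], target)
      list(target = l$target, tokens = c(l$tokens, r$tokens))
    },
    stop2("query spec contains operator '", node$kind,
          "': only terms, phrases and adjN chains can be planted"))
}

## every pattern token of a plantable tree
pattern_tokens <- function(node) {
  switch(node$kind,
    term = node$tokens,
    unlist(lapply(node$children %||% list(), pattern_tokens)))
}

token_matches <- function(pattern_tok, tok) {
  rx <- pattern_regex(pattern_tok)
  if (is.null(rx)) pattern_tok == tok else grepl(rx, tok, perl = TRUE)
}

## neutral filler vocabulary; disjointness from every pattern token is
## verified at build time so filler text can never match a planted pattern
filler_vocab <- function(patterns) {
  vocab <- paste0("v", sprintf("%02d", 1:40), "w")
  for (pt in patterns) {
    bad <- vocab[vapply(vocab, function(tk) token_matches(pt, tk),
                        logical(1))]
    if (length(bad))
      stop2("filler vocabulary collides with pattern token '", pt,
            "' (e.g. '", bad[1], "'); rename the query or its wildcards")
  }
  vocab
}

## sample.int-based subset sampling, safe for length-1 vectors
sample_vec <- function(x, k) x[sample.int(length(x), k)]

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  code
}

#' Generate a labelled synthetic corpus with planted query matches
#'
#' For each query spec, matching token sequences are injected into the
#' title, abstract or subject headings of relevant in-database documents
#' at the target within-database sensitivity, and into irrelevant
#' documents at the rate implied by the target precision.  Filler text is
#' drawn from a fixed neutral vocabulary verified not to match any planted
#' pattern.  In `"exact"` mode the number of planted documents hits the
#' target counts exactly (sampling only decides which documents carry the
#' match), making downstream counts deterministic; `"bernoulli"` mode
#' plants independently per document.  Duplicate records are cloned with
#' perturbed accessions and titles.  Generation is deterministic under the
#' config seed.
#'
#' Query specs must not interfere: query i's pattern may not match query
#' j's planted tokens (checked before generation; overlapping specs are an
#' error).  Infeasible precision targets (more irrelevant plantings than
#' irrelevant documents) are also rejected before generation.
#'
#' @param config a [generator_config()].
#' @return list with `corpus` (a [corpus()]), `gold` (a
#'   [gold_standard()]), and `manifest` (per-document truth and realized
#'   per-query counts).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_docs
  n_rel <- round(config$prevalence * n)
  n_irrel <- n - n_rel
  n_int <- round(config$internal_fraction * n_rel)
  if (n_rel < 1 || n_int < 1)
    stop2("config yields an empty relevant or internal set")
  nodes <- lapply(config$query_specs, function(qs) parse_query(qs$query))
  insts <- lapply(nodes, instantiate_query)
  pats <- lapply(nodes, pattern_tokens)
  vocab <- filler_vocab(unique(unlist(pats)))
  ## cross-query interference check (conservative, token-level)
  if (length(nodes) > 1) {
    for (i in seq_along(nodes)) for (j in seq_along(nodes)) {
      if (i == j) next
      for (pt in pats[[i]]) for (tk in insts[[j]]$tokens) {
        if (token_matches(pt, tk))
          stop2("query specs interfere: pattern token '", pt, "' of '",
                config$query_specs[[i]]$query, "' matches planted token '",
                tk, "' of '", config$query_specs[[j]]$query, "'")
      }
    }
  }
  ## feasibility of precision targets
  for (k in seq_along(config$query_specs)) {
    qs <- config$query_specs[[k]]
    k_rel <- round(qs$sensitivity * n_int)
    k_irr <- round(k_rel * (1 - qs$precision) / qs$precision)
    if (k_irr > n_irrel)
      stop2("query spec '", qs$query, "' is unsatisfiable: precision ",
            qs$precision, " at this prevalence needs ", k_irr,
            " irrelevant matches but only ", n_irrel,
            " irrelevant documents exist")
  }
  with_seed(config$seed, {
    relevant <- rep(FALSE, n)
    relevant[sample.int(n, n_rel)] <- TRUE
    rel_idx <- which(relevant)
    int_idx <- sort(sample_vec(rel_idx, n_int))
    internal <- rep(FALSE, n)
    internal[int_idx] <- TRUE
    irrel_idx <- which(!relevant)
    years <- as.integer(sample(names(config$year_distribution), n,
                               replace = TRUE,
                               prob = config$year_distribution))
    mk_text <- function(len) paste(sample(vocab, len, replace = TRUE),
                                   collapse = " ")
    titles <- vapply(seq_len(n), function(i) mk_text(6), character(1))
    abstracts <- vapply(seq_len(n), function(i) mk_text(25), character(1))
    headings <- lapply(seq_len(n), function(i)
      c(mk_text(2), mk_text(3)))
    planted <- vector("list", length(config$query_specs))
    for (k in seq_along(config$query_specs)) {
      qs <- config$query_specs[[k]]
      inst <- insts[[k]]
      if (config$mode == "exact") {
        k_rel <- round(qs$sensitivity * n_int)
        k_irr <- round(k_rel * (1 - qs$precision) / qs$precision)
        hit_rel <- if (k_rel > 0) sample_vec(int_idx, k_rel) else integer(0)
        hit_irr <- if (k_irr > 0) sample_vec(irrel_idx, k_irr)
                   else integer(0)
      } else {
        hit_rel <- int_idx[stats::runif(n_int) < qs$sensitivity]
        exp_rel <- qs$sensitivity * n_int
        r_irr <- exp_rel * (1 - qs$precision) /
          (qs$precision * max(n_irrel, 1))
        if (r_irr > 1)
          stop2("query spec '", qs$query,
                "' implies an irrelevant match rate > 1")
        hit_irr <- irrel_idx[stats::runif(n_irrel) < r_irr]
      }
      hits <- sort(c(hit_rel, hit_irr))
      seq_txt <- paste(inst$tokens, collapse = " ")
      for (i in hits) {
        if (inst$target == "ab")
          abstracts[i] <- paste(abstracts[i], seq_txt)
        else if (inst$target == "sh")
          headings[[i]] <- c(headings[[i]], seq_txt)
        else titles[i] <- paste(titles[i], seq_txt)
      }
      planted[[k]] <- list(query = qs$query, doc_idx = hits,
                           n_relevant = length(hit_rel),
                           n_irrelevant = length(hit_irr))
    }
    recs <- vector("list", n)
    for (i in seq_len(n)) {
      recs[[i]] <- document_record(
        doc_id = sprintf("D%05d", i),
        title = titles[i],
        abstract = abstracts[i],
        subject_headings = headings[[i]],
        accessions = sprintf("A%07d", i),
        pub_year = years[i],
        source_dbs = if (!relevant[i] || internal[i]) "EMBASE"
                     else "MEDLINE",
        relevant = relevant[i],
        pub_type = "article")
    }
    ## duplicate / triplicate cloning with perturbed accession and title
    n_pairs <- round(config$duplicate_rate * n)
    n_clone_src <- n_pairs + config$n_triplicates
    clusters <- list()
    if (n_clone_src > 0) {
      if (n_clone_src > n)
        stop2("duplicate/triplicate settings exceed the corpus size")
      src <- sample.int(n, n_clone_src)
      trip <- utils::head(src, config$n_triplicates)
      cl_id <- 0L
      for (i in src) {
        cl_id <- cl_id + 1L
        copies <- if (i %in% trip) 2L else 1L
        members <- recs[[i]]$doc_id
        for (ccc in seq_len(copies)) {
          r <- recs[[i]]
          r$doc_id <- paste0(r$doc_id, "x", ccc)
          r$accessions <- sprintf("A%07dX%d", i, ccc)
          r$title <- paste0(toupper(substr(r$title, 1, 1)),
                            substr(r$title, 2, nchar(r$title)), ".")
          members <- c(members, r$doc_id)
          recs[[length(recs) + 1L]] <- r
        }
        clusters[[cl_id]] <- members
      }
      ## clones of planted documents also match their queries
      for (k in seq_along(planted)) {
        base_ids <- sprintf("D%05d", planted[[k]]$doc_idx)
        extra <- unlist(lapply(clusters, function(m)
          if (m[1] %in% base_ids) m[-1] else character(0)))
        planted[[k]]$doc_ids <- sort(c(base_ids, extra))
      }
    } else {
      for (k in seq_along(planted))
        planted[[k]]$doc_ids <- sprintf("D%05d", planted[[k]]$doc_idx)
    }
    corp <- corpus(recs, name = "synthetic",
                   snapshot_date = "2011-02-28")
    gold <- gold_from_corpus(corp, internal_db = "EMBASE")
    manifest <- list(
      config = config,
      n_relevant = sum(vapply(recs, function(r) r$relevant, logical(1))),
      n_internal = length(gold$internal_set),
      planted = lapply(planted, function(p)
        list(query = p$query, doc_ids = p$doc_ids,
             n_matched = length(p$doc_ids),
             n_relevant_planted = p$n_relevant,
             n_irrelevant_planted = p$n_irrelevant)),
      duplicate_clusters = clusters,
      year_counts = table(years))
    list(corpus = corp, gold = gold, manifest = manifest)
  })
}

#' Generate a binary query x document retrieval matrix
#'
#' Matrix-only workflow for optimizer experiments: each query retrieves
#' each document with a relevance-conditional rate.  In `"exact"` mode
#' exactly `round(p_rel * n_rel)` relevant and `round(p_irrel * n_irrel)`
#' irrelevant documents are assigned per query (hypergeometric assignment,
#' deterministic counts); `"bernoulli"` mode draws independently.
#'
#' @param n_docs number of documents.
#' @param rates data.frame (or matrix) with one row per query and columns
#'   `p_rel`, `p_irrel`; row names are query labels.
#' @param prevalence fraction of relevant documents.
#' @param mode `"bernoulli"` or `"exact"`.
#' @param seed integer seed.
#' @return list with `matrix` (logical queries x docs, dimnames set),
#'   `relevant` (logical per doc), and `manifest` (realized per-query
#'   counts).
#' @export
generate_retrieval_matrix <- function(n_docs, rates,
                                      prevalence = 4067 / 6785,
                                      mode = c("bernoulli", "exact"),
                                      seed = 1L) {
  mode <- match.arg(mode)
  rates <- as.data.frame(rates)
  if (!all(c("p_rel", "p_irrel") %in% names(rates)))
    stop2("`rates` needs columns p_rel and p_irrel")
  if (any(rates$p_rel < 0 | rates$p_rel > 1 |
          rates$p_irrel < 0 | rates$p_irrel > 1))
    stop2("rates must lie in [0, 1]")
  m <- nrow(rates)
  labels <- rownames(rates)
  if (is.null(labels) || anyDuplicated(labels) ||
      identical(labels, as.character(seq_len(m))))
    labels <- paste0("q", seq_len(m))
  with_seed(seed, {
    n_rel <- round(prevalence * n_docs)
    relevant <- rep(FALSE, n_docs)
    relevant[sample.int(n_docs, n_rel)] <- TRUE
    M <- matrix(FALSE, m, n_docs,
                dimnames = list(labels, sprintf("d%04d", seq_len(n_docs))))
    for (k in seq_len(m)) {
      if (mode == "bernoulli") {
        M[k, relevant] <- stats::runif(n_rel) < rates$p_rel[k]
        M[k, !relevant] <- stats::runif(n_docs - n_rel) < rates$p_irrel[k]
      } else {
        kr <- round(rates$p_rel[k] * n_rel)
        ki <- round(rates$p_irrel[k] * (n_docs - n_rel))
        if (kr > 0) M[k, sample_vec(which(relevant), kr)] <- TRUE
        if (ki > 0) M[k, sample_vec(which(!relevant), ki)] <- TRUE
      }
    }
    manifest <- data.frame(
      label = labels,
      n_matched = rowSums(M),
      n_relevant_matched = rowSums(M[, relevant, drop = FALSE]),
      stringsAsFactors = FALSE)
    list(matrix = M, relevant = relevant, manifest = manifest)
  })
}

#' Build a candidate pool from a retrieval matrix
#'
#' @param M logical queries x documents matrix with dimnames.
#' @param relevant logical relevance vector over documents.
#' @param internal optional logical in-database vector (defaults to
#'   `relevant`, i.e. a single-database gold standard).
#' @return a [candidate_pool()].
#' @export
pool_from_matrix <- function(M, relevant, internal = NULL) {
  ids <- colnames(M) %||% sprintf("d%04d", seq_len(ncol(M)))
  internal <- internal %||% relevant
  if (!any(relevant)) stop2("no relevant documents in the matrix")
  sets <- lapply(seq_len(nrow(M)), function(k) ids[M[k, ]])
  names(sets) <- rownames(M) %||% paste0("q", seq_len(nrow(M)))
  candidate_pool(sets, gold_standard(ids[relevant],
                                     ids[relevant & internal]))
}
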