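## End-to-end runs tying the stages together, with table/report emission.
## This is the programmatic surface behind the shipped command-line
## wrapper (inst/scripts/hedgedev.R).

#' Configuration for a pipeline run
#'
#' @param mode one of `"evaluate"`, `"optimize-sensitivity"`,
#'   `"optimize-tradeoff"`, `"refine-not"`, `"simulate"`.
#' @param out_dir output directory (created if missing).
#' @param corpus path to a corpus file, or a [corpus()] object
#'   (all modes except `"simulate"`).
#' @param corpus_format corpus file dialect (`"jsonl"`, `"csv"`, `"ris"`).
#' @param gold optional path to a gold-standard override: a two-column
#'   file `doc_id,set` with `set` in `full`/`internal`, or a
#'   [gold_standard()] object; defaults to corpus labels.
#' @param queries path to a query-pool file (one query per line) or a
#'   character vector (evaluate/optimize modes).
#' @param strategy path to a strategy file or a `search_strategy`
#'   (`"refine-not"` mode).
#' @param not_terms candidate NOT-exclusion patterns (`"refine-not"`).
#' @param criterion trade-off criterion (`"optimize-tradeoff"`).
#' @param exhaustive_cap exhaustive subset-enumeration cap.
#' @param rounding `"table1"` (1 decimal) or `"table23"` (2 decimals);
#'   default depends on mode (single-query tables use `"table1"`,
#'   cumulative tables `"table23"`).
#' @param generator a [generator_config()] (`"simulate"` mode).
#' @param seed integer seed for any randomness.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(mode, out_dir,
                       corpus = NULL, corpus_format = "jsonl",
                       gold = NULL, queries = NULL, strategy = NULL,
                       not_terms = NULL,
                       criterion = "distance", exhaustive_cap = 12,
                       rounding = NULL, generator = NULL, seed = 1L) {
  mode <- match.arg(mode, c("evaluate", "optimize-sensitivity",
                            "optimize-tradeoff", "refine-not", "simulate"))
  need <- function(what, x)
    if (is.null(x)) stop2("mode '", mode, "' requires `", what, "`")
  if (mode == "simulate") {
    need("generator", generator)
  } else {
    need("corpus", corpus)
    if (mode %in% c("evaluate", "optimize-sensitivity",
                    "optimize-tradeoff")) need("queries", queries)
    if (mode == "refine-not") {
      need("strategy", strategy)
      need("not_terms", not_terms)
    }
  }
  for (p in list(corpus, queries, strategy, gold)) {
    if (is.character(p) && length(p) == 1 && !file.exists(p) &&
        !grepl("\n", p) && grepl("[.][a-z]+$", p))
      stop2("referenced path does not exist: ", p)
  }
  rounding <- rounding %||%
    if (mode == "evaluate") "table1" else "table23"
  structure(list(mode = mode, out_dir = out_dir, corpus = corpus,
                 corpus_format = corpus_format, gold = gold,
                 queries = queries, strategy = strategy,
                 not_terms = not_terms, criterion = criterion,
                 exhaustive_cap = exhaustive_cap, rounding = rounding,
                 generator = generator, seed = as.integer(seed)),
            class = "run_config")
}

provenance_header <- function(config) {
  ver <- as.character(utils::packageVersion("hedgedev"))
  key <- paste(config$mode, config$criterion, config$exhaustive_cap,
               config$seed, length(config$queries),
               paste(config$queries, collapse = "|"), sep = ";")
  hash <- sprintf("%08x", sum(utf8ToInt(key) *
                                (seq_along(utf8ToInt(key)) %% 97 + 1)) %%
                    .Machine$integer.max)
  c(paste0("# hedgedev ", ver),
    paste0("# mode: ", config$mode, "  seed: ", config$seed,
           "  config-hash: ", hash))
}

write_with_header <- function(header, writer, path) {
  tmp <- tempfile()
  writer(tmp)
  writeLines(c(header, readLines(tmp, warn = FALSE)), path)
  unlink(tmp)
  invisible(path)
}

load_corpus_arg <- function(config) {
  if (inherits(config$corpus, "corpus")) return(config$corpus)
  read_corpus(config$corpus, format = config$corpus_format)
}

load_gold_arg <- function(config, corp) {
  g <- config$gold
  if (inherits(g, "gold_standard")) return(g)
  if (is.null(g)) return(gold_from_corpus(corp))
  df <- utils::read.csv(g, stringsAsFactors = FALSE)
  if (!all(c("doc_id", "set") %in% names(df)))
    stop2("gold-standard override needs columns doc_id, set")
  full <- df$doc_id[df$set %in% c("full", "internal")]
  internal <- df$doc_id[df$set == "internal"]
  gold_standard(full, internal)
}

load_queries_arg <- function(config) {
  q <- config$queries
  if (length(q) > 1 || inherits(q, "AsIs") || !file.exists(q %||% ""))
    return(as.character(q))
  lines <- readLines(q, warn = FALSE, encoding = "UTF-8")
  lines <- trimws(sub("#.*$", "", lines))
  lines[nzchar(lines)]
}

#' Run a full pipeline stage and write its artifacts
#'
#' Every artifact carries a provenance header (tool version, mode, seed,
#' config hash) and is accompanied by a machine-readable JSON summary
#' (`summary.json`).  An invalid configuration fails before any output is
#' written.
#'
#' * `evaluate` — per-query performance table (TSV).
#' * `optimize-sensitivity` — cumulative table (TSV) + strategy file.
#' * `optimize-tradeoff` — frontier CSV + chosen strategy + its table.
#' * `refine-not` — refined strategy + delta report.
#' * `simulate` — corpus JSONL + gold id list + manifest JSON.
#'
#' @param config a [run_config()].
#' @return list of written artifact paths plus the run summary, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- provenance_header(config)
  out <- function(name) file.path(config$out_dir, name)
  artifacts <- character(0)
  summary <- list(mode = config$mode, seed = config$seed)
  if (config$mode == "simulate") {
    gen <- generate_corpus(config$generator)
    write_corpus(gen$corpus, out("corpus.jsonl"))
    writeLines(c("doc_id,set",
                 paste0(gen$gold$full_set, ",",
                        ifelse(gen$gold$full_set %in% gen$gold$internal_set,
                               "internal", "full"))),
               out("gold.csv"))
    jsonlite::write_json(list(
      n_docs = length(gen$corpus$records),
      n_relevant = gen$manifest$n_relevant,
      n_internal = gen$manifest$n_internal,
      planted = gen$manifest$planted,
      duplicate_clusters = gen$manifest$duplicate_clusters),
      out("manifest.json"), auto_unbox = TRUE, digits = NA)
    artifacts <- c(out("corpus.jsonl"), out("gold.csv"),
                   out("manifest.json"))
    summary$n_docs <- length(gen$corpus$records)
    summary$n_relevant <- gen$manifest$n_relevant
  } else {
    corp <- load_corpus_arg(config)
    gold <- load_gold_arg(config, corp)
    idx <- corpus_index(corp)
    if (config$mode == "evaluate") {
      tab <- performance_table(load_queries_arg(config), idx, gold)
      ftab <- format_performance(tab, config$rounding)
      write_with_header(hdr, function(p) write_performance(ftab, p),
                        out("performance.tsv"))
      artifacts <- out("performance.tsv")
      summary$n_queries <- nrow(tab)
      summary$top <- as.list(ftab[1, ])
    } else if (config$mode == "optimize-sensitivity") {
      pool <- build_pool(load_queries_arg(config), idx, gold)
      sel <- maximize_sensitivity(
        pool,
        mode = if (length(pool$labels) <= config$exhaustive_cap)
          "exhaustive" else "greedy",
        K = config$exhaustive_cap)
      tab <- cumulative_or_table(candidate_pool(pool$sets[sel], gold))
      ftab <- format_performance(tab, config$rounding)
      write_with_header(hdr, function(p) write_performance(ftab, p),
                        out("cumulative.tsv"))
      write_strategy(as_strategy(sel), out("strategy.txt"))
      artifacts <- c(out("cumulative.tsv"), out("strategy.txt"))
      summary$final <- as.list(ftab[nrow(ftab), ])
    } else if (config$mode == "optimize-tradeoff") {
      fit <- hedge_fit(corp, load_queries_arg(config), gold = gold,
                       objective = "balanced",
                       criterion = config$criterion,
                       exhaustive_cap = config$exhaustive_cap,
                       not_terms = config$not_terms)
      write_with_header(hdr, function(p) write_frontier(fit$frontier, p),
                        out("frontier.csv"))
      write_strategy(fit$strategy, out("strategy.txt"))
      ftab <- format_performance(fit$table, config$rounding)
      write_with_header(hdr, function(p) write_performance(ftab, p),
                        out("cumulative.tsv"))
      artifacts <- c(out("frontier.csv"), out("strategy.txt"),
                     out("cumulative.tsv"))
      summary$criterion <- config$criterion
      summary$chosen <- as.list(
        format_performance(fit$performance, config$rounding))
    } else if (config$mode == "refine-not") {
      strat <- if (inherits(config$strategy, "search_strategy"))
        config$strategy else read_strategy(config$strategy)
      ref <- not_refinement(strat, idx, gold, config$not_terms)
      write_strategy(ref$strategy, out("strategy.txt"))
      delta <- rbind(
        format_performance(ref$before, config$rounding),
        format_performance(ref$after, config$rounding))
      write_with_header(hdr, function(p) write_performance(delta, p),
                        out("refinement.tsv"))
      artifacts <- c(out("strategy.txt"), out("refinement.tsv"))
      summary$selected_terms <- ref$selected_terms
      summary$delta <- as.list(round_half_up(ref$delta, 2))
    }
  }
  summary$artifacts <- basename(artifacts)
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(list(artifacts = c(artifacts, out("summary.json")),
                 summary = summary))
}
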