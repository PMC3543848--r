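## Corpus data model: labelled bibliographic records, gold standards,
## deduplication and year stratification.

#' Construct a single bibliographic document record
#'
#' A record carries the searchable fields of a bibliographic database entry
#' (title, abstract, controlled-vocabulary subject headings, accession
#' numbers, publication type) together with provenance (source databases,
#' publication year) and a binary relevance label that defines the gold
#' standard.
#'
#' @param doc_id unique opaque identifier (required).
#' @param title record title.
#' @param abstract abstract text; may be empty (letters often lack one).
#' @param subject_headings character vector of controlled-vocabulary terms.
#' @param accessions character vector of database accession numbers.
#' @param pub_year integer publication year or `NA`.
#' @param source_dbs subset of `c("EMBASE", "MEDLINE")`; must be non-empty.
#' @param relevant logical relevance label.
#' @param pub_type free-text publication type (`"article"`,
#'   `"conference abstract"`, `"letter"`, ...).
#' @return a list of class `document_record`.
#' @export
document_record <- function(doc_id, title = "", abstract = "",
                            subject_headings = character(0),
                            accessions = character(0),
                            pub_year = NA_integer_,
                            source_dbs = "EMBASE",
                            relevant = FALSE,
                            pub_type = "article") {
  if (missing(doc_id) || is.null(doc_id) || !nzchar(as.character(doc_id)[1]))
    stop2("`doc_id` is required and must be non-empty")
  source_dbs <- as.character(source_dbs)
  if (length(source_dbs) == 0)
    stop2("record ", doc_id, ": `source_dbs` must be non-empty")
  bad <- setdiff(source_dbs, c("EMBASE", "MEDLINE"))
  if (length(bad))
    stop2("record ", doc_id, ": unknown source database(s): ",
          paste(bad, collapse = ", "))
  pub_year <- suppressWarnings(as.integer(pub_year))
  if (!is.na(pub_year) && (pub_year < 1900 || pub_year > 2100))
    stop2("record ", doc_id, ": implausible pub_year ", pub_year)
  structure(list(
    doc_id = as.character(doc_id)[1],
    title = as.character(title)[1] %||% "",
    abstract = if (is.na(abstract[1])) "" else as.character(abstract)[1],
    subject_headings = as.character(subject_headings),
    accessions = as.character(accessions),
    pub_year = pub_year,
    source_dbs = source_dbs,
    relevant = isTRUE(as.logical(relevant)),
    pub_type = as.character(pub_type)[1] %||% "article"
  ), class = "document_record")
}

#' Construct a corpus of document records
#'
#' @param records list of [document_record()] objects.
#' @param name corpus name.
#' @param snapshot_date ISO date string.
#' @return an object of class `corpus`.
#' @export
corpus <- function(records, name = "corpus", snapshot_date = NA_character_) {
  if (!is.list(records)) stop2("`records` must be a list of document records")
  ids <- vapply(records, function(r) r$doc_id, character(1))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop2("duplicate doc_id in corpus: ", paste(unique(dup), collapse = ", "))
  structure(list(records = records, name = name,
                 snapshot_date = snapshot_date),
            class = "corpus")
}

#' @export
length.corpus <- function(x) length(x$records)

#' @export
print.corpus <- function(x, ...) {
  n <- length(x$records)
  nrel <- sum(vapply(x$records, function(r) r$relevant, logical(1)))
  cat("<corpus> ", x$name, ": ", n, " records (", nrel, " relevant)\n",
      sep = "")
  invisible(x)
}

#' Extract all document identifiers of a corpus
#' @param x a `corpus`.
#' @return character vector of doc_ids.
#' @export
doc_ids <- function(x) {
  stopifnot(inherits(x, "corpus"))
  vapply(x$records, function(r) r$doc_id, character(1))
}

corpus_field <- function(x, field) {
  vapply(x$records, function(r) as.character(r[[field]])[1] %||% "",
         character(1))
}

#' Dual gold standard for retrieval evaluation
#'
#' The full (external) set contains every relevant record across the source
#' databases; the internal set is the subset retrievable in the target
#' database.  The full set is the denominator of overall sensitivity, the
#' internal set the denominator of within-database sensitivity.
#'
#' @param full_set character vector of relevant doc_ids (all databases).
#' @param internal_set character vector of relevant doc_ids indexed in the
#'   target database; must be a subset of `full_set`.
#' @return object of class `gold_standard`.
#' @export
gold_standard <- function(full_set, internal_set) {
  full_set <- unique(as.character(full_set))
  internal_set <- unique(as.character(internal_set))
  if (!all(internal_set %in% full_set))
    stop2("internal gold-standard set must be a subset of the full set")
  if (length(full_set) == 0 || length(internal_set) == 0)
    stop2("gold-standard sets must be non-empty")
  structure(list(full_set = full_set, internal_set = internal_set),
            class = "gold_standard")
}

#' @export
print.gold_standard <- function(x, ...) {
  cat("<gold_standard> full:", length(x$full_set),
      " internal:", length(x$internal_set), "\n")
  invisible(x)
}

#' Derive the dual gold standard from corpus relevance labels
#'
#' The full set is every record labelled relevant; the internal set is the
#' relevant records whose `source_dbs` includes the target database.
#'
#' @param x a `corpus`.
#' @param internal_db target database name, default `"EMBASE"`.
#' @return a [gold_standard()].
#' @export
gold_from_corpus <- function(x, internal_db = "EMBASE") {
  stopifnot(inherits(x, "corpus"))
  rel <- Filter(function(r) r$relevant, x$records)
  if (length(rel) == 0) stop2("corpus has no relevant records")
  full <- vapply(rel, function(r) r$doc_id, character(1))
  int <- vapply(Filter(function(r) internal_db %in% r$source_dbs, rel),
                function(r) r$doc_id, character(1))
  if (length(int) == 0)
    stop2("no relevant record is indexed in ", internal_db)
  gold_standard(full, int)
}

## Publication categories excluded at load time (behind a flag).
EXCLUDED_PUB_TYPES <- c("book series", "video", "erratum", "correction")

#' Read a labelled corpus from disk
#'
#' Supported dialects: JSON-lines (one record object per line, field names
#' as in [document_record()]), CSV (list fields `;`-separated), and a
#' minimal RIS-like tagged format (`TI`/`AB`/`KW`/`PY`/`AN`/`DB`/`PT`/`ID`/
#' `RL` tags, records terminated by `ER`).
#'
#' Records whose publication type is an excluded category (book series,
#' video, erratum, correction) are dropped when `drop_excluded = TRUE`.
#' Records failing field validation are reported with their line numbers.
#'
#' @param path file path.
#' @param format one of `"jsonl"`, `"csv"`, `"ris"`.
#' @param drop_excluded drop excluded publication categories (default TRUE).
#' @param name corpus name; defaults to the file name.
#' @return a [corpus()].
#' @export
read_corpus <- function(path, format = c("jsonl", "csv", "ris"),
                        drop_excluded = TRUE, name = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop2("cannot read corpus file: ", path)
  name <- name %||% basename(path)
  recs <- switch(format,
    jsonl = read_corpus_jsonl(path),
    csv = read_corpus_csv(path),
    ris = read_corpus_ris(path))
  if (drop_excluded) {
    keep <- vapply(recs$records, function(r) {
      !(tolower(trimws(r$pub_type)) %in% EXCLUDED_PUB_TYPES)
    }, logical(1))
    recs$records <- recs$records[keep]
  }
  ids <- vapply(recs$records, function(r) r$doc_id, character(1))
  if (anyDuplicated(ids)) {
    d <- ids[duplicated(ids)][1]
    ln <- recs$lines[ids == d]
    stop2("duplicate doc_id '", d, "' at lines ",
          paste(ln, collapse = " and "))
  }
  corpus(recs$records, name = name)
}

read_corpus_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- which(nzchar(trimws(lines)))
  records <- vector("list", length(keep))
  errs <- character(0)
  for (i in seq_along(keep)) {
    ln <- keep[i]
    rec <- tryCatch({
      x <- jsonlite::fromJSON(lines[ln], simplifyVector = TRUE)
      document_record(
        doc_id = x$doc_id, title = x$title %||% "",
        abstract = x$abstract %||% "",
        subject_headings = unlist(x$subject_headings) %||% character(0),
        accessions = as.character(unlist(x$accessions) %||% character(0)),
        pub_year = x$pub_year %||% NA_integer_,
        source_dbs = unlist(x$source_dbs) %||% "EMBASE",
        relevant = x$relevant %||% FALSE,
        pub_type = x$pub_type %||% "article")
    }, error = function(e) conditionMessage(e))
    if (is.character(rec)) errs <- c(errs, paste0("line ", ln, ": ", rec))
    else records[[i]] <- rec
  }
  if (length(errs))
    stop2("invalid corpus records:\n  ", paste(errs, collapse = "\n  "))
  list(records = records, lines = keep)
}

split_multi <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  trimws(strsplit(x, ";", fixed = TRUE)[[1]])
}

read_corpus_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  records <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    records[[i]] <- document_record(
      doc_id = df$doc_id[i], title = df$title[i] %||% "",
      abstract = if ("abstract" %in% names(df)) df$abstract[i] else "",
      subject_headings = split_multi(
        if ("subject_headings" %in% names(df)) df$subject_headings[i] else ""),
      accessions = split_multi(
        if ("accessions" %in% names(df)) df$accessions[i] else ""),
      pub_year = if ("pub_year" %in% names(df)) df$pub_year[i] else NA,
      source_dbs = {
        s <- split_multi(
          if ("source_dbs" %in% names(df)) df$source_dbs[i] else "EMBASE")
        if (length(s)) s else "EMBASE"
      },
      relevant = tolower(df$relevant[i] %||% "false") %in%
        c("true", "t", "1", "yes"),
      pub_type = if ("pub_type" %in% names(df)) df$pub_type[i] else "article")
  }
  list(records = records, lines = seq_len(nrow(df)) + 1L)
}

read_corpus_ris <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  records <- list()
  rec_lines <- integer(0)
  cur <- NULL
  start_line <- NA_integer_
  flush <- function() {
    if (is.null(cur)) return()
    records[[length(records) + 1L]] <<- document_record(
      doc_id = cur$ID %||% cur$AN[1],
      title = paste(cur$TI %||% "", collapse = " "),
      abstract = paste(cur$AB %||% "", collapse = " "),
      subject_headings = cur$KW %||% character(0),
      accessions = cur$AN %||% character(0),
      pub_year = (cur$PY %||% NA_character_)[1],
      source_dbs = cur$DB %||% "EMBASE",
      relevant = tolower((cur$RL %||% "false")[1]) %in%
        c("true", "t", "1", "yes"),
      pub_type = (cur$PT %||% "article")[1])
    rec_lines[length(rec_lines) + 1L] <<- start_line
    cur <<- NULL
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln))) next
    m <- regmatches(ln, regexec("^([A-Z][A-Z0-9])  ?- ?(.*)$", ln))[[1]]
    if (length(m) == 0)
      stop2("line ", i, ": not a tagged RIS-like line: ", ln)
    tag <- m[2]; val <- trimws(m[3])
    if (tag == "ER") { flush(); next }
    if (is.null(cur)) { cur <- list(); start_line <- i }
    cur[[tag]] <- c(cur[[tag]], val)
  }
  flush()
  list(records = records, lines = rec_lines)
}

#' Write a corpus as JSON-lines
#'
#' @param x a `corpus`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(x, path) {
  stopifnot(inherits(x, "corpus"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (r in x$records) {
    writeLines(jsonlite::toJSON(list(
      doc_id = r$doc_id, title = r$title, abstract = r$abstract,
      subject_headings = r$subject_headings, accessions = r$accessions,
      pub_year = r$pub_year, source_dbs = r$source_dbs,
      relevant = r$relevant, pub_type = r$pub_type
    ), auto_unbox = TRUE, null = "null", na = "null"), con)
  }
  invisible(path)
}

#' Deduplicate records sharing accession numbers or normalized titles
#'
#' Bibliographic snapshots contain duplicate and triplicate records: the
#' same logical document indexed under two accession numbers, or re-indexed
#' with typographical title variants.  Records are clustered when they share
#' any accession number and, when `"title_year"` is among the keys, when
#' their normalized titles (lowercase, punctuation and diacritics stripped,
#' whitespace collapsed) and publication years coincide.  Each cluster is
#' merged into one surviving record (the first by doc_id order) carrying the
#' union of accessions, source databases and subject headings.
#'
#' Merging records with contradictory relevance labels is refused: a
#' screening conflict must be resolved upstream, never silently.
#'
#' @param x a `corpus`.
#' @param keys character vector from `c("accession", "title_year")`.
#' @return a list with elements `corpus` (deduplicated) and `report`
#'   (data.frame with columns `cluster_id`, `doc_id`, `accession`,
#'   `reason`; one row per member of each multi-record cluster).
#' @export
dedup_records <- function(x, keys = c("accession", "title_year")) {
  stopifnot(inherits(x, "corpus"))
  keys <- match.arg(keys, several.ok = TRUE)
  n <- length(x$records)
  if (n == 0) {
    return(list(corpus = x, report = empty_dedup_report()))
  }
  ## union-find over record indices
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  unite <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  reason <- rep("", n)
  if ("accession" %in% keys) {
    acc_map <- list()
    for (i in seq_len(n)) {
      for (a in x$records[[i]]$accessions) {
        j <- acc_map[[a]]
        if (!is.null(j)) {
          unite(i, j)
          reason[i] <- reason[j] <- "shared accession"
        } else acc_map[[a]] <- i
      }
    }
  }
  if ("title_year" %in% keys) {
    key <- vapply(x$records, function(r) {
      t <- normalize_title(r$title)
      if (!nzchar(t)) return(NA_character_)
      paste0(t, "|", r$pub_year)
    }, character(1))
    seen <- list()
    for (i in seq_len(n)) {
      k <- key[i]
      if (is.na(k)) next
      j <- seen[[k]]
      if (!is.null(j)) {
        unite(i, j)
        if (!nzchar(reason[i])) reason[i] <- "title+year match"
        if (!nzchar(reason[j])) reason[j] <- "title+year match"
      } else seen[[k]] <- i
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  clusters <- split(seq_len(n), root)
  multi <- Filter(function(m) length(m) > 1, clusters)
  ## conflicting labels within a cluster are an error, never a silent merge
  for (m in multi) {
    labs <- vapply(x$records[m], function(r) r$relevant, logical(1))
    if (length(unique(labs)) > 1) {
      ids <- vapply(x$records[m], function(r) r$doc_id, character(1))
      stop2("conflicting relevance labels within duplicate cluster: ",
            paste(ids, collapse = ", "))
    }
  }
  surv <- vector("list", length(clusters))
  for (k in seq_along(clusters)) {
    m <- sort(clusters[[k]])
    r <- x$records[[m[1]]]
    if (length(m) > 1) {
      r$accessions <- unique(unlist(
        lapply(x$records[m], function(z) z$accessions)))
      r$source_dbs <- unique(unlist(
        lapply(x$records[m], function(z) z$source_dbs)))
      r$subject_headings <- unique(unlist(
        lapply(x$records[m], function(z) z$subject_headings)))
    }
    surv[[k]] <- r
  }
  rep_rows <- list()
  cid <- 0L
  for (m in multi) {
    cid <- cid + 1L
    for (i in sort(m)) {
      r <- x$records[[i]]
      rep_rows[[length(rep_rows) + 1L]] <- data.frame(
        cluster_id = cid, doc_id = r$doc_id,
        accession = paste(r$accessions, collapse = ";"),
        reason = reason[i], stringsAsFactors = FALSE)
    }
  }
  report <- if (length(rep_rows)) do.call(rbind, rep_rows)
            else empty_dedup_report()
  list(corpus = corpus(surv, name = x$name,
                       snapshot_date = x$snapshot_date),
       report = report)
}

empty_dedup_report <- function() {
  data.frame(cluster_id = integer(0), doc_id = character(0),
             accession = character(0), reason = character(0),
             stringsAsFactors = FALSE)
}

#' Partition a corpus into publication-year strata
#'
#' @param x a `corpus`.
#' @param breaks list of 2-vectors `c(from, to)` of inclusive year
#'   intervals; intervals must be disjoint.
#' @return named list of corpora, one per interval (named
#'   `"from-to"`) plus an `"unassigned"` stratum for records whose year is
#'   missing or falls in no interval.  Stratum sizes always sum to the
#'   corpus size.
#' @export
stratify_by_year <- function(x, breaks) {
  stopifnot(inherits(x, "corpus"))
  if (!is.list(breaks) || !length(breaks))
    stop2("`breaks` must be a non-empty list of c(from, to) intervals")
  iv <- lapply(breaks, function(b) {
    b <- as.integer(b)
    if (length(b) != 2 || any(is.na(b)) || b[1] > b[2])
      stop2("each interval must be c(from, to) with from <= to")
    b
  })
  ## disjointness check over the expanded years
  yrs <- unlist(lapply(iv, function(b) seq(b[1], b[2])))
  if (anyDuplicated(yrs)) stop2("year intervals overlap")
  labels <- vapply(iv, function(b) paste0(b[1], "-", b[2]), character(1))
  years <- vapply(x$records, function(r) r$pub_year, integer(1))
  assign <- rep("unassigned", length(x$records))
  for (k in seq_along(iv)) {
    inb <- !is.na(years) & years >= iv[[k]][1] & years <= iv[[k]][2]
    assign[inb] <- labels[k]
  }
  out <- lapply(c(labels, "unassigned"), function(lbl) {
    corpus(x$records[assign == lbl],
           name = paste0(x$name, "[", lbl, "]"),
           snapshot_date = x$snapshot_date)
  })
  names(out) <- c(labels, "unassigned")
  out
}
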