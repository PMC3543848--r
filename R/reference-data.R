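## Reference data shipped with the package: the published off-label
## retrieval strategies for OvidSP EMBASE and their reported contingency
## counts, used for exact recomputation of every derivable percentage.

#' Gold-standard denominators of the shipped reference tables
#'
#' The off-label drug use reference gold standard: 4067 relevant records
#' across EMBASE and MEDLINE (full set), of which 3846 were retrievable
#' within EMBASE (internal set), out of 6785 screened records.
#'
#' @return named integer vector with elements `full`, `internal`,
#'   `screened`.
#' @export
reference_gold_counts <- function() {
  c(full = 4067L, internal = 3846L, screened = 6785L)
}

ref_path <- function(file) {
  p <- system.file("extdata", file, package = "hedgedev")
  if (!nzchar(p)) stop2("reference data file not found: ", file)
  p
}

#' Load a shipped reference performance table
#'
#' `"single"`: the 15 highest-sensitivity single queries with their
#' retrieval counts and reported (rounded) percentages.  `"hsss"`: the
#' 32-line sensitivity-maximizing strategy with cumulative counts.
#' `"balanced"`: the 23-line sensitivity- and precision-maximizing
#' strategy (final line applies the NOT exclusion).  Counts are integers;
#' `*_printed` columns carry the percentages as originally rounded (1
#' decimal for `"single"`, 2 for the cumulative tables).
#'
#' @param which `"single"`, `"hsss"` or `"balanced"`.
#' @return data.frame.
#' @seealso [reference_strategy()] for the query lines as a strategy.
#' @export
reference_table <- function(which = c("single", "hsss", "balanced")) {
  which <- match.arg(which)
  f <- switch(which, single = "table_single_queries.tsv",
              hsss = "table_hsss_sensitivity.tsv",
              balanced = "table_hsss_balanced.tsv")
  utils::read.delim(ref_path(f), stringsAsFactors = FALSE,
                    check.names = FALSE, quote = "")
}

#' Load a shipped reference strategy
#'
#' The strategy's query lines as a [as_strategy()] object; `"hsss"` is the
#' sensitivity-maximizing 32-line version, `"balanced"` the 23-line
#' sensitivity- and precision-maximizing version whose final line NOTs out
#' stent and veterinary content.
#'
#' @param which `"hsss"` or `"balanced"`.
#' @return a `search_strategy`.
#' @export
reference_strategy <- function(which = c("hsss", "balanced")) {
  which <- match.arg(which)
  f <- switch(which, hsss = "strategy_hsss_sensitivity.txt",
              balanced = "strategy_hsss_balanced.txt")
  read_strategy(ref_path(f))
}
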