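## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Presentation-layer rounding used for all printed percentages.  Plain
#' `round()` rounds half to even, which does not reproduce the rounding of
#' published performance tables (e.g. 88.05 must print as 88.1, not 88.0).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up (away from zero).
#' @examples
#' round_half_up(88.05, 1)  # 88.1
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

## lowercase, hyphen/punctuation-insensitive tokenizer.
## "Off-label" -> c("off", "label"); digits are kept as token characters.
tokenize_text <- function(x) {
  x <- tolower(x)
  x <- gsub("[^a-z0-9]+", " ", x)
  x <- trimws(x)
  out <- strsplit(x, " ", fixed = TRUE)
  lapply(out, function(t) t[nzchar(t)])
}

## Single string variant returning a character vector.
tokenize1 <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  tokenize_text(x)[[1]]
}

## Normalize a title for deduplication: lowercase, strip diacritics,
## drop punctuation, collapse whitespace.
normalize_title <- function(x) {
  x <- tolower(x)
  x <- iconv(x, from = "", to = "ASCII//TRANSLIT")
  x <- gsub("[^a-z0-9]+", " ", x)
  trimws(gsub(" +", " ", x))
}

stop2 <- function(...) stop(..., call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 && x == floor(x)
}
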