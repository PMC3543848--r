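## Ovid-dialect query parser: boolean operators (OR / AND / NOT), ADJn
## proximity, truncation and wildcards, trailing field codes, quoted
## phrases, and line references (or/1-31) inside strategies.

FIELD_CODES <- c("af", "mp", "ab_ti", "ab", "ti", "sh")

q_node <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "ovid_query")
}
q_term <- function(tokens) q_node("term", tokens = as.character(tokens))
q_or <- function(children) q_node("or", children = children)
q_and <- function(children) q_node("and", children = children)
q_not <- function(keep, drop) q_node("not", children = list(keep, drop))
q_adj <- function(n, left, right)
  q_node("adj", n = as.integer(n), children = list(left, right))
q_field <- function(code, child) {
  code <- match.arg(code, FIELD_CODES)
  q_node("field", code = code, children = list(child))
}
q_lineref <- function(from, to)
  q_node("lineref", from = as.integer(from), to = as.integer(to))

parse_error <- function(text, pos, msg) {
  stop2("query parse error at position ", pos, ": ", msg,
        "\n  in: ", text)
}

## Lexer ---------------------------------------------------------------

lex_query <- function(text) {
  s <- tolower(text)
  n <- nchar(s)
  i <- 1L
  toks <- list()
  push <- function(type, pos, ...) {
    toks[[length(toks) + 1L]] <<- c(list(type = type, pos = pos), list(...))
  }
  re <- function(pattern) {
    m <- regexpr(paste0("^", pattern), substr(s, i, n), perl = TRUE)
    if (m == -1L) return(NULL)
    substr(s, i, i + attr(m, "match.length") - 1L)
  }
  while (i <= n) {
    ch <- substr(s, i, i)
    if (grepl("[[:space:],]", ch)) { i <- i + 1L; next }
    if (ch == "(") { push("LPAREN", i); i <- i + 1L; next }
    if (ch == ")") { push("RPAREN", i); i <- i + 1L; next }
    if (ch == ".") {
      m <- re("\\.\\s*(af|mp|ab\\s*,\\s*ti|ab|ti|sh)\\s*\\.")
      if (!is.null(m)) {
        code <- gsub("[.[:space:]]", "", m)
        code <- if (code == "ab,ti") "ab_ti" else code
        push("FIELD", i, code = code)
        i <- i + nchar(m)
        next
      }
      parse_error(text, i, "unknown field code")
    }
    if (ch == "\"") {
      m <- re("\"[^\"]*\"")
      if (is.null(m)) parse_error(text, i, "unterminated quote")
      push("QUOTED", i, value = substr(m, 2, nchar(m) - 1L))
      i <- i + nchar(m)
      next
    }
    m <- re("or\\s*/\\s*([0-9]+)\\s*-\\s*([0-9]+)")
    if (!is.null(m)) {
      nums <- as.integer(regmatches(m, gregexpr("[0-9]+", m))[[1]])
      if (nums[1] > nums[2])
        parse_error(text, i, "malformed line reference (from > to)")
      push("LINEREF", i, from = nums[1], to = nums[2])
      i <- i + nchar(m)
      next
    }
    m <- re("[a-z0-9*?#$'-]+")
    if (!is.null(m)) {
      word <- m
      if (word == "or") push("OR", i)
      else if (word == "and") push("AND", i)
      else if (word == "not") push("NOT", i)
      else if (grepl("^adj[0-9]*$", word)) {
        nn <- sub("^adj", "", word)
        push("ADJ", i, n = if (nzchar(nn)) as.integer(nn) else 1L)
      } else push("WORD", i, value = word)
      i <- i + nchar(m)
      next
    }
    parse_error(text, i, paste0("unexpected character '", ch, "'"))
  }
  toks
}

## split a raw query word into term tokens consistent with the document
## tokenizer (hyphens and apostrophes are boundaries); wildcards survive.
word_to_tokens <- function(word) {
  parts <- strsplit(word, "[-']+")[[1]]
  parts[nzchar(parts)]
}

## Recursive-descent parser --------------------------------------------
## precedence (loosest to tightest): OR < NOT/AND < ADJn < atom/phrase

#' Parse an Ovid-dialect query string
#'
#' Grammar understood: boolean `or` / `and` / `not` (binary set
#' difference), `adjN` proximity (binds tighter than `not`/`or`),
#' parentheses, quoted phrases, truncation and wildcards (`*` trailing
#' truncation, `?` zero-or-one character, `#` exactly one character, `$`
#' synonym of `*`), trailing field codes (`.af.`, `.mp.`, `.ab.`, `.ti.`,
#' `.ab,ti.`, `.sh.`) and strategy line references (`or/1-31`).  A trailing
#' field code binds to the immediately preceding parenthesized group or to
#' the whole preceding phrase.  Parsing is case-insensitive; an unquoted or
#' quoted multi-word phrase means exact adjacency in order.
#'
#' @param text a single query string.
#' @return an expression tree of class `ovid_query`.
#' @examples
#' parse_query("(off adj2 label*).mp.")
#' parse_query("(or/1-22) not (stent* or veterinar*).af.")
#' @export
parse_query <- function(text) {
  if (!is.character(text) || length(text) != 1 || !nzchar(trimws(text)))
    stop2("`text` must be a single non-empty query string")
  toks <- lex_query(text)
  if (length(toks) == 0) stop2("empty query: ", text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$i <- 1L
  st$text <- text
  node <- p_or(st)
  if (st$i <= length(st$toks))
    parse_error(text, st$toks[[st$i]]$pos, "unexpected trailing input")
  node
}

peek <- function(st) if (st$i <= length(st$toks)) st$toks[[st$i]] else NULL
advance <- function(st) { t <- st$toks[[st$i]]; st$i <- st$i + 1L; t }

p_or <- function(st) {
  children <- list(p_notand(st))
  repeat {
    t <- peek(st)
    if (is.null(t) || t$type != "OR") break
    advance(st)
    children[[length(children) + 1L]] <- p_notand(st)
  }
  if (length(children) == 1L) children[[1L]] else q_or(children)
}

p_notand <- function(st) {
  left <- p_adj(st)
  repeat {
    t <- peek(st)
    if (is.null(t) || !(t$type %in% c("NOT", "AND"))) break
    advance(st)
    right <- p_adj(st)
    left <- if (t$type == "NOT") q_not(left, right)
            else q_and(list(left, right))
  }
  left
}

p_adj <- function(st) {
  left <- p_phrase(st)
  repeat {
    t <- peek(st)
    if (is.null(t) || t$type != "ADJ") break
    advance(st)
    right <- p_phrase(st)
    left <- q_adj(t$n, left, right)
  }
  left
}

p_phrase <- function(st) {
  words <- character(0)
  grp <- NULL
  start <- peek(st)
  mix_err <- function(t) parse_error(
    st$text, t$pos,
    "cannot mix a parenthesized group with adjacent bare terms")
  repeat {
    t <- peek(st)
    if (is.null(t)) break
    if (t$type == "WORD") {
      if (!is.null(grp)) mix_err(t)
      advance(st)
      words <- c(words, word_to_tokens(t$value))
    } else if (t$type == "QUOTED") {
      if (!is.null(grp)) mix_err(t)
      advance(st)
      words <- c(words, unlist(lapply(strsplit(t$value, "[[:space:]]+")[[1]],
                                      word_to_tokens)))
    } else if (t$type == "LPAREN") {
      if (!is.null(grp) || length(words)) mix_err(t)
      advance(st)
      grp <- p_or(st)
      t2 <- peek(st)
      if (is.null(t2) || t2$type != "RPAREN")
        parse_error(st$text, if (is.null(t2)) nchar(st$text) else t2$pos,
                    "unbalanced parentheses")
      advance(st)
    } else if (t$type == "LINEREF") {
      if (!is.null(grp) || length(words)) mix_err(t)
      advance(st)
      grp <- q_lineref(t$from, t$to)
    } else if (t$type == "FIELD") {
      advance(st)
      unit <- if (!is.null(grp)) grp
              else if (length(words)) q_term(words)
              else parse_error(st$text, t$pos,
                               "field code with nothing to scope")
      grp <- q_field(t$code, unit)
      words <- character(0)
    } else break
  }
  if (!is.null(grp)) {
    if (length(words)) mix_err(start)
    return(grp)
  }
  if (length(words) == 0)
    parse_error(st$text,
                if (is.null(start)) nchar(st$text) else start$pos,
                "expected a search term")
  q_term(words)
}

## Serialization --------------------------------------------------------

node_prec <- function(node) {
  switch(node$kind,
         term = 4L, lineref = 4L, field = 4L,
         adj = 3L, not = 2L, and = 2L, or = 1L)
}

ser <- function(node, min_prec = 1L) {
  out <- switch(node$kind,
    term = paste(node$tokens, collapse = " "),
    lineref = paste0("or/", node$from, "-", node$to),
    field = {
      child <- node$children[[1L]]
      inner <- ser(child, 1L)
      code <- if (node$code == "ab_ti") "ab,ti" else node$code
      if (child$kind %in% c("term", "lineref"))
        paste0(inner, ".", code, ".")
      else paste0("(", inner, ").", code, ".")
    },
    adj = paste0(ser(node$children[[1L]], 3L), " adj", node$n, " ",
                 ser(node$children[[2L]], 4L)),
    not = paste0(ser(node$children[[1L]], 2L), " not ",
                 ser(node$children[[2L]], 3L)),
    and = paste(vapply(seq_along(node$children), function(k) {
      ser(node$children[[k]], if (k == 1L) 2L else 3L)
    }, character(1)), collapse = " and "),
    or = paste(vapply(node$children, ser, character(1), min_prec = 2L),
               collapse = " or "))
  if (node_prec(node) < min_prec) paste0("(", out, ")") else out
}

#' Serialize a query tree back to Ovid-dialect text
#'
#' `parse_query(serialize_query(x))` is structurally identical to `x` for
#' every valid tree (the round-trip property); parenthesization may differ
#' from the original source string.
#'
#' @param node an `ovid_query` tree.
#' @return a single query string.
#' @export
serialize_query <- function(node) {
  stopifnot(inherits(node, "ovid_query"))
  ser(node, 1L)
}

#' @export
print.ovid_query <- function(x, ...) {
  cat("<ovid_query> ", serialize_query(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.ovid_query <- function(x, ...) serialize_query(x)

## maximum strategy line referenced anywhere in a tree (0 if none)
max_lineref <- function(node) {
  if (node$kind == "lineref") return(node$to)
  if (is.null(node$children)) return(0L)
  max(c(0L, vapply(node$children, max_lineref, integer(1))))
}
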