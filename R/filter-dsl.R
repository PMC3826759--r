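# Read-filter expression language.
#
# Filters decide which aligned reads may contribute evidence to a pileup.
# They are written as boolean expressions over per-read attributes, e.g.
#
#   "align_len >= 35 or (second_in_pair and proper_pair)"
#
# Grammar (whitespace-insensitive):
#   expr    := and_ex ( "or" and_ex )*
#   and_ex  := not_ex ( "and" not_ex )*
#   not_ex  := "not" not_ex | primary
#   primary := "(" expr ")" | comparison | flag
#   comparison := field cmp number        cmp in < <= > >= == !=
#   field   := mapq_single | align_len | mismatches
#   flag    := duplicate | proper_pair | second_in_pair

.dsl_numeric_fields <- c(
  mapq_single = "mapq_single",
  align_len   = "align_len",
  mismatches  = "mismatches"
)

.dsl_flag_fields <- c(
  duplicate      = "is_duplicate",
  proper_pair    = "is_proper_pair",
  second_in_pair = "is_second_in_pair"
)

.dsl_tokenize <- function(text) {
  pat <- paste0(
    "(?<ws>\\s+)|",
    "(?<num>\\d+(\\.\\d+)?)|",
    "(?<op><=|>=|==|!=|<|>)|",
    "(?<lpar>\\()|(?<rpar>\\))|",
    "(?<word>[A-Za-z_][A-Za-z0-9_]*)"
  )
  tokens <- list()
  i <- 1L
  while (i <= nchar(text)) {
    m <- regexpr(pat, substr(text, i, nchar(text)), perl = TRUE)
    if (m != 1L) {
      abort(sprintf(
        "filter expression: unexpected character '%s' at position %d",
        substr(text, i, i), i
      ), class = "snvpure_dsl_error")
    }
    len <- attr(m, "match.length")
    tok <- substr(text, i, i + len - 1L)
    if (!grepl("^\\s+$", tok)) {
      type <-
        if (grepl("^\\d", tok)) "num"
        else if (tok %in% c("<", "<=", ">", ">=", "==", "!=")) "op"
        else if (tok == "(") "lpar"
        else if (tok == ")") "rpar"
        else "word"
      tokens[[length(tokens) + 1L]] <- list(text = tok, type = type, pos = i)
    }
    i <- i + len
  }
  tokens
}

#' Parse a read-filter expression
#'
#' Compiles a filter expression written in the package's small boolean
#' language into a `filter_spec` object that [passes_filter()] and
#' [build_pileup()] can evaluate against a reads table. Available numeric
#' fields are `mapq_single` (single-read mapping quality), `align_len`
#' (aligned length in bp) and `mismatches` (mismatch count to the
#' reference); boolean flags are `duplicate`, `proper_pair` and
#' `second_in_pair`. Combine atoms with `and`, `or`, `not` and parentheses.
#'
#' @param text A single non-empty string containing the expression.
#' @return A `filter_spec` object (the compiled predicate plus its source
#'   text).
#' @examples
#' spec <- parse_filter_spec("mapq_single > 10 and mismatches <= 3 and not duplicate")
#' spec
#' @seealso [filter_preset()] for the built-in SOLiD and Illumina filters.
#' @export
parse_filter_spec <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) ||
      !nzchar(trimws(text))) {
    abort("filter expression must be a single non-empty string",
          class = "snvpure_dsl_error")
  }
  tokens <- .dsl_tokenize(text)
  idx <- 1L

  peek <- function() if (idx <= length(tokens)) tokens[[idx]] else NULL
  advance <- function() {
    tok <- tokens[[idx]]
    idx <<- idx + 1L
    tok
  }
  fail <- function(msg, tok = peek()) {
    where <- if (is.null(tok)) "end of expression"
             else sprintf("'%s' at position %d", tok$text, tok$pos)
    abort(sprintf("filter expression: %s near %s", msg, where),
          class = "snvpure_dsl_error")
  }

  parse_primary <- function() {
    tok <- peek()
    if (is.null(tok)) fail("expected a term")
    if (tok$type == "lpar") {
      advance()
      inner <- parse_or()
      close <- peek()
      if (is.null(close) || close$type != "rpar") fail("expected ')'")
      advance()
      return(call("(", inner))
    }
    if (tok$type != "word") fail("expected a field name, flag or '('")
    advance()
    word <- tok$text
    if (word %in% names(.dsl_flag_fields)) {
      return(as.name(.dsl_flag_fields[[word]]))
    }
    if (word %in% names(.dsl_numeric_fields)) {
      op <- peek()
      if (is.null(op) || op$type != "op") fail("expected a comparison operator")
      advance()
      num <- peek()
      if (is.null(num) || num$type != "num") fail("expected a number")
      advance()
      return(call(op$text, as.name(.dsl_numeric_fields[[word]]),
                  as.numeric(num$text)))
    }
    if (word %in% c("and", "or", "not")) fail("misplaced keyword", tok)
    fail(sprintf("unknown field '%s'", word), tok)
  }

  parse_not <- function() {
    tok <- peek()
    if (!is.null(tok) && tok$type == "word" && tok$text == "not") {
      advance()
      return(call("!", parse_not()))
    }
    parse_primary()
  }

  parse_and <- function() {
    lhs <- parse_not()
    repeat {
      tok <- peek()
      if (is.null(tok) || tok$type != "word" || tok$text != "and") return(lhs)
      advance()
      lhs <- call("&", lhs, parse_not())
    }
  }

  parse_or <- function() {
    lhs <- parse_and()
    repeat {
      tok <- peek()
      if (is.null(tok) || tok$type != "word" || tok$text != "or") return(lhs)
      advance()
      lhs <- call("|", lhs, parse_and())
    }
  }

  expr <- parse_or()
  if (!is.null(peek())) fail("unexpected trailing input")

  structure(
    list(source = text, expr = expr),
    class = "filter_spec"
  )
}

#' @export
print.filter_spec <- function(x, ...) {
  cat("<filter_spec> ", x$source, "\n", sep = "")
  invisible(x)
}

#' Built-in read-filter presets
#'
#' Platform-tuned read filters for SOLiD v4 and Illumina paired-end data.
#' The SOLiD preset requires a 35 bp alignment (or a properly paired second
#' read), single mapping quality above 15 and at most 2 mismatches; the
#' Illumina preset requires single mapping quality above 10 and at most 3
#' mismatches. Both reject PCR-duplicate-marked reads.
#'
#' @param platform `"solid"` or `"illumina"`.
#' @return A `filter_spec`.
#' @examples
#' filter_preset("illumina")
#' @export
filter_preset <- function(platform = c("solid", "illumina")) {
  platform <- match.arg(platform)
  text <- switch(platform,
    solid = paste(
      "(align_len >= 35 or (second_in_pair and proper_pair))",
      "and mapq_single > 15 and mismatches <= 2 and not duplicate"
    ),
    illumina = "mapq_single > 10 and mismatches <= 3 and not duplicate"
  )
  parse_filter_spec(text)
}

#' Evaluate a read filter
#'
#' @param reads A reads table (see [reads_tbl()]).
#' @param spec A `filter_spec` from [parse_filter_spec()] or
#'   [filter_preset()], or a string to be parsed on the fly.
#' @return A logical vector, one element per read.
#' @examples
#' rd <- reads_tbl(chrom = "chr1", start = 100, strand = "+", bases = "A",
#'                 quals = "I", mapq_single = 20)
#' passes_filter(rd, filter_preset("illumina"))
#' @export
passes_filter <- function(reads, spec) {
  if (is.character(spec)) spec <- parse_filter_spec(spec)
  stopifnot(inherits(spec, "filter_spec"))
  reads <- validate_reads(reads)
  out <- eval(spec$expr, envir = reads, enclos = baseenv())
  # guarantee a clean logical vector (comparisons on NA fields surface here)
  if (anyNA(out)) {
    abort("filter evaluation produced NA; check read fields for missing values")
  }
  as.logical(out)
}
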