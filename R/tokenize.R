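# Shared tokenizer for the SPARQL-subset parser and the restricted Turtle
# reader. Produces a tibble of tokens with 1-based line/column positions so
# parse errors can point at the offending input.

TOKEN_PATTERNS <- c(
  IRIREF  = "<[^<>\"{}|^`\\\\[:space:]]*>",
  # "lex"@lang | "lex"^^<iri> | "lex"^^pname | "lex"
  STRING  = "\"(?:[^\"\\\\]|\\\\.)*\"(?:@[A-Za-z][A-Za-z0-9-]*|\\^\\^<[^<>\"{}|^`\\\\[:space:]]*>|\\^\\^[A-Za-z][A-Za-z0-9_-]*:[A-Za-z0-9_%-]+)?",
  VAR     = "[?$][A-Za-z_][A-Za-z0-9_]*",
  BLANK   = "_:[A-Za-z0-9][A-Za-z0-9_.-]*",
  # prefixed name; local part may contain interior dots (ec:3.2.1.161)
  PNAME   = "(?:[A-Za-z][A-Za-z0-9_-]*)?:(?:[A-Za-z0-9_%-]|\\.(?=[A-Za-z0-9_%-]))*",
  NUMBER  = "[+-]?[0-9]+(?:\\.[0-9]+)?(?:[eE][+-]?[0-9]+)?",
  ATNAME  = "@[A-Za-z][A-Za-z0-9-]*",
  NAME    = "[A-Za-z][A-Za-z0-9_]*",
  OP2     = "&&|\\|\\||!=|<=|>=|\\^\\^",
  PUNCT   = "[{}()\\[\\].;,=<>!+*/-]"
)

tokenize <- function(text) {
  text <- paste(text, collapse = "\n")
  types <- character(0); values <- character(0); lines <- integer(0); cols <- integer(0)
  pos <- 1L; line <- 1L; col <- 1L
  n <- nchar(text)
  advance <- function(s) {
    nl <- gregexpr("\n", s, fixed = TRUE)[[1]]
    if (nl[1] == -1) {
      col <<- col + nchar(s)
    } else {
      line <<- line + length(nl)
      col <<- nchar(s) - max(nl) + 1L
    }
    pos <<- pos + nchar(s)
  }
  while (pos <= n) {
    rest <- substring(text, pos)
    ws <- regmatches(rest, regexpr("^(?:[[:space:]]+|#[^\n]*)+", rest))
    if (length(ws) == 1) { advance(ws); next }
    matched <- FALSE
    for (ty in names(TOKEN_PATTERNS)) {
      m <- regmatches(rest, regexpr(paste0("^(?:", TOKEN_PATTERNS[[ty]], ")"), rest, perl = TRUE))
      if (length(m) == 1 && nzchar(m)) {
        types <- c(types, ty); values <- c(values, m)
        lines <- c(lines, line); cols <- c(cols, col)
        advance(m)
        matched <- TRUE
        break
      }
    }
    if (!matched) {
      stop(sprintf("tokenizer: unexpected character '%s' at line %d, column %d",
                   substr(rest, 1, 1), line, col), call. = FALSE)
    }
  }
  tibble::tibble(type = types, value = values, line = lines, col = cols)
}

# Cursor over a token tibble used by the recursive-descent parsers.
new_cursor <- function(tokens) {
  env <- new.env(parent = emptyenv())
  env$tokens <- tokens
  env$i <- 1L
  env
}

cur_eof <- function(cur) cur$i > nrow(cur$tokens)
cur_peek <- function(cur, ahead = 0L) {
  i <- cur$i + ahead
  if (i > nrow(cur$tokens)) return(NULL)
  as.list(cur$tokens[i, ])
}
cur_next <- function(cur) {
  tk <- cur_peek(cur)
  if (is.null(tk)) stop("parse error: unexpected end of input", call. = FALSE)
  cur$i <- cur$i + 1L
  tk
}
cur_error <- function(cur, expected) {
  tk <- cur_peek(cur)
  if (is.null(tk)) {
    stop(sprintf("parse error: expected %s but reached end of input", expected), call. = FALSE)
  }
  stop(sprintf("parse error at line %d, column %d: expected %s, found '%s'",
               tk$line, tk$col, expected, tk$value), call. = FALSE)
}
# keyword match, case-insensitive
cur_is_kw <- function(cur, kw, ahead = 0L) {
  tk <- cur_peek(cur, ahead)
  !is.null(tk) && tk$type == "NAME" && toupper(tk$value) == toupper(kw)
}
cur_is_val <- function(cur, val, ahead = 0L) {
  tk <- cur_peek(cur, ahead)
  !is.null(tk) && tk$value == val
}
cur_expect_val <- function(cur, val) {
  if (!cur_is_val(cur, val)) cur_error(cur, paste0("'", val, "'"))
  cur_next(cur)
}
cur_expect_kw <- function(cur, kw) {
  if (!cur_is_kw(cur, kw)) cur_error(cur, kw)
  cur_next(cur)
}
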