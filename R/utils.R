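`%||%` <- function(x, y) if (is.null(x)) y else x

#' @keywords internal
#' @noRd
stop_gsmn <- function(...) stop(sprintf(...), call. = FALSE)

warn_gsmn <- function(...) warning(sprintf(...), call. = FALSE)

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

## ---- SBML SId escaping -------------------------------------------------
## SBML SIds allow only [A-Za-z0-9_] and must not start with a digit.
## Any other character is escaped as __<decimal codepoint>__ (the libsbml
## convention), which is unambiguous and reversible.

sid_escape <- function(x) {
  vapply(x, function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    ok <- grepl("^[A-Za-z0-9_]$", chars)
    chars[!ok] <- sprintf("__%d__", utf8ToInt(paste0(chars[!ok], collapse = ""))[seq_len(sum(!ok))])
    # note: utf8ToInt on the collapsed string keeps the original order
    paste0(chars, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

sid_unescape <- function(x) {
  vapply(x, function(s) {
    m <- gregexpr("__([0-9]+)__", s)
    regmatches(s, m) <- lapply(regmatches(s, m), function(hits) {
      if (length(hits) == 0) return(hits)
      vapply(hits, function(h) {
        intToUtf8(as.integer(sub("^__([0-9]+)__$", "\\1", h)))
      }, character(1))
    })
    s
  }, character(1), USE.NAMES = FALSE)
}

## ---- GPR boolean expressions -------------------------------------------
## Grammar:  expr := term ("or" term)* ; term := factor ("and" factor)* ;
##           factor := gene-id | "(" expr ")"
## Gene ids are any token without whitespace or parentheses that is not a
## keyword. Parsed ASTs are lists: list(op = "and"|"or", args = list(...))
## or a character scalar for a leaf.

gpr_tokenize <- function(text) {
  text <- gsub("([()])", " \\1 ", text)
  toks <- strsplit(trimws(text), "[[:space:]]+")[[1]]
  toks[nzchar(toks)]
}

gpr_parse <- function(text) {
  if (!is_string(text) || !nzchar(trimws(text))) return(NULL)
  toks <- gpr_tokenize(text)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- peek(); pos <<- pos + 1L; t }
  parse_expr <- function() {
    args <- list(parse_term())
    while (!is.na(peek()) && tolower(peek()) == "or") {
      take()
      args <- c(args, list(parse_term()))
    }
    if (length(args) == 1L) args[[1]] else list(op = "or", args = args)
  }
  parse_term <- function() {
    args <- list(parse_factor())
    while (!is.na(peek()) && tolower(peek()) == "and") {
      take()
      args <- c(args, list(parse_factor()))
    }
    if (length(args) == 1L) args[[1]] else list(op = "and", args = args)
  }
  parse_factor <- function() {
    t <- take()
    if (is.na(t)) stop_gsmn("GPR parse error: unexpected end of expression in %s", sQuote(text))
    if (t == "(") {
      e <- parse_expr()
      if (!identical(take(), ")"))
        stop_gsmn("GPR parse error: unbalanced parentheses in %s", sQuote(text))
      return(e)
    }
    if (t == ")" || tolower(t) %in% c("and", "or"))
      stop_gsmn("GPR parse error: unexpected token %s in %s", sQuote(t), sQuote(text))
    t
  }
  out <- parse_expr()
  if (pos <= length(toks))
    stop_gsmn("GPR parse error: trailing tokens in %s", sQuote(text))
  out
}

gpr_deparse <- function(ast) {
  if (is.null(ast)) return("")
  if (is.character(ast)) return(ast)
  parts <- vapply(ast$args, function(a) {
    s <- gpr_deparse(a)
    # "and" binds tighter than "or": parenthesise or-children under "and"
    if (ast$op == "and" && is.list(a) && identical(a$op, "or")) s <- paste0("(", s, ")")
    s
  }, character(1))
  paste(parts, collapse = paste0(" ", ast$op, " "))
}

#' Canonicalise a GPR string
#'
#' Parses a boolean gene association ("g1 and (g2 or g3)") and re-emits it
#' in a canonical layout: lowercase operators, minimal parentheses with
#' `and` binding tighter than `or`. Used by all constructors so that
#' round-trips through SBML compare equal string-wise.
#' @param text GPR string; empty or NA means "no gene association".
#' @return canonical GPR string ("" when empty).
#' @keywords internal
gpr_canonical <- function(text) {
  if (is.null(text) || length(text) == 0 || is.na(text)) return("")
  gpr_deparse(gpr_parse(text))
}

#' Genes referenced by a GPR string
#' @keywords internal
gpr_genes <- function(text) {
  ast <- gpr_parse(text)
  collect <- function(a) {
    if (is.null(a)) return(character(0))
    if (is.character(a)) return(a)
    unlist(lapply(a$args, collect), use.names = FALSE)
  }
  sort(unique(collect(ast)))
}

#' OR-join two GPR strings
#'
#' Returns the canonical disjunction; identical inputs (or one empty input)
#' collapse to a single expression.
#' @keywords internal
gpr_or_join <- function(a, b) {
  a <- gpr_canonical(a); b <- gpr_canonical(b)
  if (!nzchar(a)) return(b)
  if (!nzchar(b)) return(a)
  if (identical(a, b)) return(a)
  gpr_canonical(paste0("(", a, ") or (", b, ")"))
}

## Artificial gene id convention: prefix + zero-padded 3-digit counter.
ARTIFICIAL_GENE_RE <- "^(t|d|u|sk|p|s)[0-9]{3}$"

is_artificial_gene_id <- function(id) grepl(ARTIFICIAL_GENE_RE, id)

format_artificial_gene <- function(prefix, n) sprintf("%s%03d", prefix, n)
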