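#' Parse a chemical formula into element counts
#'
#' Parses Hill-notation molecular formulas ("C6H12O6", "C10H16N5O13P3") into
#' a named integer vector of element counts. The dialect is deliberately
#' strict: a formula is a sequence of element symbols (one capital letter
#' optionally followed by one lowercase letter) each with an optional
#' positive integer count. Anything else -- polymer notation ("(C2H4O)n"),
#' generic groups ("R", "X" with a count of zero), charges or isotopes --
#' is reported as `unparseable` rather than guessed at. The function is
#' total: it never throws, whatever the input.
#'
#' @param text A single formula string. `NA`, `NULL` or `""` count as an
#'   absent formula.
#' @return An object of class `gsmn_elements`: a list with `elements`
#'   (named integer vector, alphabetical by symbol) and `status`, one of
#'   `"ok"`, `"absent"`, `"unparseable"`.
#' @examples
#' parse_formula("C6H12O6")$elements
#' parse_formula("(C2H4O)n")$status
ELEMENT_SYMBOLS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd", "Pm", "Sm",
  "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu", "Hf", "Ta", "W",
  "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi", "Po", "At", "Rn",
  "Fr", "Ra", "Ac", "Th", "Pa", "U", "Np", "Pu")

#' @export
parse_formula <- function(text) {
  out <- function(elements, status) {
    structure(list(elements = elements, status = status), class = "gsmn_elements")
  }
  empty <- stats::setNames(integer(0), character(0))
  if (is.null(text) || length(text) != 1L || is.na(text) || !nzchar(trimws(text)))
    return(out(empty, "absent"))
  text <- trimws(text)
  if (!grepl("^([A-Z][a-z]?[0-9]*)+$", text))
    return(out(empty, "unparseable"))
  m <- gregexpr("[A-Z][a-z]?[0-9]*", text)[[1]]
  toks <- regmatches(text, list(m))[[1]]
  syms <- sub("[0-9]*$", "", toks)
  nums <- sub("^[A-Za-z]+", "", toks)
  counts <- ifelse(nzchar(nums), suppressWarnings(as.integer(nums)), 1L)
  if (anyNA(counts) || any(counts == 0L))   # explicit zero counts are nonsense
    return(out(empty, "unparseable"))
  if (!all(syms %in% ELEMENT_SYMBOLS))      # generic groups (R, X, ...) are not elements
    return(out(empty, "unparseable"))
  tab <- tapply(counts, syms, sum)
  elements <- stats::setNames(as.integer(tab), names(tab))
  elements <- elements[order(names(elements))]
  out(elements, "ok")
}

#' @export
print.gsmn_elements <- function(x, ...) {
  if (x$status != "ok") {
    cat("<formula:", x$status, ">\n")
  } else {
    cat(paste0(names(x$elements), x$elements, collapse = " "), "\n")
  }
  invisible(x)
}

# Element-count arithmetic on named integer vectors.
element_sum <- function(a, b, w = 1) {
  syms <- union(names(a), names(b))
  va <- stats::setNames(rep(0, length(syms)), syms)
  va[names(a)] <- a
  vb <- stats::setNames(rep(0, length(syms)), syms)
  vb[names(b)] <- b
  res <- va + w * vb
  res[order(names(res))]
}

format_elements <- function(x) {
  x <- x[x != 0]
  if (length(x) == 0) return("")
  # Hill order: C first, H second, rest alphabetical
  syms <- names(x)
  ord <- order(match(syms, c("C", "H"), nomatch = 3L), syms)
  paste0(syms[ord], ifelse(x[ord] == 1, "", x[ord]), collapse = "")
}
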