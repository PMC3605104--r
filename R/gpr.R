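# Gene-protein-reaction rules: isozymes are OR, complex subunits are AND.
# Internal representation is disjunctive normal form: a list of character
# vectors, each vector one complex (AND-set); an empty list means no
# association (orphan reaction).

#' Parse a gene association string into DNF
#'
#' Accepts boolean rules such as `"g1 and g2 or g3"` or
#' `"(g1 and g2) or (g1 and g3)"` (case-insensitive `and`/`or`, optional
#' parentheses) and returns the disjunction-of-conjunctions form used
#' throughout the package.
#'
#' @param x a rule string; `""`/`NA` give an empty association.
#' @return a list of character vectors (sorted, unique gene ids per complex).
#' @export
parse_gpr <- function(x) {
  if (is.null(x) || length(x) == 0L || is.na(x) || !nzchar(trimws(x))) return(list())
  toks <- regmatches(x, gregexpr("\\(|\\)|[^()[:space:]]+", x))[[1]]
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() { pos <<- pos + 1L }
  parse_expr <- function() {
    terms <- list(parse_term())
    while (!is.na(peek()) && tolower(peek()) == "or") {
      advance()
      terms <- c(terms, list(parse_term()))
    }
    do.call(c, terms)
  }
  parse_term <- function() {
    f <- parse_factor()
    while (!is.na(peek()) && tolower(peek()) == "and") {
      advance()
      g <- parse_factor()
      # cartesian product of the two disjunctions
      f <- unlist(lapply(f, function(a) lapply(g, function(b) union(a, b))),
                  recursive = FALSE)
    }
    f
  }
  parse_factor <- function() {
    t <- peek()
    if (is.na(t)) stop("gene association parse error: unexpected end in ", sQuote(x))
    if (t == "(") {
      advance()
      e <- parse_expr()
      if (is.na(peek()) || peek() != ")") stop("gene association parse error: unbalanced '(' in ", sQuote(x))
      advance()
      return(e)
    }
    if (t == ")" || tolower(t) %in% c("and", "or")) {
      stop("gene association parse error: unexpected ", sQuote(t), " in ", sQuote(x))
    }
    advance()
    list(t)
  }
  out <- parse_expr()
  if (pos <= length(toks)) stop("gene association parse error: trailing tokens in ", sQuote(x))
  out <- lapply(out, function(cx) sort(unique(cx)))
  unique(out)
}

#' Format a DNF gene association back to a rule string
#' @param assoc a list of character vectors as returned by [parse_gpr()].
#' @return a single string, `""` for an empty association.
#' @export
format_gpr <- function(assoc) {
  if (length(assoc) == 0L) return("")
  parts <- vapply(assoc, function(cx) {
    s <- paste(cx, collapse = " and ")
    if (length(cx) > 1L && length(assoc) > 1L) paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = " or ")
}

#' Evaluate a gene association under a deletion set
#'
#' A reaction stays active iff at least one complex has no deleted member.
#' An empty association (orphan reaction: literature or spontaneous evidence,
#' no gene) always evaluates true, so orphan reactions are retained in
#' deletion screens.
#'
#' @param assoc DNF list from [parse_gpr()].
#' @param deleted_genes character vector of deleted gene ids.
#' @return logical scalar.
#' @export
evaluate_gpr <- function(assoc, deleted_genes = character()) {
  if (length(assoc) == 0L) return(TRUE)
  any(vapply(assoc, function(cx) !any(cx %in% deleted_genes), logical(1)))
}

gpr_genes <- function(assoc) sort(unique(unlist(assoc)))
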