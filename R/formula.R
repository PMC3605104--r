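#' @keywords internal
ELEMENTS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "W", "Pt", "Au", "Hg", "Pb"
)

#' Parse a chemical formula in Hill notation
#'
#' Parses element/count tokens such as `"C6H12O6"` or `"C10H12N5O7P"`.
#' Generic or polymeric tokens (`R` groups written as `R`, `X`, `*`, or a
#' trailing `n` as in `(C6H10O5)n`) make the composition unknown: KEGG-style
#' generic formulas must not poison elemental balancing, so they parse to
#' `NULL` rather than to a wrong composition.
#'
#' @param formula a single formula string; `NA` or `""` mean no composition.
#' @return a named numeric vector of element counts, or `NULL` when the
#'   composition is unknown or unparseable.
#' @export
#' @examples
#' parse_formula("C6H12O6")
#' parse_formula("RC2H4")  # NULL: generic R group
parse_formula <- function(formula) {
  if (length(formula) != 1L) stop("parse_formula() takes a single string")
  if (is.na(formula) || !nzchar(trimws(formula))) return(NULL)
  f <- trimws(formula)
  # polymer notation or explicit generic markers => unknown composition
  if (grepl("[()*.]|\\bn\\b", f)) return(NULL)
  counts <- c(H = 0)[0]
  pos <- 1L
  n <- nchar(f)
  while (pos <= n) {
    rest <- substr(f, pos, n)
    m <- regmatches(rest, regexec("^([A-Z][a-z]?)([0-9]*\\.?[0-9]*)", rest))[[1]]
    if (length(m) == 0L || !nzchar(m[2])) return(NULL)
    elem <- m[2]
    if (!(elem %in% ELEMENTS)) return(NULL)
    cnt <- if (nzchar(m[3])) as.numeric(m[3]) else 1
    counts[elem] <- (if (elem %in% names(counts)) counts[[elem]] else 0) + cnt
    pos <- pos + nchar(m[1])
  }
  if (length(counts) == 0L) NULL else counts
}

#' Elemental balance of reactions
#'
#' Computes, per reaction, the signed elemental net balance: the sum over
#' participants of stoichiometric coefficient times the metabolite's parsed
#' formula. A reaction is `balanced` only if every element nets to zero
#' within `tol` *and* all participants have known composition; any
#' formula-less or unparseable participant gives `unknown_composition`.
#' Exchange reactions move mass across the system boundary and are flagged
#' `unbalanced_by_design`; QC summaries should exclude them.
#'
#' @param model a [gem_model].
#' @param rxn_ids reactions to check; default all.
#' @param tol per-element tolerance (floating coefficients in lipid
#'   pseudo-reactions make exact zero unrealistic).
#' @return a data.frame with columns `reaction_id`, `status` and a
#'   list-column `balance` of named per-element nets.
#' @export
elemental_balance <- function(model, rxn_ids = NULL, tol = 1e-6) {
  stopifnot(inherits(model, "gem_model"))
  if (is.null(rxn_ids)) rxn_ids <- model$rxns$id
  missing <- setdiff(rxn_ids, model$rxns$id)
  if (length(missing)) stop("unknown reaction id(s): ", paste(missing, collapse = ", "))
  forms <- lapply(model$mets$formula, parse_formula)
  names(forms) <- model$mets$id
  exch <- is_exchange(model)
  out <- vector("list", length(rxn_ids))
  status <- character(length(rxn_ids))
  for (i in seq_along(rxn_ids)) {
    rid <- rxn_ids[i]
    col <- model$S[, rid]
    idx <- which(col != 0)
    mets <- rownames(model$S)[idx]
    if (exch[[rid]]) {
      status[i] <- "unbalanced_by_design"
      out[[i]] <- numeric(0)
      next
    }
    fs <- forms[mets]
    if (any(vapply(fs, is.null, logical(1)))) {
      status[i] <- "unknown_composition"
      out[[i]] <- numeric(0)
      next
    }
    elems <- unique(unlist(lapply(fs, names)))
    bal <- stats::setNames(numeric(length(elems)), elems)
    for (j in seq_along(idx)) {
      fj <- fs[[j]]
      bal[names(fj)] <- bal[names(fj)] + col[idx[j]] * fj
    }
    status[i] <- if (all(abs(bal) <= tol)) "balanced" else "unbalanced"
    out[[i]] <- bal
  }
  res <- data.frame(reaction_id = rxn_ids, status = status, stringsAsFactors = FALSE)
  res$balance <- out
  res
}
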