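# The central container: a genome-scale metabolic model (GEM).
#
# A gem_model is a list with
#   id            model id
#   compartments  named character, compartment id -> display name
#   mets          data.frame: id (instance id "glc[c]"), base_id, name,
#                 compartment, formula, charge
#   rxns          data.frame: id, name, lb, ub, subsystem, ec, evidence
#   S             sparse stoichiometric matrix (mets x rxns, dimnames set);
#                 negative coefficient = substrate, positive = product
#   gpr           named list (per reaction) of DNF gene associations
#   genes         character vector of all gene ids
#   objective     named numeric, reaction id -> weight
#   biomass_composition  optional named numeric (component -> g/gDW)
#
# Reversibility is encoded solely through bounds: a reaction is reversible
# iff lb < 0. The positive flux direction is left-to-right as written.

met_instance_id <- function(base_id, compartment) paste0(base_id, "[", compartment, "]")

#' Create an empty metabolic model
#'
#' @param id model identifier.
#' @param compartments named character vector, compartment id -> name;
#'   unnamed vectors use the ids as names.
#' @return an object of class `gem_model`.
#' @export
gem_model <- function(id = "model", compartments = c(c = "cytosol")) {
  if (is.null(names(compartments))) names(compartments) <- compartments
  m <- list(
    id = id,
    compartments = compartments,
    mets = data.frame(id = character(), base_id = character(), name = character(),
                      compartment = character(), formula = character(),
                      charge = integer(), stringsAsFactors = FALSE),
    rxns = data.frame(id = character(), name = character(), lb = numeric(),
                      ub = numeric(), subsystem = character(), ec = character(),
                      evidence = character(), exchange = logical(),
                      stringsAsFactors = FALSE),
    S = Matrix::Matrix(0, 0, 0, sparse = TRUE, dimnames = list(NULL, NULL)),
    gpr = stats::setNames(list(), character()),
    genes = character(),
    objective = stats::setNames(numeric(), character()),
    biomass_composition = NULL
  )
  class(m) <- "gem_model"
  m
}

n_mets <- function(model) nrow(model$mets)
n_rxns <- function(model) nrow(model$rxns)

#' Add a metabolite to a model
#'
#' @param model a [gem_model].
#' @param base_id species id without compartment suffix.
#' @param compartment compartment id (must exist in the model).
#' @param name display name.
#' @param formula Hill-notation formula string ("" = composition unknown).
#' @param charge integer charge or NA.
#' @return the modified model.
#' @export
add_metabolite <- function(model, base_id, compartment, name = base_id,
                           formula = "", charge = NA_integer_) {
  stopifnot(inherits(model, "gem_model"))
  if (!compartment %in% names(model$compartments)) {
    stop("unknown compartment ", sQuote(compartment))
  }
  iid <- met_instance_id(base_id, compartment)
  if (iid %in% model$mets$id) stop("duplicate metabolite id ", sQuote(iid))
  model$mets <- rbind(model$mets, data.frame(
    id = iid, base_id = base_id, name = name, compartment = compartment,
    formula = formula, charge = as.integer(charge), stringsAsFactors = FALSE))
  model$S <- rbind(model$S, Matrix::Matrix(0, 1, ncol(model$S), sparse = TRUE))
  rownames(model$S) <- model$mets$id
  model
}

#' Add a reaction to a model
#'
#' The reaction can be given either as an equation string
#' (`"2 A[c] + B[c] => C[m]"`, arrows `=>` irreversible / `<=>` reversible,
#' metabolite tokens carrying a `[compartment]` suffix) or as a named
#' stoichiometry vector over metabolite instance ids (negative = substrate).
#'
#' @param model a [gem_model].
#' @param id unique reaction id.
#' @param equation equation string (alternative to `stoich`).
#' @param stoich named numeric stoichiometry (alternative to `equation`).
#' @param lb,ub flux bounds; defaults follow the arrow (`<=>` gives lb -1000).
#' @param gpr gene association rule string or DNF list.
#' @param name,subsystem,ec,evidence annotation fields.
#' @param add_mets if TRUE (default) metabolites referenced but absent are
#'   created with unknown composition; if FALSE such references are an error.
#' @param exchange is this an exchange (boundary) reaction? Default NULL
#'   auto-detects: a single metabolite appearing on one side only. The flag
#'   is explicit because net stoichiometry cannot distinguish an exchange
#'   from a mass-creating internal reaction like `B => 2 B`.
#' @return the modified model.
#' @export
add_reaction <- function(model, id, equation = NULL, stoich = NULL,
                         lb = NULL, ub = NULL, gpr = "", name = id,
                         subsystem = "", ec = "", evidence = "literature",
                         add_mets = TRUE, exchange = NULL) {
  stopifnot(inherits(model, "gem_model"))
  if (id %in% model$rxns$id) stop("duplicate reaction id ", sQuote(id))
  if (is.null(stoich)) {
    if (is.null(equation)) stop("need either equation or stoich")
    pe <- parse_equation(equation)
    stoich <- pe$stoich
    if (is.null(lb)) lb <- if (pe$reversible) -1000 else 0
    if (is.null(exchange)) {
      mets_all <- union(pe$lhs, pe$rhs)
      exchange <- length(mets_all) == 1L &&
        !(mets_all %in% pe$lhs && mets_all %in% pe$rhs)
    }
  }
  if (is.null(exchange)) exchange <- length(stoich) == 1L
  if (length(stoich) == 0L) stop("reaction ", sQuote(id), " has empty stoichiometry")
  if (is.null(lb)) lb <- 0
  if (is.null(ub)) ub <- 1000
  if (lb > ub) stop("reaction ", sQuote(id), ": lower bound exceeds upper bound")
  unknown <- setdiff(names(stoich), model$mets$id)
  if (length(unknown)) {
    if (!add_mets) {
      stop("reaction ", sQuote(id), " references unknown metabolite(s): ",
           paste(unknown, collapse = ", "))
    }
    for (iid in unknown) {
      p <- parse_met_instance(iid)
      if (!p$compartment %in% names(model$compartments)) {
        stop("reaction ", sQuote(id), ": unknown compartment in ", sQuote(iid))
      }
      model <- add_metabolite(model, p$base_id, p$compartment)
    }
  }
  assoc <- if (is.character(gpr)) parse_gpr(gpr) else gpr
  model$rxns <- rbind(model$rxns, data.frame(
    id = id, name = name, lb = lb, ub = ub, subsystem = subsystem, ec = ec,
    evidence = evidence, exchange = exchange, stringsAsFactors = FALSE))
  col <- Matrix::Matrix(0, nrow(model$S), 1, sparse = TRUE)
  col[match(names(stoich), model$mets$id), 1] <- unname(stoich)
  model$S <- cbind(model$S, col)
  dimnames(model$S) <- list(model$mets$id, model$rxns$id)
  model$gpr[[id]] <- assoc
  model$genes <- sort(union(model$genes, gpr_genes(assoc)))
  model
}

parse_met_instance <- function(iid) {
  m <- regmatches(iid, regexec("^(.*)\\[([^][]+)\\]$", iid))[[1]]
  if (length(m) == 0L) stop("metabolite id ", sQuote(iid), " lacks a [compartment] suffix")
  list(base_id = m[2], compartment = m[3])
}

#' Parse a reaction equation string
#'
#' @param equation e.g. `"2 A[c] + B[c] <=> C[m]"`.
#' @return list with `stoich` (named numeric) and `reversible` (logical).
#' @export
parse_equation <- function(equation) {
  arrow <- if (grepl("<=>", equation, fixed = TRUE)) "<=>"
           else if (grepl("=>", equation, fixed = TRUE)) "=>"
           else stop("equation parse error: no '=>' or '<=>' arrow in ", sQuote(equation))
  sides <- strsplit(equation, arrow, fixed = TRUE)[[1]]
  if (length(sides) == 1L) sides <- c(sides, "")
  parse_side <- function(s, sign) {
    s <- trimws(s)
    if (!nzchar(s)) return(stats::setNames(numeric(), character()))
    terms <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
    out <- numeric(length(terms))
    ids <- character(length(terms))
    for (i in seq_along(terms)) {
      m <- regmatches(terms[i], regexec("^([0-9]*\\.?[0-9]+(?:[eE][+-]?[0-9]+)?\\s+)?(\\S.*)$", terms[i]))[[1]]
      if (length(m) == 0L) stop("equation parse error in term ", sQuote(terms[i]))
      out[i] <- if (nzchar(trimws(m[2]))) as.numeric(trimws(m[2])) else 1
      ids[i] <- trimws(m[3])
    }
    stats::setNames(sign * out, ids)
  }
  lhs <- parse_side(sides[1], -1)
  rhs <- parse_side(sides[2], 1)
  st <- c(lhs, rhs)
  # merge duplicated instances (metabolite on both sides)
  st <- tapply(st, names(st), sum)
  st <- st[st != 0]
  list(stoich = stats::setNames(as.numeric(st), names(st)),
       reversible = arrow == "<=>",
       lhs = names(lhs), rhs = names(rhs))
}

#' Format a reaction as an equation string
#' @param model a [gem_model]; @param rxn_id reaction id.
#' @return equation string using `=>` or `<=>` per the bounds.
#' @export
format_equation <- function(model, rxn_id) {
  col <- model$S[, rxn_id]
  subs <- which(col < 0); prods <- which(col > 0)
  fmt <- function(idx) {
    paste(vapply(idx, function(i) {
      cf <- abs(col[i])
      if (cf == 1) rownames(model$S)[i] else paste(format(cf, scientific = FALSE), rownames(model$S)[i])
    }, character(1)), collapse = " + ")
  }
  arrow <- if (model$rxns$lb[match(rxn_id, model$rxns$id)] < 0) "<=>" else "=>"
  paste(fmt(subs), arrow, fmt(prods))
}

#' Identify exchange reactions
#'
#' An exchange reaction moves a single metabolite across the system
#' boundary. Positive flux is excretion, negative flux is uptake. The flag
#' is an explicit reaction attribute (set at creation, carried through
#' I/O): the *net* stoichiometric column cannot distinguish an exchange
#' from a mass-creating internal reaction such as `B => 2 B`, whose column
#' also touches a single metabolite.
#'
#' @param model a [gem_model].
#' @return named logical vector over reaction ids.
#' @export
is_exchange <- function(model) {
  stats::setNames(model$rxns$exchange, model$rxns$id)
}

#' Set flux bounds
#' @param model a [gem_model]; @param rxn_ids reaction ids;
#' @param lb,ub new bounds (recycled); NULL leaves a side unchanged.
#' @export
set_bounds <- function(model, rxn_ids, lb = NULL, ub = NULL) {
  idx <- match(rxn_ids, model$rxns$id)
  if (anyNA(idx)) stop("unknown reaction id(s): ", paste(rxn_ids[is.na(idx)], collapse = ", "))
  if (!is.null(lb)) model$rxns$lb[idx] <- rep_len(lb, length(idx))
  if (!is.null(ub)) model$rxns$ub[idx] <- rep_len(ub, length(idx))
  if (any(model$rxns$lb[idx] > model$rxns$ub[idx])) stop("lower bound exceeds upper bound")
  model
}

#' Set the objective
#' @param model a [gem_model]; @param objective named numeric (rxn id -> weight).
#' @export
set_objective <- function(model, objective) {
  bad <- setdiff(names(objective), model$rxns$id)
  if (length(bad)) stop("unknown reaction id(s): ", paste(bad, collapse = ", "))
  model$objective <- objective
  model
}

#' Remove reactions (and optionally now-orphaned metabolites)
#' @param model a [gem_model]; @param rxn_ids ids to drop;
#' @param drop_orphan_mets drop metabolites left unused.
#' @export
remove_reactions <- function(model, rxn_ids, drop_orphan_mets = FALSE) {
  idx <- match(rxn_ids, model$rxns$id)
  if (anyNA(idx)) stop("unknown reaction id(s): ", paste(rxn_ids[is.na(idx)], collapse = ", "))
  if (length(idx) == 0L) return(model)
  keep <- setdiff(seq_len(n_rxns(model)), idx)
  model$S <- model$S[, keep, drop = FALSE]
  model$rxns <- model$rxns[keep, , drop = FALSE]
  rownames(model$rxns) <- NULL
  model$gpr <- model$gpr[model$rxns$id]
  model$objective <- model$objective[intersect(names(model$objective), model$rxns$id)]
  if (drop_orphan_mets) {
    used <- Matrix::rowSums(model$S != 0) > 0
    model$S <- model$S[used, , drop = FALSE]
    model$mets <- model$mets[used, , drop = FALSE]
    rownames(model$mets) <- NULL
  }
  model
}

#' Remove metabolites
#' @param model a [gem_model]; @param met_ids instance ids to drop;
#' @param cascade also remove reactions referencing them (error otherwise).
#' @export
remove_metabolites <- function(model, met_ids, cascade = FALSE) {
  idx <- match(met_ids, model$mets$id)
  if (anyNA(idx)) stop("unknown metabolite id(s): ", paste(met_ids[is.na(idx)], collapse = ", "))
  touching <- model$rxns$id[Matrix::colSums(model$S[idx, , drop = FALSE] != 0) > 0]
  if (length(touching)) {
    if (!cascade) {
      stop("metabolite(s) still referenced by ", paste(touching, collapse = ", "),
           "; use cascade = TRUE to remove those reactions too")
    }
    model <- remove_reactions(model, touching)
    idx <- match(met_ids, model$mets$id)
  }
  keep <- setdiff(seq_len(n_mets(model)), idx)
  model$S <- model$S[keep, , drop = FALSE]
  model$mets <- model$mets[keep, , drop = FALSE]
  rownames(model$mets) <- NULL
  model
}

#' Merge compartments
#'
#' Collapses the metabolite instances of several compartments onto one:
#' instances sharing a base id become a single row of S, and transport
#' reactions that thereby become identities (all-zero columns) are deleted.
#'
#' @param model a [gem_model]; @param comps compartment ids to merge;
#' @param into the surviving compartment id (default first of `comps`).
#' @export
merge_compartments <- function(model, comps, into = comps[1]) {
  stopifnot(all(comps %in% names(model$compartments)), into %in% comps)
  relabel <- model$mets$compartment %in% comps
  new_ids <- ifelse(relabel, met_instance_id(model$mets$base_id, into), model$mets$id)
  groups <- split(seq_len(n_mets(model)), new_ids)
  keep_rows <- vapply(groups, `[`, integer(1), 1L)
  Snew <- model$S[keep_rows, , drop = FALSE]
  for (g in groups) {
    if (length(g) > 1L) {
      Snew[match(g[1], keep_rows), ] <- Matrix::colSums(model$S[g, , drop = FALSE])
    }
  }
  mets <- model$mets[keep_rows, , drop = FALSE]
  sel <- mets$compartment %in% comps
  mets$compartment[sel] <- into
  mets$id <- ifelse(sel, met_instance_id(mets$base_id, into), mets$id)
  rownames(mets) <- NULL
  model$mets <- mets
  rownames(Snew) <- mets$id
  model$S <- Snew
  model$compartments <- model$compartments[!(names(model$compartments) %in% setdiff(comps, into))]
  identity_cols <- model$rxns$id[Matrix::colSums(model$S != 0) == 0]
  if (length(identity_cols)) model <- remove_reactions(model, identity_cols)
  model
}

#' Apply a list of edit operations
#'
#' Thin dispatcher over the individual editing functions, for scripted
#' model curation: each op is `list(op = "add_reaction" | "remove_reactions" |
#' "remove_metabolites" | "set_bounds" | "set_objective" |
#' "merge_compartments", ...args)`.
#'
#' @param model a [gem_model]; @param ops list of operation specs.
#' @export
edit_model <- function(model, ops) {
  for (o in ops) {
    fn <- switch(o$op,
      add_reaction = add_reaction, remove_reactions = remove_reactions,
      remove_metabolites = remove_metabolites, set_bounds = set_bounds,
      set_objective = set_objective, merge_compartments = merge_compartments,
      stop("unknown edit op ", sQuote(o$op)))
    o$op <- NULL
    model <- do.call(fn, c(list(model), o))
  }
  model
}

#' Validate model invariants
#'
#' Checks id uniqueness, bound ordering, non-empty stoichiometries,
#' gene-list consistency and S dimensions; stops on the first violation.
#' @param model a [gem_model].
#' @return the model, invisibly.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "gem_model"))
  if (anyDuplicated(model$mets$id)) stop("duplicate metabolite ids")
  if (anyDuplicated(model$rxns$id)) stop("duplicate reaction ids")
  if (any(model$rxns$lb > model$rxns$ub)) stop("lower bound exceeds upper bound")
  if (nrow(model$S) != n_mets(model) || ncol(model$S) != n_rxns(model)) {
    stop("S dimensions disagree with metabolite/reaction tables")
  }
  if (n_rxns(model) > 0 && any(Matrix::colSums(model$S != 0) == 0)) {
    stop("reaction with empty stoichiometry")
  }
  gpr_all <- gpr_genes(unlist(model$gpr, recursive = FALSE))
  if (!all(gpr_all %in% model$genes)) stop("gene association references a gene absent from genes")
  if (!all(model$mets$compartment %in% names(model$compartments))) {
    stop("metabolite in unknown compartment")
  }
  invisible(model)
}

#' @export
print.gem_model <- function(x, ...) {
  cat("Genome-scale metabolic model", sQuote(x$id), "\n")
  cat(sprintf("  %d metabolites x %d reactions (%d exchange), %d genes, %d compartments\n",
              n_mets(x), n_rxns(x), sum(is_exchange(x)), length(x$genes),
              length(x$compartments)))
  if (length(x$objective)) {
    cat("  objective:", paste(sprintf("%s (%g)", names(x$objective), x$objective),
                              collapse = ", "), "\n")
  }
  invisible(x)
}
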