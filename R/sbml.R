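# SBML reading and writing.
#
# Writer emits SBML Level 3 Version 1 with the fbc (version 2) package:
# bounds as global parameters, gene associations as fbc:geneProductAssociation
# trees, the objective as fbc:listOfObjectives. Reader accepts that dialect
# and, for legacy models, SBML Level 2 with bounds in kinetic-law parameters
# (LOWER_BOUND/UPPER_BOUND) and GPRs in "GENE_ASSOCIATION:" notes lines.
# Species flagged boundaryCondition="true" are excluded from S, which turns
# the reactions touching them into exchange reactions.
#
# SBML SIds cannot carry the "[c]" instance suffix, so ids are sanitized
# ("M_A_c", "R_R1", "G_g1") while the original id is kept in the name
# attribute and restored on read.

sanitize_sid <- function(x) gsub("[^A-Za-z0-9_]", "_", x)

sbml_ns <- c(
  sbml = "http://www.sbml.org/sbml/level3/version1/core",
  fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2"
)

#' Write a model as SBML Level 3 + fbc
#'
#' @param model a [gem_model].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(model, path) {
  stopifnot(inherits(model, "gem_model"))
  validate_model(model)
  doc <- xml2::xml_new_root(
    "sbml",
    xmlns = sbml_ns[["sbml"]], "xmlns:fbc" = sbml_ns[["fbc"]],
    level = "3", version = "1", "fbc:required" = "false")
  mdl <- xml2::xml_add_child(doc, "model", id = sanitize_sid(model$id),
                             name = model$id, "fbc:strict" = "false")
  cl <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (i in seq_along(model$compartments)) {
    xml2::xml_add_child(cl, "compartment", id = names(model$compartments)[i],
                        name = unname(model$compartments[i]), constant = "true")
  }
  sl <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(n_mets(model))) {
    sp <- xml2::xml_add_child(
      sl, "species", id = sanitize_sid(paste0("M_", model$mets$id[i])),
      name = model$mets$id[i], compartment = model$mets$compartment[i],
      hasOnlySubstanceUnits = "false", boundaryCondition = "false",
      constant = "false")
    if (nzchar(model$mets$formula[i]) && !is.na(model$mets$formula[i])) {
      xml2::xml_set_attr(sp, "fbc:chemicalFormula", model$mets$formula[i])
    }
    if (!is.na(model$mets$charge[i])) {
      xml2::xml_set_attr(sp, "fbc:charge", as.character(model$mets$charge[i]))
    }
  }
  pl <- xml2::xml_add_child(mdl, "listOfParameters")
  for (i in seq_len(n_rxns(model))) {
    rid <- sanitize_sid(paste0("R_", model$rxns$id[i]))
    xml2::xml_add_child(pl, "parameter", id = paste0(rid, "_lb"),
                        value = format(model$rxns$lb[i], scientific = FALSE, digits = 15),
                        constant = "true")
    xml2::xml_add_child(pl, "parameter", id = paste0(rid, "_ub"),
                        value = format(model$rxns$ub[i], scientific = FALSE, digits = 15),
                        constant = "true")
  }
  add_assoc <- function(parent, assoc) {
    node <- if (length(assoc) > 1L) xml2::xml_add_child(parent, "fbc:or") else parent
    for (cx in assoc) {
      inner <- if (length(cx) > 1L) xml2::xml_add_child(node, "fbc:and") else node
      for (g in cx) {
        xml2::xml_add_child(inner, "fbc:geneProductRef",
                            "fbc:geneProduct" = sanitize_sid(paste0("G_", g)))
      }
    }
  }
  rl <- xml2::xml_add_child(mdl, "listOfReactions")
  for (i in seq_len(n_rxns(model))) {
    id <- model$rxns$id[i]
    rid <- sanitize_sid(paste0("R_", id))
    rx <- xml2::xml_add_child(
      rl, "reaction", id = rid, name = id,
      reversible = if (model$rxns$lb[i] < 0) "true" else "false",
      fast = "false",
      "fbc:lowerFluxBound" = paste0(rid, "_lb"),
      "fbc:upperFluxBound" = paste0(rid, "_ub"))
    # SBO marks exchange vs biochemical reaction explicitly; the net
    # stoichiometry alone cannot (e.g. "B => 2 B" nets to one species)
    xml2::xml_set_attr(rx, "sboTerm",
                       if (model$rxns$exchange[i]) "SBO:0000627" else "SBO:0000176")
    col <- model$S[, id]
    subs <- which(col < 0); prods <- which(col > 0)
    if (length(subs)) {
      lr <- xml2::xml_add_child(rx, "listOfReactants")
      for (j in subs) {
        xml2::xml_add_child(lr, "speciesReference",
                            species = sanitize_sid(paste0("M_", model$mets$id[j])),
                            stoichiometry = format(-col[j], scientific = FALSE, digits = 15),
                            constant = "true")
      }
    }
    if (length(prods)) {
      lp <- xml2::xml_add_child(rx, "listOfProducts")
      for (j in prods) {
        xml2::xml_add_child(lp, "speciesReference",
                            species = sanitize_sid(paste0("M_", model$mets$id[j])),
                            stoichiometry = format(col[j], scientific = FALSE, digits = 15),
                            constant = "true")
      }
    }
    if (length(model$gpr[[id]])) {
      ga <- xml2::xml_add_child(rx, "fbc:geneProductAssociation")
      add_assoc(ga, model$gpr[[id]])
    }
  }
  if (length(model$objective)) {
    lo <- xml2::xml_add_child(mdl, "fbc:listOfObjectives", "fbc:activeObjective" = "obj")
    ob <- xml2::xml_add_child(lo, "fbc:objective", "fbc:id" = "obj", "fbc:type" = "maximize")
    lf <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
    for (j in seq_along(model$objective)) {
      xml2::xml_add_child(lf, "fbc:fluxObjective",
                          "fbc:reaction" = sanitize_sid(paste0("R_", names(model$objective)[j])),
                          "fbc:coefficient" = format(model$objective[j], scientific = FALSE))
    }
  }
  if (length(model$genes)) {
    lg <- xml2::xml_add_child(mdl, "fbc:listOfGeneProducts")
    for (g in model$genes) {
      xml2::xml_add_child(lg, "fbc:geneProduct",
                          "fbc:id" = sanitize_sid(paste0("G_", g)), "fbc:label" = g)
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

attr_any <- function(attrs, keys) {
  for (k in keys) if (k %in% names(attrs)) return(attrs[[k]])
  NA_character_
}

#' Read an SBML model
#'
#' Accepts the package's own Level 3 + fbc dialect and legacy Level 2
#' files (kinetic-law LOWER_BOUND/UPPER_BOUND parameters, GPRs in
#' "GENE_ASSOCIATION:" notes). Boundary-condition species are dropped from
#' the stoichiometric matrix.
#'
#' @param path SBML file.
#' @return a [gem_model].
#' @export
read_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse error in ", path, ": ",
                                           conditionMessage(e)))
  find <- function(node, what) xml2::xml_find_all(node, paste0(".//*[local-name()='", what, "']"))
  mnode <- find(doc, "model")[[1]]
  mattrs <- xml2::xml_attrs(mnode)
  model_id <- if (!is.na(attr_any(mattrs, "name"))) attr_any(mattrs, "name") else attr_any(mattrs, "id")
  comps <- find(doc, "compartment")
  cids <- xml2::xml_attr(comps, "id")
  cnames <- xml2::xml_attr(comps, "name")
  cnames[is.na(cnames)] <- cids[is.na(cnames)]
  if (anyDuplicated(cids)) stop("SBML validation error: duplicate compartment ids")
  model <- gem_model(model_id, stats::setNames(cnames, cids))
  # parameters (L3 bounds)
  pars <- find(doc, "parameter")
  parmap <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                            xml2::xml_attr(pars, "id"))
  # species
  sp <- find(doc, "species")
  sp_ids <- xml2::xml_attr(sp, "id")
  if (anyDuplicated(sp_ids)) stop("SBML validation error: duplicate species ids")
  boundary <- xml2::xml_attr(sp, "boundaryCondition") %in% "true"
  sid2instance <- character(0)
  for (i in seq_along(sp)) {
    if (boundary[i]) next
    a <- xml2::xml_attrs(sp[[i]])
    comp <- a[["compartment"]]
    nm <- attr_any(a, "name")
    inst <- if (!is.na(nm) && grepl("\\[[^][]+\\]$", nm)) nm else {
      met_instance_id(sub("^M_", "", a[["id"]]), comp)
    }
    p <- parse_met_instance(inst)
    formula <- attr_any(a, c("fbc:chemicalFormula", "chemicalFormula"))
    charge <- attr_any(a, c("fbc:charge", "charge"))
    model <- add_metabolite(model, p$base_id, p$compartment,
                            name = if (is.na(nm)) p$base_id else nm,
                            formula = if (is.na(formula)) "" else formula,
                            charge = if (is.na(charge)) NA_integer_ else as.integer(charge))
    sid2instance[a[["id"]]] <- model$mets$id[n_mets(model)]
  }
  # gene products (L3)
  gps <- find(doc, "geneProduct")
  gid2label <- stats::setNames(
    ifelse(is.na(xml2::xml_attr(gps, "label")),
           sub("^G_", "", xml2::xml_attr(gps, "id")),
           xml2::xml_attr(gps, "label")),
    xml2::xml_attr(gps, "id"))
  parse_assoc_node <- function(node) {
    nm <- xml2::xml_name(node)
    kids <- xml2::xml_children(node)
    if (nm == "geneProductRef") {
      ref <- attr_any(xml2::xml_attrs(node), c("fbc:geneProduct", "geneProduct"))
      lbl <- if (ref %in% names(gid2label)) gid2label[[ref]] else sub("^G_", "", ref)
      return(list(c(lbl)))
    }
    if (nm == "and") {
      parts <- lapply(kids, parse_assoc_node)
      out <- list(character(0))
      for (p in parts) {
        out <- unlist(lapply(out, function(a) lapply(p, function(b) union(a, b))),
                      recursive = FALSE)
      }
      return(out)
    }
    # "or" or wrapper
    do.call(c, lapply(kids, parse_assoc_node))
  }
  rxns <- find(doc, "reaction")
  rseen <- character()
  for (rn in rxns) {
    a <- xml2::xml_attrs(rn)
    nm <- attr_any(a, "name")
    rid <- if (!is.na(nm) && nzchar(nm)) nm else sub("^R_", "", a[["id"]])
    if (rid %in% rseen) stop("SBML validation error: duplicate reaction id ", sQuote(rid))
    rseen <- c(rseen, rid)
    st <- numeric(0)
    side_mets <- list(reactants = character(), products = character())
    touches_boundary <- FALSE
    for (side in c("listOfReactants", "listOfProducts")) {
      sgn <- if (side == "listOfReactants") -1 else 1
      refs <- xml2::xml_find_all(rn, paste0("./*[local-name()='", side,
                                            "']/*[local-name()='speciesReference']"))
      for (ref in refs) {
        ra <- xml2::xml_attrs(ref)
        sidr <- ra[["species"]]
        if (!sidr %in% names(sid2instance)) {  # boundary species: skip
          touches_boundary <- TRUE
          next
        }
        coef <- if ("stoichiometry" %in% names(ra)) as.numeric(ra[["stoichiometry"]]) else 1
        inst <- sid2instance[[sidr]]
        st[inst] <- (if (inst %in% names(st)) st[[inst]] else 0) + sgn * coef
        key <- if (sgn < 0) "reactants" else "products"
        side_mets[[key]] <- c(side_mets[[key]], inst)
      }
    }
    st <- st[st != 0]
    if (length(st) == 0L) next  # pure boundary reaction
    sbo <- attr_any(a, "sboTerm")
    exch <- if (!is.na(sbo)) identical(sbo, "SBO:0000627") else {
      touches_boundary ||
        (length(union(side_mets$reactants, side_mets$products)) == 1L &&
         !(length(side_mets$reactants) && length(side_mets$products)))
    }
    # bounds: fbc attributes, else kinetic-law parameters, else reversible flag
    lbp <- attr_any(a, c("fbc:lowerFluxBound", "lowerFluxBound"))
    ubp <- attr_any(a, c("fbc:upperFluxBound", "upperFluxBound"))
    lb <- if (!is.na(lbp) && lbp %in% names(parmap)) parmap[[lbp]] else NA_real_
    ub <- if (!is.na(ubp) && ubp %in% names(parmap)) parmap[[ubp]] else NA_real_
    if (is.na(lb) || is.na(ub)) {
      klp <- xml2::xml_find_all(rn, ".//*[local-name()='kineticLaw']//*[local-name()='parameter']")
      if (length(klp)) {
        kid <- xml2::xml_attr(klp, "id")
        kval <- as.numeric(xml2::xml_attr(klp, "value"))
        if (is.na(lb) && "LOWER_BOUND" %in% kid) lb <- kval[match("LOWER_BOUND", kid)]
        if (is.na(ub) && "UPPER_BOUND" %in% kid) ub <- kval[match("UPPER_BOUND", kid)]
      }
    }
    rev <- identical(attr_any(a, "reversible"), "true")
    if (is.na(lb)) lb <- if (rev) -1000 else 0
    if (is.na(ub)) ub <- 1000
    # GPR: fbc association, else notes GENE_ASSOCIATION line
    assoc <- list()
    ga <- xml2::xml_find_first(rn, ".//*[local-name()='geneProductAssociation']")
    if (!inherits(ga, "xml_missing")) {
      assoc <- do.call(c, lapply(xml2::xml_children(ga), parse_assoc_node))
    } else {
      notes <- xml2::xml_find_all(rn, ".//*[local-name()='notes']//*")
      for (nnode in notes) {
        txt <- xml2::xml_text(nnode)
        if (grepl("GENE_ASSOCIATION", txt)) {
          rule <- trimws(sub(".*GENE_ASSOCIATION\\s*:\\s*", "", txt))
          if (nzchar(rule)) assoc <- parse_gpr(rule)
          break
        }
      }
    }
    model <- add_reaction(model, rid, stoich = st, lb = lb, ub = ub,
                          gpr = assoc, add_mets = FALSE, exchange = exch)
  }
  # objective
  fo <- find(doc, "fluxObjective")
  if (length(fo)) {
    refs <- vapply(fo, function(x) attr_any(xml2::xml_attrs(x),
                                            c("fbc:reaction", "reaction")), character(1))
    coefs <- vapply(fo, function(x) {
      v <- attr_any(xml2::xml_attrs(x), c("fbc:coefficient", "coefficient"))
      if (is.na(v)) 1 else as.numeric(v)
    }, numeric(1))
    # map sanitized ids back through reaction name lookup
    sids <- sanitize_sid(paste0("R_", model$rxns$id))
    idx <- match(refs, sids)
    ok <- !is.na(idx)
    if (any(ok)) {
      model <- set_objective(model, stats::setNames(coefs[ok], model$rxns$id[idx[ok]]))
    }
  }
  validate_model(model)
  model
}
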