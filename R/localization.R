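# Subcellular localization by simulated annealing.
#
# The problem: place each gene product (and the reactions it catalyzes) in
# a compartment so that (a) predictor scores are respected and (b) the
# network stays connected, where connectivity means every ordinary
# metabolite instance is produced by at least one reaction and consumed by
# at least one reaction in its compartment. Reversible reactions count both
# ways, and so do the passive-diffusion transport reactions the method adds
# to stitch compartments together. The objective traded off is
#   fitness = sum_g score(g, assigned(g)) - transport_cost * n_transports.

#' Annealing configuration
#'
#' @param transport_cost fitness cost per added transport reaction
#'   (default 0.1, the validated setting).
#' @param initial_temperature Metropolis temperature at step 1.
#' @param cooling_rate geometric cooling factor per step.
#' @param steps number of proposals; default `10 * n_genes`.
#' @param seed RNG seed (mandatory: annealing results are only meaningful
#'   with their seed).
#' @return list of class `anneal_config`.
#' @export
anneal_config <- function(transport_cost = 0.1, initial_temperature = 0.5,
                          cooling_rate = 0.99, steps = NULL, seed = 1) {
  stopifnot(transport_cost >= 0, cooling_rate > 0, cooling_rate < 1,
            is.null(steps) || steps > 0)
  structure(list(transport_cost = transport_cost,
                 initial_temperature = initial_temperature,
                 cooling_rate = cooling_rate, steps = steps, seed = seed),
            class = "anneal_config")
}

#' Parse localization-predictor output into normalized scores
#'
#' Two dialects are supported. `wolfpsort` summary lines look like
#' `"g1 mito 20, cyto 5"` (gene, then comma-separated label/value pairs,
#' `label: value` also accepted). `cello` is a delimited table with columns
#' gene, compartment, score. Labels are mapped onto model compartment ids
#' through `aliases`; an alias may name several compartments
#' (`c("cyto_mito" = "c,m")`), in which case the value is split evenly.
#' Scores are normalized per gene to sum to one; genes in `genes` missing
#' from the file get uniform scores.
#'
#' @param path predictor output file.
#' @param dialect "wolfpsort" or "cello".
#' @param compartments model compartment ids (column set of the result).
#' @param aliases named character mapping predictor labels to compartment
#'   ids (comma-separated for splits). Labels equal to a compartment id
#'   need no alias.
#' @param genes optional full gene set; absent genes get uniform scores.
#' @return numeric matrix genes x compartments, rows summing to 1.
#' @export
parse_predictor_output <- function(path, dialect = c("wolfpsort", "cello"),
                                   compartments, aliases = character(),
                                   genes = NULL) {
  dialect <- match.arg(dialect)
  resolve <- function(label) {
    if (label %in% compartments) return(label)
    if (label %in% names(aliases)) {
      tgt <- trimws(strsplit(aliases[[label]], ",")[[1]])
      bad <- setdiff(tgt, compartments)
      if (length(bad)) stop("alias for ", sQuote(label), " names unknown compartment(s): ",
                            paste(bad, collapse = ", "))
      return(tgt)
    }
    stop("unknown compartment label ", sQuote(label),
         " (no alias given); known: ", paste(compartments, collapse = ", "))
  }
  acc <- list()
  if (dialect == "wolfpsort") {
    for (line in readLines(path, warn = FALSE)) {
      line <- trimws(line)
      if (!nzchar(line) || startsWith(line, "#")) next
      toks <- strsplit(line, "\\s+", perl = TRUE)[[1]]
      gene <- toks[1]
      rest <- paste(toks[-1], collapse = " ")
      pairs <- trimws(strsplit(rest, ",", fixed = TRUE)[[1]])
      sc <- stats::setNames(numeric(length(compartments)), compartments)
      for (p in pairs[nzchar(pairs)]) {
        kv <- strsplit(gsub(":", " ", p), "\\s+")[[1]]
        kv <- kv[nzchar(kv)]
        tgt <- resolve(kv[1])
        sc[tgt] <- sc[tgt] + as.numeric(kv[2]) / length(tgt)
      }
      acc[[gene]] <- sc
    }
  } else {
    tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    names(tab) <- tolower(names(tab))
    for (i in seq_len(nrow(tab))) {
      gene <- as.character(tab$gene[i])
      if (is.null(acc[[gene]])) {
        acc[[gene]] <- stats::setNames(numeric(length(compartments)), compartments)
      }
      tgt <- resolve(as.character(tab$compartment[i]))
      acc[[gene]][tgt] <- acc[[gene]][tgt] + as.numeric(tab$score[i]) / length(tgt)
    }
  }
  all_genes <- union(names(acc), genes)
  sc <- matrix(1 / length(compartments), length(all_genes), length(compartments),
               dimnames = list(all_genes, compartments))
  for (g in names(acc)) {
    tot <- sum(acc[[g]])
    sc[g, ] <- if (tot > 0) acc[[g]] / tot else 1 / length(compartments)
  }
  sc
}

# ---- connectivity predicate & transport counting -------------------------

# Reaction ownership: a reaction follows the alphabetically first gene of
# its association; gene-less reactions stay in the default compartment.
reaction_owners <- function(model) {
  vapply(model$rxns$id, function(rid) {
    gs <- gpr_genes(model$gpr[[rid]])
    if (length(gs)) gs[1] else NA_character_
  }, character(1))
}

# Minimal passive transports needed for an assignment: every non-exempt
# metabolite instance must have a producer and a consumer in its
# compartment (reversible reactions and transports count as both). A
# transport connects two instances and fixes both, so a metabolite with k
# deficient instances needs ceiling(k/2) transports (k = 1: connect to any
# other compartment where the metabolite occurs, or to the default).
required_transports <- function(model, assignment, default, exempt_mets) {
  owners <- reaction_owners(model)
  rxn_comp <- ifelse(is.na(owners), default, assignment[owners])
  exch <- is_exchange(model)
  S <- model$S
  transports <- list()
  for (b in unique(model$mets$base_id)) {
    if (b %in% exempt_mets) next
    rows <- which(model$mets$base_id == b)
    touching <- which(Matrix::colSums(abs(S[rows, , drop = FALSE])) > 0)
    if (any(exch[touching])) next  # exchange metabolites are exempt
    coefs <- Matrix::colSums(S[rows, , drop = FALSE])  # one instance pre-split
    usage <- split(touching, rxn_comp[touching])
    deficient <- character()
    for (cp in names(usage)) {
      js <- usage[[cp]]
      cf <- coefs[js]
      rev <- model$rxns$lb[js] < 0
      produced <- any(cf > 0 | (rev & cf != 0))
      consumed <- any(cf < 0 | (rev & cf != 0))
      if (!produced || !consumed) deficient <- c(deficient, cp)
    }
    if (length(deficient) == 0L) next
    comps_here <- sort(names(usage))
    deficient <- sort(deficient)
    while (length(deficient) >= 2L) {
      transports[[length(transports) + 1L]] <-
        list(met = b, from = deficient[1], to = deficient[2])
      deficient <- deficient[-(1:2)]
    }
    if (length(deficient) == 1L) {
      other <- setdiff(comps_here, deficient)
      to <- if (length(other)) other[1] else default
      if (identical(to, deficient[1])) to <- default
      transports[[length(transports) + 1L]] <-
        list(met = b, from = deficient[1], to = to)
    }
  }
  transports
}

localization_fitness <- function(scores, assignment, n_transports, transport_cost) {
  sum(scores[cbind(names(assignment), assignment)]) - transport_cost * n_transports
}

#' Assign gene products to compartments by simulated annealing
#'
#' Starting from everything in the default compartment, proposes moving one
#' gene product (picked with probability proportional to how poorly it is
#' placed) together with its reactions to another compartment (picked
#' proportionally to its predictor score there), re-derives the minimal
#' passive-transport set that keeps the network connected, and accepts by
#' the Metropolis criterion on the fitness change under geometric cooling.
#' The best state ever visited is returned.
#'
#' @param model single-compartment [gem_model] (pre-compartmentalization).
#' @param scores matrix genes x compartments from
#'   [parse_predictor_output()] or [fix4_localization_scores()].
#' @param compartments compartment ids to distribute over (>= 2); the
#'   first is the default, cytosol-like one.
#' @param config an [anneal_config()].
#' @param exempt_mets metabolite base ids exempt from the
#'   produced-and-consumed predicate (designated cofactors); exchange
#'   metabolites are always exempt.
#' @return object of class `localization_solution`: `assignment` (named
#'   character), `transports` (data.frame met/from/to), `fitness`, `seed`,
#'   `model` (re-compartmentalized, transports included).
#' @export
predict_localization <- function(model, scores, compartments,
                                 config = anneal_config(),
                                 exempt_mets = character()) {
  stopifnot(length(model$compartments) == 1L, length(compartments) >= 2L)
  genes <- model$genes
  missing <- setdiff(genes, rownames(scores))
  if (length(missing)) {
    add <- matrix(1 / length(compartments), length(missing), length(compartments),
                  dimnames = list(missing, compartments))
    scores <- rbind(scores[, compartments, drop = FALSE], add)
  }
  scores <- scores[genes, compartments, drop = FALSE]
  default <- compartments[1]
  isolated <- model$mets$id[Matrix::rowSums(model$S != 0) == 0]
  if (length(isolated)) {
    stop("isolated metabolite(s) can never satisfy connectivity: ",
         paste(isolated, collapse = ", "))
  }
  steps <- if (is.null(config$steps)) 10L * max(length(genes), 1L) else config$steps
  set.seed(config$seed)
  state <- stats::setNames(rep(default, length(genes)), genes)
  eval_state <- function(a) {
    tr <- required_transports(model, a, default, exempt_mets)
    list(transports = tr,
         fitness = localization_fitness(scores, a, length(tr), config$transport_cost))
  }
  cur <- eval_state(state)
  best <- list(assignment = state, eval = cur)
  temp <- config$initial_temperature
  if (length(genes)) {
    for (step in seq_len(steps)) {
      w <- 1 - scores[cbind(genes, state[genes])] + 1e-6
      g <- sample(genes, 1, prob = w)
      others <- setdiff(compartments, state[[g]])
      tgt <- if (length(others) == 1L) others else {
        sample(others, 1, prob = scores[g, others] + 1e-6)
      }
      prop <- state
      prop[[g]] <- tgt
      pe <- eval_state(prop)
      accept <- pe$fitness >= cur$fitness ||
        stats::runif(1) < exp((pe$fitness - cur$fitness) / temp)
      if (accept) {
        state <- prop
        cur <- pe
        if (cur$fitness > best$eval$fitness + 1e-12) {
          best <- list(assignment = state, eval = cur)
        }
      }
      temp <- temp * config$cooling_rate
    }
  }
  tr <- best$eval$transports
  tr_df <- if (length(tr)) {
    data.frame(met = vapply(tr, `[[`, character(1), "met"),
               from = vapply(tr, `[[`, character(1), "from"),
               to = vapply(tr, `[[`, character(1), "to"),
               stringsAsFactors = FALSE)
  } else data.frame(met = character(), from = character(), to = character(),
                    stringsAsFactors = FALSE)
  out_model <- compartmentalize(model, best$assignment, compartments, default, tr_df)
  structure(list(assignment = best$assignment, transports = tr_df,
                 fitness = best$eval$fitness, seed = config$seed,
                 model = out_model),
            class = "localization_solution")
}

#' @export
print.localization_solution <- function(x, ...) {
  cat("Localization solution (fitness ", format(x$fitness), ", seed ", x$seed, ")\n", sep = "")
  tab <- table(x$assignment)
  cat("  ", paste(sprintf("%s: %d genes", names(tab), tab), collapse = "; "), "\n", sep = "")
  cat("  ", nrow(x$transports), " transport reaction(s) added\n", sep = "")
  invisible(x)
}

# Rebuild the model with reactions placed in their gene's compartment and
# reversible diffusion transports added.
compartmentalize <- function(model, assignment, compartments, default, transports) {
  out <- gem_model(model$id, stats::setNames(
    ifelse(compartments %in% names(model$compartments),
           model$compartments[compartments], compartments), compartments))
  owners <- reaction_owners(model)
  rxn_comp <- ifelse(is.na(owners), default, assignment[owners])
  exch <- is_exchange(model)
  rxn_comp[exch] <- default
  for (i in seq_len(n_rxns(model))) {
    rid <- model$rxns$id[i]
    col <- model$S[, rid]
    nz <- which(col != 0)
    st <- stats::setNames(col[nz],
                          met_instance_id(model$mets$base_id[nz], rxn_comp[i]))
    out <- add_reaction(out, rid, stoich = st, lb = model$rxns$lb[i],
                        ub = model$rxns$ub[i], gpr = model$gpr[[rid]],
                        name = model$rxns$name[i],
                        subsystem = model$rxns$subsystem[i],
                        ec = model$rxns$ec[i], evidence = model$rxns$evidence[i],
                        exchange = model$rxns$exchange[i])
  }
  if (nrow(transports)) {
    for (i in seq_len(nrow(transports))) {
      a <- met_instance_id(transports$met[i], transports$from[i])
      b <- met_instance_id(transports$met[i], transports$to[i])
      tid <- paste0("T_", transports$met[i], "_", transports$from[i], transports$to[i])
      out <- add_reaction(out, tid, stoich = stats::setNames(c(-1, 1), c(a, b)),
                          lb = -1000, ub = 1000, evidence = "connectivity")
    }
  }
  # carry formulas over
  idx <- match(out$mets$base_id, model$mets$base_id)
  out$mets$formula <- model$mets$formula[idx]
  out$mets$name <- model$mets$name[idx]
  out
}
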