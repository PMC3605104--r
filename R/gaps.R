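# Quality-control and gap-filling MILPs.
#
# All encodings share the big-M indicator pattern: a binary y_i per
# candidate reaction with -M y_i <= v_i <= M y_i, and a cardinality
# objective min sum(y). Minimal sets are made reproducible by a secondary
# lexicographic solve: with the cardinality fixed at its optimum, the sum
# of reaction ranks (position in the reaction table) is minimized, so ties
# between alternate minimal sets always break the same way.

#' Gap-analysis configuration
#'
#' @param big_m indicator big-M constant; must exceed any meaningful flux.
#' @param production_epsilon minimal net rate that counts as "production";
#'   decouples a real leak from numerical noise.
#' @param flux_tolerance zero threshold on fluxes.
#' @param solver_time_limit unused placeholder (the built-in solver is
#'   deterministic); kept so configs serialize stably.
#' @return a list of class `gap_config`.
#' @export
gap_config <- function(big_m = 1000, production_epsilon = 1e-3,
                       flux_tolerance = 1e-6, solver_time_limit = Inf) {
  stopifnot(big_m > production_epsilon, production_epsilon > flux_tolerance,
            flux_tolerance > 0)
  structure(list(big_m = big_m, production_epsilon = production_epsilon,
                 flux_tolerance = flux_tolerance,
                 solver_time_limit = solver_time_limit), class = "gap_config")
}

gap_report <- function(kind, reaction_ids = character(), metabolite_ids = character(),
                       solver_status = "optimal", extra = list()) {
  structure(c(list(kind = kind, reaction_ids = reaction_ids,
                   metabolite_ids = metabolite_ids,
                   objective_size = length(reaction_ids) + length(metabolite_ids),
                   solver_status = solver_status), extra),
            class = "gap_report")
}

#' @export
print.gap_report <- function(x, ...) {
  cat("Gap report [", x$kind, "]: status ", x$solver_status, "\n", sep = "")
  if (length(x$reaction_ids)) cat("  reactions:", paste(x$reaction_ids, collapse = ", "), "\n")
  if (length(x$metabolite_ids)) cat("  metabolites:", paste(x$metabolite_ids, collapse = ", "), "\n")
  invisible(x)
}

# shared core: minimal reaction set with S v >= 0 (or <= 0) elementwise and
# total net production >= eps (<= -eps), exchanges closed.
free_lunch_milp <- function(model, cfg, direction = c("make", "consume")) {
  direction <- match.arg(direction)
  n <- n_rxns(model)
  m <- n_mets(model)
  S <- as.matrix(model$S)
  lb <- pmax(model$rxns$lb, -cfg$big_m)
  ub <- pmin(model$rxns$ub, cfg$big_m)
  exch <- which(is_exchange(model))
  lb[exch] <- 0; ub[exch] <- 0
  # columns: v (n), y (n)
  sgn <- if (direction == "make") 1 else -1
  A <- rbind(
    cbind(sgn * S, matrix(0, m, n)),                  # sgn * S v >= 0
    c(sgn * colSums(S), numeric(n)),                  # total >= eps
    cbind(diag(n), -cfg$big_m * diag(n)),             # v - M y <= 0
    cbind(-diag(n), -cfg$big_m * diag(n)))            # -v - M y <= 0
  sense <- c(rep(">=", m + 1L), rep("<=", 2L * n))
  rhs <- c(numeric(m), cfg$production_epsilon, numeric(2L * n))
  solve_card <- function(extra_obj = NULL, fixed_card = NULL) {
    obj <- c(numeric(n), if (is.null(extra_obj)) rep(1, n) else extra_obj)
    AA <- A; ss <- sense; rr <- rhs
    if (!is.null(fixed_card)) {
      AA <- rbind(AA, c(numeric(n), rep(1, n)))
      ss <- c(ss, "="); rr <- c(rr, fixed_card)
    }
    solve_milp(obj, AA, ss, rr, lb = c(lb, numeric(n)), ub = c(ub, rep(1, n)),
               int_vars = n + seq_len(n), obj_integral = TRUE)
  }
  sol <- solve_card()
  if (!identical(sol$status, "optimal")) {
    return(gap_report(direction, solver_status = "infeasible"))
  }
  k <- round(sol$objval)
  sol2 <- solve_card(extra_obj = seq_len(n), fixed_card = k)
  use <- if (identical(sol2$status, "optimal")) sol2 else sol
  y <- use$x[n + seq_len(n)] > 0.5
  gap_report(direction, reaction_ids = model$rxns$id[y],
             extra = list(fluxes = stats::setNames(use$x[seq_len(n)], model$rxns$id)))
}

#' Smallest reaction set creating mass from nothing
#'
#' With every exchange reaction closed, searches for the minimal-cardinality
#' set of reactions admitting a flux with non-negative net production of
#' every metabolite and strictly positive total production. A feasible
#' answer is a "free lunch" — some participating reaction must be
#' stoichiometrically unbalanced (or of unknown composition); infeasibility
#' certifies the model conserves mass.
#'
#' @param model a [gem_model].
#' @param cfg a [gap_config()].
#' @return a `gap_report` (kind "make"); `solver_status` "infeasible" means
#'   no free lunch exists.
#' @export
make_something <- function(model, cfg = gap_config()) {
  free_lunch_milp(model, cfg, "make")
}

#' Smallest reaction set consuming mass into nothing
#'
#' Mirror of [make_something()]: non-positive net production everywhere and
#' strictly negative total.
#' @inheritParams make_something
#' @return a `gap_report` (kind "consume").
#' @export
consume_something <- function(model, cfg = gap_config()) {
  free_lunch_milp(model, cfg, "consume")
}

#' Iteratively remove mass-unbalanced reactions
#'
#' Alternates [make_something()] / [consume_something()] and, in each round,
#' removes from the returned minimal set those reactions that
#' [elemental_balance()] reports unbalanced (or of unknown composition when
#' `allow_removing_unknown`). Stops when both MILPs are infeasible, i.e. the
#' model conserves mass. If a round's set contains only balanced,
#' known-composition reactions, removal halts with those reactions reported
#' unresolved rather than deleting chemistry that looks correct.
#'
#' @param model a [gem_model].
#' @param cfg a [gap_config()].
#' @param allow_removing_unknown may reactions touching composition-unknown
#'   metabolites be removed?
#' @return list with `model`, `removed` (ids), `unresolved` (ids, empty on
#'   clean convergence), `rounds`.
#' @export
remove_bad_reactions <- function(model, cfg = gap_config(),
                                 allow_removing_unknown = FALSE) {
  removed <- character()
  unresolved <- character()
  rounds <- 0L
  repeat {
    rounds <- rounds + 1L
    progressed <- FALSE
    for (op in list(make_something, consume_something)) {
      rep_ <- op(model, cfg)
      if (!identical(rep_$solver_status, "optimal")) next
      bal <- elemental_balance(model, rep_$reaction_ids)
      bad <- bal$status == "unbalanced"
      if (allow_removing_unknown) bad <- bad | bal$status == "unknown_composition"
      if (!any(bad)) {
        unresolved <- union(unresolved, rep_$reaction_ids)
        next
      }
      drop <- bal$reaction_id[bad]
      model <- remove_reactions(model, drop)
      removed <- c(removed, drop)
      progressed <- TRUE
    }
    if (!progressed) break
    if (rounds > n_rxns(model) + length(removed) + 2L) break  # safety
  }
  list(model = model, removed = removed, unresolved = unresolved, rounds = rounds)
}

#' Which metabolites can have net synthesis (consumption)?
#'
#' A metabolite is producible iff the LP with a temporary sink demanding at
#' least `production_epsilon` of it is feasible, with the model's exchange
#' bounds exactly as the user set them (so the answer depends on which
#' uptakes are open). `can_consume` mirrors this with a temporary source.
#'
#' @param model a [gem_model].
#' @param metabolites instance ids (default all).
#' @param cfg a [gap_config()].
#' @return named logical vector.
#' @export
can_produce <- function(model, metabolites = NULL, cfg = gap_config()) {
  producibility(model, metabolites, cfg, sink = TRUE)
}

#' @rdname can_produce
#' @export
can_consume <- function(model, metabolites = NULL, cfg = gap_config()) {
  producibility(model, metabolites, cfg, sink = FALSE)
}

producibility <- function(model, metabolites, cfg, sink) {
  if (is.null(metabolites)) metabolites <- model$mets$id
  bad <- setdiff(metabolites, model$mets$id)
  if (length(bad)) stop("unknown metabolite(s): ", paste(bad, collapse = ", "))
  lp <- build_lp(model)
  out <- vapply(metabolites, function(met) {
    col <- numeric(lp$n_mets)
    col[match(met, rownames(lp$S))] <- if (sink) -1 else 1
    S2 <- cbind(lp$S, col)
    sol <- solve_lp(numeric(ncol(S2)), S2, rep("=", lp$n_mets), numeric(lp$n_mets),
                    c(lp$lb, cfg$production_epsilon), c(lp$ub, cfg$big_m))
    identical(sol$status, "optimal")
  }, logical(1))
  stats::setNames(out, metabolites)
}

#' Minimal metabolite set whose synthesis unlocks all others
#'
#' Finds the smallest set of metabolites which must be granted net
#' synthesis (an artificial source) so that every metabolite of the model
#' becomes producible. Solved as one MILP: a binary-gated artificial
#' synthesis reaction per currently non-producible metabolite, a sink
#' demanding `production_epsilon` of every metabolite, cardinality
#' objective. For each enabled metabolite the set of metabolites its
#' synthesis unlocks is reported, which is how one reads off e.g. "enable
#' choline and this whole branch of lipid metabolism comes alive".
#'
#' @param model a [gem_model].
#' @param cfg a [gap_config()].
#' @param merge_comps merge all compartments first (connectivity questions
#'   often make more sense compartment-free).
#' @return list with `enabled` (metabolite ids), `unlocks` (named list),
#'   `isolated` (metabolites in no reaction), `status`.
#' @export
check_production <- function(model, cfg = gap_config(), merge_comps = FALSE) {
  if (merge_comps && length(model$compartments) > 1L) {
    model <- merge_compartments(model, names(model$compartments))
  }
  isolated <- model$mets$id[Matrix::rowSums(model$S != 0) == 0]
  if (length(isolated)) {
    return(list(enabled = character(), unlocks = list(), isolated = isolated,
                status = "isolated_metabolites"))
  }
  base <- can_produce(model, cfg = cfg)
  np <- names(base)[!base]
  if (length(np) == 0L) {
    return(list(enabled = character(), unlocks = list(), isolated = character(),
                status = "optimal"))
  }
  m <- n_mets(model); n <- n_rxns(model); k <- length(np)
  S <- as.matrix(model$S)
  npi <- match(np, rownames(S))
  Ssrc <- matrix(0, m, k); Ssrc[cbind(npi, seq_len(k))] <- 1
  # columns: v (n), s (k sources), w (m sinks), y (k binaries)
  A <- rbind(
    cbind(S, Ssrc, -diag(m), matrix(0, m, k)),          # balance rows
    cbind(matrix(0, k, n), diag(k), matrix(0, k, m), -cfg$big_m * diag(k)))  # s <= M y
  sense <- c(rep("=", m), rep("<=", k))
  rhs <- numeric(m + k)
  lb <- c(model$rxns$lb, numeric(k), rep(cfg$production_epsilon, m), numeric(k))
  ub <- c(model$rxns$ub, rep(cfg$big_m, k), rep(cfg$big_m, m), rep(1, k))
  nvar <- n + k + m
  obj <- c(numeric(nvar), rep(1, k))
  sol <- solve_milp(obj, A, sense, rhs, lb, ub, int_vars = nvar + seq_len(k),
                    obj_integral = TRUE)
  if (!identical(sol$status, "optimal")) {
    return(list(enabled = character(), unlocks = list(), isolated = character(),
                status = sol$status))
  }
  card <- round(sol$objval)
  sol2 <- solve_milp(c(numeric(nvar), seq_len(k)),
                     rbind(A, c(numeric(nvar), rep(1, k))), c(sense, "="),
                     c(rhs, card), lb, ub, int_vars = nvar + seq_len(k),
                     obj_integral = TRUE)
  if (identical(sol2$status, "optimal")) sol <- sol2
  enabled <- np[sol$x[nvar + seq_len(k)] > 0.5]
  unlocks <- lapply(enabled, function(met) {
    m2 <- add_reaction(model, paste0(".src_", met),
                       stoich = stats::setNames(1, met), lb = 0, ub = cfg$big_m,
                       evidence = "spontaneous", add_mets = FALSE)
    now <- can_produce(m2, cfg = cfg)
    setdiff(names(now)[now & !base[names(now)]], met)
  })
  names(unlocks) <- enabled
  list(enabled = enabled, unlocks = unlocks, isolated = character(),
       status = "optimal")
}

#' Classify reactions by flux-carrying capability
#'
#' Opens every existing exchange reaction fully (no new exchanges are
#' added), then asks per reaction whether any steady-state flux
#' distribution can route flux through it. Blocked reactions are
#' sub-classified by cause: if a free sink on the reaction's products
#' unblocks it the block is downstream (a product cannot be consumed); if
#' a free source on its substrates unblocks it the block is upstream (a
#' substrate cannot be made); `blocked_both` needs both.
#'
#' @param model a [gem_model].
#' @param cfg a [gap_config()].
#' @return data.frame with `reaction_id`, `status` in can_carry /
#'   blocked_upstream / blocked_downstream / blocked_both, and `max_abs_flux`.
#' @export
have_flux <- function(model, cfg = gap_config()) {
  exch <- names(which(is_exchange(model)))
  m <- set_bounds(model, exch, lb = -cfg$big_m, ub = cfg$big_m)
  lp <- build_lp(m)
  maxabs <- function(lpx, rid) {
    obj <- numeric(ncol(lpx$S)); obj[match(rid, lpx$cols)] <- 1
    hi <- solve_lp(obj, lpx$S, rep("=", lpx$n_mets), numeric(lpx$n_mets),
                   lpx$lb, lpx$ub, maximize = TRUE)
    lo <- solve_lp(obj, lpx$S, rep("=", lpx$n_mets), numeric(lpx$n_mets),
                   lpx$lb, lpx$ub, maximize = FALSE)
    max(abs(c(if (identical(hi$status, "optimal")) hi$objval else 0,
              if (identical(lo$status, "optimal")) lo$objval else 0)))
  }
  relieved <- function(rid, side) {
    col <- m$S[, rid]
    mets <- if (side == "sink") rownames(m$S)[col > 0] else rownames(m$S)[col < 0]
    if (m$rxns$lb[match(rid, m$rxns$id)] < 0) {
      # reversible: relieve both orientations' products/substrates
      mets <- rownames(m$S)[col != 0]
    }
    if (length(mets) == 0L) return(FALSE)
    ec <- lapply(mets, function(met) {
      list(stoich = stats::setNames(if (side == "sink") -1 else 1, met),
           lb = 0, ub = cfg$big_m)
    })
    names(ec) <- paste0(".", side, "_", mets)
    lpx <- build_lp(m, ec)
    maxabs(lpx, rid) > cfg$flux_tolerance
  }
  status <- vapply(m$rxns$id, function(rid) {
    if (maxabs(lp, rid) > cfg$flux_tolerance) return("can_carry")
    down <- relieved(rid, "sink")
    up <- relieved(rid, "source")
    if (down && !up) "blocked_downstream"
    else if (up && !down) "blocked_upstream"
    else if (down && up) {
      # either single-side fix works; report the downstream cause first per
      # the sink-then-source testing order
      "blocked_downstream"
    } else "blocked_both"
  }, character(1))
  mx <- vapply(m$rxns$id, function(rid) maxabs(lp, rid), numeric(1))
  data.frame(reaction_id = m$rxns$id, status = status, max_abs_flux = mx,
             stringsAsFactors = FALSE)
}

#' Connected subnetworks of the metabolite-reaction graph
#'
#' Connected components of the bipartite graph with metabolites and
#' reactions as nodes and an edge wherever a stoichiometric coefficient is
#' non-zero. Currency metabolites (ATP, water, protons ...) connect
#' everything to everything; removing them first (by base id) reveals the
#' biologically meaningful islands.
#'
#' @param model a [gem_model].
#' @param currency_mets base ids to drop before decomposition (default none).
#' @return list of components, each `list(metabolites, reactions)`, sorted
#'   by total size descending.
#' @export
get_subnetworks <- function(model, currency_mets = character()) {
  keep <- !(model$mets$base_id %in% currency_mets)
  S <- model$S[keep, , drop = FALSE]
  metn <- model$mets$id[keep]
  idx <- Matrix::which(S != 0, arr.ind = TRUE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = metn[idx[, 1]], to = paste0("rxn::", model$rxns$id[idx[, 2]])),
    directed = FALSE,
    vertices = data.frame(name = c(metn, paste0("rxn::", model$rxns$id))))
  comp <- igraph::components(g)
  parts <- split(names(comp$membership), comp$membership)
  out <- lapply(parts, function(v) {
    list(metabolites = sort(v[!startsWith(v, "rxn::")]),
         reactions = sort(sub("^rxn::", "", v[startsWith(v, "rxn::")])))
  })
  sizes <- vapply(out, function(p) length(p$metabolites) + length(p$reactions), numeric(1))
  first <- vapply(out, function(p) c(p$reactions, p$metabolites, "")[1], character(1))
  out[order(-sizes, first)]
}

# template reactions absent from the model, by stoichiometric identity
# (sorted instance-id/coefficient pairs + reversibility)
rxn_signature <- function(model, rid, by_base = FALSE) {
  col <- model$S[, rid]
  nz <- which(col != 0)
  ids <- if (by_base) model$mets$base_id[nz] else model$mets$id[nz]
  o <- order(ids)
  paste(paste(ids[o], signif(col[nz][o], 10), sep = ":"), collapse = "|",
        paste0("rev=", model$rxns$lb[match(rid, model$rxns$id)] < 0))
}

#' Minimal gap filling from template models
#'
#' Selects a minimal-cardinality set of candidate reactions (the template
#' reactions not already present, by stoichiometric identity) whose
#' addition makes the goal hold:
#' \describe{
#'   \item{produce_all}{every target metabolite (default: all currently
#'     non-producible) gains net synthesis;}
#'   \item{satisfy_tasks}{every task in `tasks` becomes feasible
#'     (format as [check_tasks()]);}
#'   \item{unblock_all}{every currently blocked model reaction can carry
#'     flux.}
#' }
#' All scenarios share one set of binary selection variables but get their
#' own flux vector, so one MILP certifies the whole goal. Added reactions
#' carry `evidence = "connectivity"` and their source template is recorded.
#'
#' @param model a [gem_model].
#' @param templates list of template [gem_model]s (compartment ids must be
#'   compatible with the model's).
#' @param goal one of "produce_all", "satisfy_tasks", "unblock_all".
#' @param tasks task table for `goal = "satisfy_tasks"`.
#' @param targets metabolite ids for `goal = "produce_all"` (default: the
#'   currently non-producible ones).
#' @param cfg a [gap_config()].
#' @return list with `model`, `added`, `provenance` (named character:
#'   added id -> template id), `status`, `failing` (goal components still
#'   unreachable when status is "infeasible").
#' @export
fill_gaps <- function(model, templates,
                      goal = c("produce_all", "satisfy_tasks", "unblock_all"),
                      tasks = NULL, targets = NULL, cfg = gap_config()) {
  goal <- match.arg(goal)
  if (inherits(templates, "gem_model")) templates <- list(templates)
  have <- vapply(model$rxns$id, function(r) rxn_signature(model, r), character(1))
  cand <- list()
  for (tm in templates) {
    for (rid in tm$rxns$id) {
      sig <- rxn_signature(tm, rid)
      if (sig %in% have) next
      have <- c(have, sig)
      col <- tm$S[, rid]
      nz <- which(col != 0)
      cid <- rid
      while (cid %in% c(model$rxns$id, vapply(cand, `[[`, character(1), "id"))) {
        cid <- paste0(cid, "_t")
      }
      ti <- match(rid, tm$rxns$id)
      cand[[length(cand) + 1L]] <- list(
        id = cid, template = tm$id,
        stoich = stats::setNames(col[nz], tm$mets$id[nz]),
        lb = tm$rxns$lb[ti], ub = tm$rxns$ub[ti],
        gpr = tm$gpr[[rid]], exchange = tm$rxns$exchange[ti])
    }
  }
  # extended model: model + all candidates (gated by y in the MILP)
  ext <- model
  for (cd in cand) {
    for (iid in setdiff(names(cd$stoich), ext$mets$id)) {
      p <- parse_met_instance(iid)
      if (!p$compartment %in% names(ext$compartments)) {
        stop("template compartment ", sQuote(p$compartment),
             " absent from the model; merge or relabel first")
      }
    }
    ext <- add_reaction(ext, cd$id, stoich = cd$stoich, lb = cd$lb, ub = cd$ub,
                        gpr = cd$gpr, evidence = "connectivity", add_mets = TRUE,
                        exchange = cd$exchange)
  }
  nc <- length(cand)
  cand_ids <- vapply(cand, `[[`, character(1), "id")
  if (is.null(targets)) {
    base <- can_produce(model, cfg = cfg)
    targets <- names(base)[!base]
  }
  scen <- build_gap_scenarios(ext, model, goal, tasks, targets, cfg)
  if (length(scen) == 0L) {
    return(list(model = model, added = character(),
                provenance = stats::setNames(character(), character()),
                status = "optimal", failing = character()))
  }
  if (length(cand) == 0L) {
    ok <- vapply(scen, function(s) scenario_feasible(model, s, cfg), logical(1))
    return(list(model = model, added = character(),
                provenance = stats::setNames(character(), character()),
                status = if (all(ok)) "optimal" else "infeasible",
                failing = vapply(scen[!ok], `[[`, character(1), "label")))
  }
  res <- solve_gap_fill(ext, cand_ids, scen, cfg)
  if (!identical(res$status, "optimal")) {
    failing <- vapply(scen, function(s) !scenario_feasible(ext, s, cfg), logical(1))
    return(list(model = model, added = character(),
                provenance = stats::setNames(character(), character()),
                status = "infeasible",
                failing = vapply(scen[failing], `[[`, character(1), "label")))
  }
  added <- res$added
  out <- ext
  drop <- setdiff(cand_ids, added)
  if (length(drop)) out <- remove_reactions(out, drop, drop_orphan_mets = TRUE)
  prov <- stats::setNames(
    vapply(cand[match(added, cand_ids)], `[[`, character(1), "template"), added)
  list(model = out, added = added, provenance = prov, status = "optimal",
       failing = character())
}

# Scenario: a list(label, bounds_override (named list lb/ub), extra_cols,
# require = list(list(rxn = id, min_abs = eps)) ) over the extended model.
build_gap_scenarios <- function(ext, model, goal, tasks, targets, cfg) {
  if (goal == "produce_all") {
    if (length(targets) == 0L) return(list())
    ec <- lapply(targets, function(met) {
      list(stoich = stats::setNames(-1, met), lb = cfg$production_epsilon,
           ub = cfg$big_m)
    })
    names(ec) <- paste0(".sink_", targets)
    return(list(list(label = "produce_all", extra_cols = ec,
                     bounds = NULL, require = list())))
  }
  if (goal == "satisfy_tasks") {
    if (is.null(tasks) || nrow(tasks) == 0L) return(list())
    exch <- names(which(is_exchange(model)))
    lapply(seq_len(nrow(tasks)), function(i) {
      row <- tasks[i, ]
      ec <- list()
      for (p in strsplit(paste0(row$inputs, ""), ";")[[1]]) {
        p <- trimws(p); if (!nzchar(p) || is.na(p)) next
        kv <- trimws(strsplit(p, ":")[[1]])
        ec[[paste0(".in_", kv[1])]] <- list(
          stoich = stats::setNames(1, kv[1]), lb = 0,
          ub = if (length(kv) > 1) as.numeric(kv[2]) else cfg$big_m)
      }
      for (p in strsplit(paste0(row$outputs, ""), ";")[[1]]) {
        p <- trimws(p); if (!nzchar(p) || is.na(p)) next
        kv <- trimws(strsplit(p, ":")[[1]])
        ec[[paste0(".out_", kv[1])]] <- list(
          stoich = stats::setNames(-1, kv[1]),
          lb = if (length(kv) > 1) as.numeric(kv[2]) else cfg$production_epsilon,
          ub = cfg$big_m)
      }
      list(label = paste0("task:", row$description), extra_cols = ec,
           bounds = list(rxns = exch, lb = 0, ub = 0), require = list())
    })
  } else {  # unblock_all
    hf <- have_flux(model, cfg)
    blocked <- hf$reaction_id[hf$status != "can_carry"]
    lapply(blocked, function(rid) {
      list(label = paste0("unblock:", rid), extra_cols = list(), bounds = NULL,
           require = list(list(rxn = rid, min_abs = cfg$production_epsilon)))
    })
  }
}

scenario_lp <- function(ext, scen, cfg) {
  m <- ext
  if (!is.null(scen$bounds)) {
    m <- set_bounds(m, scen$bounds$rxns, lb = scen$bounds$lb, ub = scen$bounds$ub)
  }
  # open exchanges fully for unblock scenarios? no: respect model bounds
  build_lp(m, scen$extra_cols)
}

# is the scenario feasible with every candidate reaction enabled?
scenario_feasible <- function(ext, scen, cfg) {
  lp <- scenario_lp(ext, scen, cfg)
  A <- lp$S
  sense <- rep("=", lp$n_mets)
  rhs <- numeric(lp$n_mets)
  lbx <- lp$lb; ubx <- lp$ub
  intv <- integer()
  for (rq in scen$require) {
    j <- match(rq$rxn, lp$cols)
    if (lbx[j] >= 0) {
      lbx[j] <- max(lbx[j], rq$min_abs)
      next
    }
    # reversible |v| >= eps via a direction binary d:
    #   v - M d <= -eps   (d = 0 forces the reverse direction)
    #   v - M d >= eps-M  (d = 1 forces the forward direction)
    A <- cbind(A, 0)
    d <- ncol(A)
    r1 <- numeric(d); r1[j] <- 1; r1[d] <- -cfg$big_m
    r2 <- r1
    A <- rbind(A, r1, r2)
    sense <- c(sense, "<=", ">=")
    rhs <- c(rhs, -rq$min_abs, rq$min_abs - cfg$big_m)
    lbx <- c(lbx, 0); ubx <- c(ubx, 1)
    intv <- c(intv, d)
  }
  sol <- solve_milp(numeric(ncol(A)), A, sense, rhs, lbx, ubx, int_vars = intv)
  identical(sol$status, "optimal")
}

solve_gap_fill <- function(ext, cand_ids, scen, cfg) {
  ns <- length(scen)
  lps <- lapply(scen, scenario_lp, ext = ext, cfg = cfg)
  widths <- vapply(lps, function(l) ncol(l$S), integer(1))
  nc <- length(cand_ids)
  nvar <- sum(widths)          # scenario flux blocks
  total <- nvar + nc           # + binaries
  rows <- list(); sense <- character(); rhs <- numeric()
  lb <- numeric(0); ub <- numeric(0)
  intv <- nvar + seq_len(nc)
  offset <- 0L
  extra_rows <- list()
  req_specs <- list()
  for (s in seq_len(ns)) {
    lp <- lps[[s]]
    blk <- matrix(0, lp$n_mets, total)
    blk[, offset + seq_len(widths[s])] <- lp$S
    rows[[length(rows) + 1L]] <- blk
    sense <- c(sense, rep("=", lp$n_mets))
    rhs <- c(rhs, numeric(lp$n_mets))
    lbs <- lp$lb; ubs <- lp$ub
    ci <- match(cand_ids, lp$cols)
    for (k in seq_len(nc)) {
      j <- offset + ci[k]
      # v_j <= M y_k ; v_j >= -M y_k
      r1 <- numeric(total); r1[j] <- 1; r1[nvar + k] <- -cfg$big_m
      r2 <- numeric(total); r2[j] <- -1; r2[nvar + k] <- -cfg$big_m
      extra_rows[[length(extra_rows) + 1L]] <- r1
      extra_rows[[length(extra_rows) + 1L]] <- r2
    }
    for (rq in scen[[s]]$require) {
      j <- offset + match(rq$rxn, lp$cols)
      if (lbs[j - offset] >= 0) {
        lbs[match(rq$rxn, lp$cols)] <- max(lbs[match(rq$rxn, lp$cols)], rq$min_abs)
      } else {
        req_specs[[length(req_specs) + 1L]] <- list(col = j, eps = rq$min_abs)
      }
    }
    lb <- c(lb, lbs); ub <- c(ub, ubs)
    offset <- offset + widths[s]
  }
  lb <- c(lb, numeric(nc)); ub <- c(ub, rep(1, nc))
  # direction binaries for reversible require constraints
  for (rq in req_specs) {
    lb <- c(lb, 0); ub <- c(ub, 1)
    total2 <- length(lb)
    intv <- c(intv, total2)
  }
  total2 <- length(lb)
  pad <- function(r) c(r, numeric(total2 - length(r)))
  A <- do.call(rbind, c(lapply(rows, function(b) cbind(b, matrix(0, nrow(b), total2 - total))),
                        lapply(extra_rows, function(r) matrix(pad(r), 1))))
  sense <- c(sense, rep("<=", length(extra_rows)))
  rhs <- c(rhs, numeric(length(extra_rows)))
  dcol <- nvar + nc
  for (rq in req_specs) {
    dcol <- dcol + 1L
    r1 <- numeric(total2); r1[rq$col] <- 1; r1[dcol] <- -cfg$big_m  # v - M d <= -eps
    r2 <- numeric(total2); r2[rq$col] <- 1; r2[dcol] <- -cfg$big_m  # v - M d >= eps - M
    A <- rbind(A, r1, r2)
    sense <- c(sense, "<=", ">=")
    rhs <- c(rhs, -rq$eps, rq$eps - cfg$big_m)
  }
  obj <- numeric(total2); obj[nvar + seq_len(nc)] <- 1
  sol <- solve_milp(obj, A, sense, rhs, lb, ub, int_vars = intv, obj_integral = TRUE)
  if (!identical(sol$status, "optimal")) return(list(status = sol$status))
  card <- round(sum(sol$x[nvar + seq_len(nc)]))
  # lexicographic secondary objective for reproducible minimal sets
  obj2 <- numeric(total2); obj2[nvar + seq_len(nc)] <- seq_len(nc)
  A2 <- rbind(A, replace(numeric(total2), nvar + seq_len(nc), 1))
  sol2 <- solve_milp(obj2, A2, c(sense, "="), c(rhs, card), lb, ub,
                     int_vars = intv, obj_integral = TRUE)
  if (identical(sol2$status, "optimal")) sol <- sol2
  list(status = "optimal", added = cand_ids[sol$x[nvar + seq_len(nc)] > 0.5])
}
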