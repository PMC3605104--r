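# Flux balance analysis and phenotype simulation.
#
# Fluxes are in mmol/gDW/h inside the default +-1000 box. The steady-state
# constraint S v = 0 holds for every internal metabolite; exchange reactions
# (single-metabolite columns) connect the network to the environment with
# positive flux = excretion, negative = uptake.

# Build the LP skeleton for a model, optionally with extra columns
# (temporary sinks/sources, artificial reactions). Returns dense S over all
# columns plus bounds and column names.
build_lp <- function(model, extra_cols = list()) {
  S <- as.matrix(model$S)
  lb <- model$rxns$lb
  ub <- model$rxns$ub
  cols <- model$rxns$id
  for (nm in names(extra_cols)) {
    ec <- extra_cols[[nm]]
    col <- numeric(nrow(S))
    idx <- match(names(ec$stoich), rownames(S))
    if (anyNA(idx)) stop("extra column ", sQuote(nm), " references unknown metabolite")
    col[idx] <- unname(ec$stoich)
    S <- cbind(S, col)
    lb <- c(lb, ec$lb)
    ub <- c(ub, ec$ub)
    cols <- c(cols, nm)
  }
  colnames(S) <- cols
  list(S = S, lb = lb, ub = ub, cols = cols, n_mets = nrow(S))
}

#' Flux balance analysis
#'
#' Maximizes (or minimizes) a linear objective over the steady-state flux
#' polytope \{v : S v = 0, lb <= v <= ub\}. Shadow prices are reported per
#' metabolite with the convention that a positive price means extra
#' availability of the metabolite (a small free source) would increase the
#' objective.
#'
#' With `pfba = TRUE` the objective is fixed at its optimum and total
#' absolute flux is minimized before reporting fluxes — alternate optima
#' make auxiliary fluxes irreproducible otherwise.
#'
#' @param model a [gem_model].
#' @param objective named numeric (reaction id -> weight); defaults to the
#'   model objective.
#' @param maximize logical (default TRUE).
#' @param pfba minimize total |v| at the fixed optimum before reporting.
#' @return object of class `gem_flux`: list with `fluxes`, `objective_value`,
#'   `shadow_prices`, `status`.
#' @export
fba <- function(model, objective = model$objective, maximize = TRUE, pfba = FALSE) {
  stopifnot(inherits(model, "gem_model"))
  if (length(objective) == 0L) stop("no objective set")
  lp <- build_lp(model)
  obj <- numeric(ncol(lp$S))
  idx <- match(names(objective), lp$cols)
  if (anyNA(idx)) stop("objective references unknown reaction(s)")
  obj[idx] <- unname(objective)
  sol <- solve_lp(obj, lp$S, rep("=", lp$n_mets), numeric(lp$n_mets),
                  lp$lb, lp$ub, maximize = maximize)
  if (!identical(sol$status, "optimal")) {
    return(structure(list(fluxes = NULL, objective_value = NA_real_,
                          shadow_prices = NULL, status = sol$status),
                     class = "gem_flux"))
  }
  fluxes <- stats::setNames(sol$x, lp$cols)
  sp <- stats::setNames(-sol$duals, rownames(lp$S))
  if (pfba) {
    n <- ncol(lp$S)
    big <- pmax(abs(lp$lb), abs(lp$ub))
    # min sum a_i, a_i >= |v_i|, objective row fixed at optimum
    obj2 <- c(numeric(n), rep(1, n))
    A <- rbind(
      cbind(lp$S, matrix(0, lp$n_mets, n)),
      c(obj, numeric(n)),
      cbind(diag(n), -diag(n)),    # v - a <= 0
      cbind(-diag(n), -diag(n)))   # -v - a <= 0
    sense <- c(rep("=", lp$n_mets), "=", rep("<=", 2 * n))
    rhs <- c(numeric(lp$n_mets), sol$objval, numeric(2 * n))
    sol2 <- solve_lp(obj2, A, sense, rhs, c(lp$lb, numeric(n)), c(lp$ub, big),
                     maximize = FALSE)
    if (identical(sol2$status, "optimal")) {
      fluxes <- stats::setNames(sol2$x[seq_len(n)], lp$cols)
    }
  }
  structure(list(fluxes = fluxes, objective_value = sol$objval,
                 shadow_prices = sp, status = "optimal"),
            class = "gem_flux")
}

#' @export
print.gem_flux <- function(x, ...) {
  cat("Flux distribution (", x$status, ")\n", sep = "")
  if (identical(x$status, "optimal")) {
    cat("  objective value:", format(x$objective_value), "\n")
    nz <- sum(abs(x$fluxes) > 1e-9)
    cat("  ", nz, " of ", length(x$fluxes), " reactions carry flux\n", sep = "")
  }
  invisible(x)
}

#' Shadow prices of metabolites
#'
#' Extracts LP duals from an optimal [fba()] solution: the marginal gain in
#' objective per unit of extra availability of the metabolite. Because duals
#' can be degenerate, [shadow_price_fd()] provides an independent
#' finite-difference estimate (temporary source of rate eps, re-solve).
#'
#' @param flux a `gem_flux` from [fba()].
#' @param metabolites metabolite instance ids (default all).
#' @return named numeric vector.
#' @export
shadow_prices <- function(flux, metabolites = NULL) {
  stopifnot(inherits(flux, "gem_flux"), identical(flux$status, "optimal"))
  sp <- flux$shadow_prices
  if (!is.null(metabolites)) {
    bad <- setdiff(metabolites, names(sp))
    if (length(bad)) stop("unknown metabolite(s): ", paste(bad, collapse = ", "))
    sp <- sp[metabolites]
  }
  sp
}

#' @rdname shadow_prices
#' @param model the model the flux came from.
#' @param metabolite one metabolite instance id.
#' @param objective,maximize as in [fba()].
#' @param eps source rate for the finite difference.
#' @export
shadow_price_fd <- function(model, metabolite, objective = model$objective,
                            maximize = TRUE, eps = 1e-4) {
  base <- fba(model, objective, maximize)
  # the source is optional (ub = eps, lb = 0): extra availability of a
  # metabolite the network cannot absorb must read as 0, not infeasible
  ec <- list(src = list(stoich = stats::setNames(1, metabolite), lb = 0, ub = eps))
  lp <- build_lp(model, ec)
  obj <- numeric(ncol(lp$S))
  obj[match(names(objective), lp$cols)] <- unname(objective)
  sol <- solve_lp(obj, lp$S, rep("=", lp$n_mets), numeric(lp$n_mets),
                  lp$lb, lp$ub, maximize = maximize)
  if (!identical(sol$status, "optimal") || !identical(base$status, "optimal")) {
    return(NA_real_)
  }
  (sol$objval - base$objective_value) / eps
}

#' Minimization of metabolic adjustment (MoMA)
#'
#' Finds the feasible flux distribution of a (typically perturbed) model
#' closest in Euclidean distance to a reference flux distribution:
#' `min ||v - v_ref||^2` s.t. `S v = 0`, bounds. Solved as a strictly convex
#' QP via quadprog.
#'
#' @param model the (perturbed) [gem_model].
#' @param reference a `gem_flux` or named flux vector over the model's
#'   reactions (missing entries are treated as 0).
#' @return a `gem_flux` with extra field `distance` (Euclidean).
#' @export
moma <- function(model, reference) {
  ref <- if (inherits(reference, "gem_flux")) reference$fluxes else reference
  v0 <- numeric(n_rxns(model))
  idx <- match(names(ref), model$rxns$id)
  v0[idx[!is.na(idx)]] <- unname(ref)[!is.na(idx)]
  n <- n_rxns(model)
  S <- as.matrix(model$S)
  Amat <- cbind(t(S), diag(n), -diag(n))
  bvec <- c(numeric(nrow(S)), model$rxns$lb, -model$rxns$ub)
  sol <- tryCatch(
    quadprog::solve.QP(Dmat = diag(n), dvec = v0, Amat = Amat, bvec = bvec,
                       meq = nrow(S)),
    error = function(e) NULL)
  if (is.null(sol)) {
    return(structure(list(fluxes = NULL, objective_value = NA_real_,
                          shadow_prices = NULL, status = "infeasible",
                          distance = NA_real_), class = "gem_flux"))
  }
  v <- stats::setNames(sol$solution, model$rxns$id)
  structure(list(fluxes = v, objective_value = NA_real_, shadow_prices = NULL,
                 status = "optimal", distance = sqrt(sum((v - v0)^2))),
            class = "gem_flux")
}

# reactions disabled by a gene deletion set
disabled_reactions <- function(model, deleted) {
  keep <- vapply(model$rxns$id, function(rid) evaluate_gpr(model$gpr[[rid]], deleted),
                 logical(1))
  model$rxns$id[!keep]
}

#' Combinatorial gene-deletion screen
#'
#' Evaluates all gene deletion combinations up to `max_k` (<= 3): reactions
#' whose gene association evaluates false are constrained to zero and the
#' objective re-optimized by FBA or MoMA. Supersets of combinations that
#' already abolish the objective are pruned — a genome-scale triple screen
#' is otherwise computationally hopeless.
#'
#' When `coupling_target` is given (e.g. a product exchange), its flux at
#' the objective optimum is reported; the optimum is usually degenerate, so
#' the target is re-optimized at fixed objective in the direction given by
#' `coupling_mode` ("max": best-case coupled flux, "min": guaranteed flux).
#'
#' @param model a [gem_model].
#' @param max_k maximum number of simultaneous deletions (1-3).
#' @param objective named numeric; defaults to the model objective.
#' @param method "fba" or "moma" (MoMA uses the wild-type FBA flux as
#'   reference).
#' @param coupling_target optional reaction id to monitor.
#' @param coupling_mode "max" or "min" (see above).
#' @param genes genes to screen; defaults to all model genes.
#' @return data.frame with columns `genes`, `k`, `objective_value`,
#'   `target_flux`.
#' @export
deletion_screen <- function(model, max_k = 1L, objective = model$objective,
                            method = c("fba", "moma"), coupling_target = NULL,
                            coupling_mode = c("max", "min"),
                            genes = model$genes) {
  method <- match.arg(method)
  coupling_mode <- match.arg(coupling_mode)
  stopifnot(max_k >= 1L, max_k <= 3L)
  wt <- fba(model, objective)
  lethal <- list()
  rows <- list()
  eval_combo <- function(del) {
    off <- disabled_reactions(model, del)
    m2 <- if (length(off)) set_bounds(model, off, lb = 0, ub = 0) else model
    if (method == "moma") {
      fx <- moma(m2, wt)
      objv <- if (identical(fx$status, "optimal")) {
        sum(fx$fluxes[names(objective)] * objective)
      } else NA_real_
    } else {
      fx <- fba(m2, objective)
      objv <- fx$objective_value
    }
    tgt <- NA_real_
    if (!is.null(coupling_target) && identical(fx$status, "optimal")) {
      if (method == "fba") {
        tgt <- optimize_at_fixed_objective(m2, objective, objv, coupling_target,
                                           maximize = coupling_mode == "max")
      } else {
        tgt <- unname(fx$fluxes[coupling_target])
      }
    }
    list(obj = objv, tgt = tgt)
  }
  for (k in seq_len(max_k)) {
    if (k > length(genes)) break
    combos <- utils::combn(genes, k, simplify = FALSE)
    for (del in combos) {
      if (any(vapply(lethal, function(l) all(l %in% del), logical(1)))) next
      r <- eval_combo(del)
      if (!is.na(r$obj) && abs(r$obj) < 1e-9) lethal <- c(lethal, list(del))
      rows[[length(rows) + 1L]] <- data.frame(
        genes = paste(del, collapse = ";"), k = k,
        objective_value = r$obj, target_flux = r$tgt, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# maximize/minimize a single reaction with the primary objective fixed
optimize_at_fixed_objective <- function(model, objective, opt_value, target,
                                        maximize = TRUE) {
  lp <- build_lp(model)
  objrow <- numeric(ncol(lp$S))
  objrow[match(names(objective), lp$cols)] <- unname(objective)
  tgt <- numeric(ncol(lp$S))
  tgt[match(target, lp$cols)] <- 1
  sol <- solve_lp(tgt, rbind(lp$S, objrow),
                  c(rep("=", lp$n_mets), "="), c(numeric(lp$n_mets), opt_value),
                  lp$lb, lp$ub, maximize = maximize)
  if (identical(sol$status, "optimal")) sol$objval else NA_real_
}

#' Check metabolic tasks
#'
#' Each task is a feasibility question: with every exchange reaction closed
#' and only the task's allowed inputs available (temporary sources, capped
#' at the stated rates), can the required outputs be produced at at least
#' their stated rates? A task passes when feasibility matches its
#' expectation, so negative controls ("must NOT be able to ...") are
#' first-class.
#'
#' @param model a [gem_model].
#' @param tasks data.frame with columns `description`, `inputs`
#'   (semicolon-separated `"met[c]:maxrate"`), `outputs`
#'   (`"met[c]:minrate"`), `expected` ("feasible"/"infeasible"), optional
#'   `bounds` (`"rxn:lb:ub;..."` overrides).
#' @return data.frame with `description`, `expected`, `observed`, `pass`,
#'   `error`.
#' @export
check_tasks <- function(model, tasks) {
  parse_rates <- function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(list())
    parts <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
    out <- lapply(parts, function(p) {
      kv <- trimws(strsplit(p, ":", fixed = TRUE)[[1]])
      list(met = kv[1], rate = if (length(kv) > 1L) as.numeric(kv[2]) else 1000)
    })
    out
  }
  exch <- names(which(is_exchange(model)))
  closed <- set_bounds(model, exch, lb = 0, ub = 0)
  res <- lapply(seq_len(nrow(tasks)), function(i) {
    row <- tasks[i, ]
    obs <- tryCatch({
      m <- closed
      if (!is.null(row$bounds) && !is.na(row$bounds) && nzchar(trimws(row$bounds))) {
        for (b in trimws(strsplit(row$bounds, ";")[[1]])) {
          kv <- trimws(strsplit(b, ":")[[1]])
          m <- set_bounds(m, kv[1], lb = as.numeric(kv[2]), ub = as.numeric(kv[3]))
        }
      }
      ec <- list()
      for (inp in parse_rates(row$inputs)) {
        if (!inp$met %in% m$mets$id) stop("unknown metabolite ", sQuote(inp$met))
        ec[[paste0("task_in_", inp$met)]] <-
          list(stoich = stats::setNames(1, inp$met), lb = 0, ub = inp$rate)
      }
      for (outp in parse_rates(row$outputs)) {
        if (!outp$met %in% m$mets$id) stop("unknown metabolite ", sQuote(outp$met))
        ec[[paste0("task_out_", outp$met)]] <-
          list(stoich = stats::setNames(-1, outp$met), lb = outp$rate, ub = 1000)
      }
      lp <- build_lp(m, ec)
      sol <- solve_lp(numeric(ncol(lp$S)), lp$S, rep("=", lp$n_mets),
                      numeric(lp$n_mets), lp$lb, lp$ub)
      if (identical(sol$status, "optimal")) "feasible" else "infeasible"
    }, error = function(e) conditionMessage(e))
    err <- !obs %in% c("feasible", "infeasible")
    data.frame(description = row$description, expected = row$expected,
               observed = if (err) NA_character_ else obs,
               pass = if (err) NA else identical(obs, row$expected),
               error = if (err) obs else NA_character_, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Fit maintenance-ATP parameters from chemostat data
#'
#' The ATP demand not accounted for by biomass synthesis follows
#' `q_ATP = m_ATP + K_xATP * mu` across dilution rates `mu` of a
#' substrate-limited chemostat; `m_ATP` (mmol ATP/gDW/h) is the
#' non-growth-associated and `K_xATP` (mmol ATP/gDW) the growth-associated
#' maintenance. Fitted by (weighted) linear regression; when the table
#' carries a `sigma` column of per-measurement uncertainties the fit is
#' weighted by `1/sigma^2`.
#'
#' If the table lacks `q_atp` but a model plus its ATP-hydrolysis reaction
#' id are supplied, `q_atp` is computed per row by fixing the measured
#' exchange rates (columns named by exchange reaction id) and maximizing
#' the hydrolysis flux.
#'
#' @param chemostat data.frame with `mu`, and `q_atp` (or exchange-rate
#'   columns), optional `sigma`.
#' @param model optional [gem_model] used to compute `q_atp`.
#' @param atp_rxn ATP hydrolysis/maintenance reaction id in `model`.
#' @return object of class `maintenance_fit`: `m_atp`, `k_xatp`,
#'   `residuals`, `r_squared`, `fit` (the lm).
#' @export
fit_maintenance <- function(chemostat, model = NULL, atp_rxn = NULL) {
  if (length(unique(chemostat$mu)) < 2L) {
    stop("need at least two distinct dilution rates")
  }
  if (is.null(chemostat$q_atp)) {
    if (is.null(model) || is.null(atp_rxn)) {
      stop("table lacks q_atp; supply model and atp_rxn to compute it")
    }
    excols <- intersect(names(chemostat), model$rxns$id)
    chemostat$q_atp <- vapply(seq_len(nrow(chemostat)), function(i) {
      m <- model
      for (rid in excols) {
        m <- set_bounds(m, rid, lb = chemostat[[rid]][i], ub = chemostat[[rid]][i])
      }
      f <- fba(m, stats::setNames(1, atp_rxn))
      if (identical(f$status, "optimal")) f$objective_value else NA_real_
    }, numeric(1))
  }
  w <- if (!is.null(chemostat$sigma) && all(chemostat$sigma > 0)) 1 / chemostat$sigma^2 else NULL
  fit <- stats::lm(q_atp ~ mu, data = chemostat, weights = w)
  cf <- stats::coef(fit)
  if (anyNA(cf)) stop("singular regression")
  structure(list(m_atp = unname(cf[1]), k_xatp = unname(cf[2]),
                 residuals = stats::residuals(fit),
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 fit = fit),
            class = "maintenance_fit")
}

#' @export
print.maintenance_fit <- function(x, ...) {
  cat(sprintf("Maintenance fit: m_ATP = %.4g mmol ATP/gDW/h, K_xATP = %.4g mmol ATP/gDW (R^2 = %.4f)\n",
              x$m_atp, x$k_xatp, x$r_squared))
  invisible(x)
}

#' Fit the P/O ratio via ATP-synthase proton stoichiometry
#'
#' The effective P/O ratio of oxidative phosphorylation is set by the number
#' of protons the F0F1-ATPase translocates per ATP synthesized. This routine
#' grid-searches that stoichiometric coefficient: for each candidate value
#' the synthase reaction's proton coefficient is rewritten, the model is run
#' against each measured row (the driver exchange fixed to the measured
#' rate, ATP output maximized), and the squared error against measured ATP
#' rates accumulated.
#'
#' @param model a [gem_model].
#' @param data data.frame with columns `rate` (driver exchange rate, sign as
#'   the exchange convention requires) and `q_atp` (measured).
#' @param synthase_id ATP synthase reaction id.
#' @param proton_met proton metabolite instance id consumed by the synthase.
#' @param driver_rxn exchange reaction fixed to `rate` per row.
#' @param atp_rxn reaction whose maximal flux is the predicted ATP rate.
#' @param grid candidate protons-per-ATP values.
#' @return object of class `po_fit`: `h_per_atp`, `sse`, `identifiable`,
#'   `at_boundary`, `grid`, `sse_grid`.
#' @export
fit_po_ratio <- function(model, data, synthase_id, proton_met, driver_rxn,
                         atp_rxn, grid = seq(1, 6, by = 0.05)) {
  if (!synthase_id %in% model$rxns$id) stop("synthase reaction ", sQuote(synthase_id), " not in model")
  if (!proton_met %in% model$mets$id) stop("proton metabolite ", sQuote(proton_met), " not in model")
  sse <- vapply(grid, function(h) {
    m <- model
    m$S[proton_met, synthase_id] <- -h
    pred <- vapply(seq_len(nrow(data)), function(i) {
      mi <- set_bounds(m, driver_rxn, lb = data$rate[i], ub = data$rate[i])
      f <- fba(mi, stats::setNames(1, atp_rxn))
      if (identical(f$status, "optimal")) f$objective_value else NA_real_
    }, numeric(1))
    sum((pred - data$q_atp)^2)
  }, numeric(1))
  if (all(is.na(sse))) stop("no candidate stoichiometry gave a feasible model")
  rng <- diff(range(sse, na.rm = TRUE))
  identifiable <- is.finite(rng) && rng > 1e-9 * max(1, max(abs(sse), na.rm = TRUE))
  best <- which.min(sse)
  at_boundary <- best %in% c(1L, length(grid))
  if (at_boundary && identifiable) {
    warning("optimum at grid boundary; the true stoichiometry may lie outside the grid")
  }
  if (!identifiable) warning("objective flat across the grid: P/O not identifiable from these data")
  structure(list(h_per_atp = grid[best], sse = sse[best],
                 identifiable = identifiable, at_boundary = at_boundary,
                 grid = grid, sse_grid = sse), class = "po_fit")
}

#' @export
print.po_fit <- function(x, ...) {
  cat(sprintf("P/O fit: %.3g protons per ATP (SSE %.4g)%s\n", x$h_per_atp, x$sse,
              if (!x$identifiable) " [non-identifiable]" else ""))
  invisible(x)
}

#' Block futile cofactor cycles
#'
#' NADH and NADPH carry similar energy, so reversible dehydrogenase pairs
#' that accept either cofactor create transhydrogenase-like cycles that are
#' probably inactive in vivo but distort redox accounting in simulations.
#' The probe reaction (default `NADH + NADP <=> NAD + NADPH`) is added, all
#' carbon uptakes are closed, and while the probe can still carry flux the
#' most active internal cycle reaction is deleted. The probe is removed and
#' the uptake bounds restored before returning.
#'
#' @param model a [gem_model].
#' @param probe_equation probe reaction equation string.
#' @param tol flux tolerance.
#' @param max_rounds safety cap.
#' @return list with `model` (cycles blocked) and `deleted` reaction ids.
#' @export
block_cofactor_cycles <- function(model, probe_equation, tol = 1e-6,
                                  max_rounds = 50L) {
  pe <- parse_equation(probe_equation)
  if (!all(names(pe$stoich) %in% model$mets$id)) {
    stop("probe references metabolites absent from the model")
  }
  work <- add_reaction(model, ".probe", stoich = pe$stoich, lb = -1000, ub = 1000,
                       evidence = "spontaneous", add_mets = FALSE)
  # close carbon uptakes: exchanges of metabolites whose formula contains C
  exch <- names(which(is_exchange(work)))
  orig_lb <- stats::setNames(work$rxns$lb[match(exch, work$rxns$id)], exch)
  for (rid in exch) {
    met <- rownames(work$S)[which(work$S[, rid] != 0)]
    f <- parse_formula(work$mets$formula[match(met, work$mets$id)])
    has_c <- !is.null(f) && "C" %in% names(f) && f[["C"]] > 0
    if (has_c || is.null(f)) work <- set_bounds(work, rid, lb = 0)  # unknown: be safe
  }
  deleted <- character()
  for (round in seq_len(max_rounds)) {
    fwd <- fba(work, stats::setNames(1, ".probe"), maximize = TRUE, pfba = TRUE)
    rev <- fba(work, stats::setNames(1, ".probe"), maximize = FALSE, pfba = TRUE)
    vmax <- max(abs(c(fwd$objective_value, rev$objective_value)), na.rm = TRUE)
    if (!is.finite(vmax) || vmax <= tol) break
    use <- if (abs(fwd$objective_value) >= abs(rev$objective_value)) fwd else rev
    act <- use$fluxes
    cand <- setdiff(names(act)[abs(act) > tol], c(".probe", exch))
    if (length(cand) == 0L) break
    # deterministic: largest participating flux, ties by id order
    cand <- cand[order(-abs(act[cand]), cand)]
    del <- cand[1]
    deleted <- c(deleted, del)
    work <- remove_reactions(work, del)
  }
  work <- remove_reactions(work, ".probe")
  still <- intersect(names(orig_lb), work$rxns$id)
  work <- set_bounds(work, still, lb = unname(orig_lb[still]))
  list(model = work, deleted = deleted)
}

#' Maximum theoretical product yield
#'
#' Closes all uptakes, opens the stated medium exchanges freely, keeps
#' excretion of every exchange metabolite allowed, fixes the substrate
#' uptake rate, and maximizes the product exchange. The yield is the
#' product flux divided by the substrate uptake rate (mol/mol when both
#' rates share units). `free_atp_equation` optionally adds an artificial
#' cost-free ATP regeneration reaction (`ADP + Pi => ATP + H2O`) to probe
#' how ATP-limited the yield is.
#'
#' @param model a [gem_model].
#' @param substrate substrate exchange reaction id.
#' @param product product exchange reaction id.
#' @param medium exchange reaction ids left freely open for uptake.
#' @param uptake_rate substrate uptake rate (default 1.0 mmol/gDW/h).
#' @param free_atp_equation optional artificial ATP reaction equation.
#' @return list with `yield`, `flux` (a `gem_flux`), `diagnostic` (NULL or
#'   the [have_flux()] classification of the product when unreachable).
#' @export
theoretical_yield <- function(model, substrate, product, medium = character(),
                              uptake_rate = 1, free_atp_equation = NULL) {
  stopifnot(substrate %in% model$rxns$id, product %in% model$rxns$id)
  exch <- names(which(is_exchange(model)))
  m <- set_bounds(model, exch, lb = 0)          # no uptakes ...
  m <- set_bounds(m, exch, ub = 1000)           # ... excretion allowed
  if (length(medium)) m <- set_bounds(m, medium, lb = -1000)
  m <- set_bounds(m, substrate, lb = -uptake_rate, ub = -uptake_rate)
  if (!is.null(free_atp_equation)) {
    m <- add_reaction(m, ".free_atp", equation = free_atp_equation,
                      lb = 0, ub = 1000, evidence = "spontaneous", add_mets = FALSE)
  }
  fx <- fba(m, stats::setNames(1, product), maximize = TRUE)
  if (!identical(fx$status, "optimal") || fx$objective_value <= 1e-9) {
    diag <- have_flux(m)
    return(list(yield = 0, flux = fx,
                diagnostic = diag[diag$reaction_id == product, , drop = FALSE]))
  }
  list(yield = fx$objective_value / uptake_rate, flux = fx, diagnostic = NULL)
}
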