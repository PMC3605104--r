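# Shared fixtures and independent brute-force oracles.

toys <- make_toy_models()

# Exhaustive free-lunch oracle: smallest reaction subset admitting a flux
# with sgn * S v >= 0 elementwise and sgn * total >= eps, exchanges closed,
# reactions outside the subset forced to zero. Enumerates all subsets, so it
# is only usable on fixtures (<= ~10 reactions) — which is the point.
brute_force_free_lunch <- function(model, direction = c("make", "consume"),
                                   eps = 1e-3, M = 1000) {
  direction <- match.arg(direction)
  sgn <- if (direction == "make") 1 else -1
  n <- nrow(model$rxns)
  S <- as.matrix(model$S)
  lb0 <- pmax(model$rxns$lb, -M)
  ub0 <- pmin(model$rxns$ub, M)
  exch <- is_exchange(model)
  lb0[exch] <- 0
  ub0[exch] <- 0
  feasible <- function(subset) {
    lb <- lb0; ub <- ub0
    off <- setdiff(seq_len(n), subset)
    lb[off] <- 0; ub[off] <- 0
    A <- rbind(sgn * S, sgn * colSums(S))
    sol <- solve_lp(numeric(n), A, c(rep(">=", nrow(S)), ">="),
                    c(numeric(nrow(S)), eps), lb, ub)
    identical(sol$status, "optimal")
  }
  for (k in 0:n) {
    for (subset in utils::combn(n, k, simplify = FALSE)) {
      if (feasible(subset)) {
        return(list(size = k, reactions = sort(model$rxns$id[subset])))
      }
    }
  }
  list(size = NA_integer_, reactions = NULL)
}

# Exhaustive gap-filling oracle over all candidate subsets: smallest subset
# of template reactions making every target metabolite producible.
brute_force_fill <- function(model, template, targets, eps = 1e-3) {
  n <- nrow(template$rxns)
  best <- NULL
  for (k in 0:n) {
    for (subset in utils::combn(n, k, simplify = FALSE)) {
      m <- model
      ok <- TRUE
      for (j in subset) {
        rid <- template$rxns$id[j]
        col <- template$S[, rid]
        nz <- which(col != 0)
        m <- tryCatch(
          add_reaction(m, paste0("cand_", rid),
                       stoich = stats::setNames(col[nz], template$mets$id[nz]),
                       lb = template$rxns$lb[j], ub = template$rxns$ub[j],
                       exchange = template$rxns$exchange[j]),
          error = function(e) NULL)
        if (is.null(m)) { ok <- FALSE; break }
      }
      if (!ok) next
      prod <- can_produce(m, targets)
      if (all(prod)) return(list(size = k, reactions = sort(template$rxns$id[subset])))
    }
  }
  list(size = NA_integer_, reactions = NULL)
}

# FIX4 exhaustive localization oracle. The chain structure makes the minimal
# transport count explicit: one transport per interior metabolite whose
# producing and consuming reactions sit in different compartments.
fix4_exhaustive_optimum <- function(transport_cost = 0.1) {
  sc <- fix4_localization_scores()
  genes <- rownames(sc)
  comps <- colnames(sc)
  best <- list(fitness = -Inf)
  grid <- expand.grid(rep(list(comps), 4), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    a <- stats::setNames(as.character(grid[i, ]), genes)
    transports <- sum(a[c("g1", "g2", "g3")] != a[c("g2", "g3", "g4")])
    fit <- sum(sc[cbind(genes, a)]) - transport_cost * transports
    if (fit > best$fitness) best <- list(fitness = fit, assignment = a,
                                         transports = transports)
  }
  best
}

make_task_table <- function(description, inputs, outputs, expected, bounds = NA) {
  data.frame(description = description, inputs = inputs, outputs = outputs,
             expected = expected, bounds = bounds, stringsAsFactors = FALSE)
}
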