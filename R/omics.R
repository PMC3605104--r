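# Transcriptome integration: quadratic exchange fitting, uniform sampling
# of the steady-state flux polytope, detection of transcriptionally
# regulated reactions across two conditions, and Reporter Metabolites.

#' Fit exchange fluxes to measured rates
#'
#' Solves `min sum_i ((v_i - m_i) / sigma_i)^2` subject to `S v = 0` and the
#' model bounds, then narrows the measured exchange bounds to the fitted
#' values +- `tolerance` so downstream sampling explores the measured
#' condition. Measurements with infinite (or absent) uncertainty carry no
#' weight and their bounds are left untouched. Jointly infeasible
#' measurements simply yield the least-squares compromise, visible in the
#' residuals.
#'
#' @param model a [gem_model].
#' @param measurements data.frame with `rxn`, `value`, optional `sigma`
#'   (default 1).
#' @param tolerance half-width of the new bounds around fitted values.
#' @return list with `model` (bounds narrowed), `fitted` (named), `residuals`
#'   (named, value - fitted), `sse` (weighted).
#' @export
fit_exchange_fluxes <- function(model, measurements, tolerance = 1e-6) {
  stopifnot(all(c("rxn", "value") %in% names(measurements)))
  bad <- setdiff(measurements$rxn, model$rxns$id)
  if (length(bad)) stop("unknown reaction(s): ", paste(bad, collapse = ", "))
  sigma <- if (is.null(measurements$sigma)) rep(1, nrow(measurements)) else measurements$sigma
  use <- is.finite(sigma) & sigma < 1e6
  n <- n_rxns(model)
  w <- numeric(n)
  tgt <- numeric(n)
  idx <- match(measurements$rxn[use], model$rxns$id)
  w[idx] <- 1 / sigma[use]^2
  tgt[idx] <- measurements$value[use]
  D <- diag(pmax(w, 1e-8))  # ridge keeps the QP strictly convex
  S <- as.matrix(model$S)
  Amat <- cbind(t(S), diag(n), -diag(n))
  bvec <- c(numeric(nrow(S)), model$rxns$lb, -model$rxns$ub)
  sol <- quadprog::solve.QP(Dmat = D, dvec = w * tgt, Amat = Amat, bvec = bvec,
                            meq = nrow(S))
  v <- stats::setNames(sol$solution, model$rxns$id)
  fitted <- v[measurements$rxn]
  resid <- measurements$value - fitted
  out <- model
  for (k in which(use)) {
    rid <- measurements$rxn[k]
    out <- set_bounds(out, rid, lb = fitted[[k]] - tolerance,
                      ub = fitted[[k]] + tolerance)
  }
  list(model = out, fitted = fitted,
       residuals = stats::setNames(resid, measurements$rxn),
       sse = sum((resid[use] / sigma[use])^2))
}

#' Uniformly sample the steady-state flux polytope
#'
#' Hit-and-run sampling of \{v : S v = 0, lb <= v <= ub\}: fluxes are
#' parameterized on an orthonormal null-space basis of S, a strictly
#' interior start point is found by maximizing the minimal slack to the
#' bounds, and each step picks an isotropic random direction and jumps to a
#' uniform point on the feasible chord. If the polytope has empty interior
#' (an equality-constrained point) a degenerate single-point set is
#' returned and flagged.
#'
#' @param model a [gem_model] with a bounded flux box.
#' @param n_samples samples to return.
#' @param seed RNG seed (sampling is reproducible under it).
#' @param warmup burn-in steps discarded.
#' @param thin keep every `thin`-th step.
#' @param condition label stored with the set.
#' @return object of class `flux_samples`: `samples`
#'   (n_samples x n_reactions), `mean`, `sd`, `n_samples`, `condition`,
#'   `degenerate`, `seed`.
#' @export
sample_flux_space <- function(model, n_samples = 5000, seed = 1, warmup = 1000,
                              thin = 10, condition = "condition") {
  lb <- model$rxns$lb
  ub <- model$rxns$ub
  S <- as.matrix(model$S)
  n <- ncol(S)
  sv <- svd(rbind(S, 0), nu = 0, nv = n)
  rank <- sum(sv$d > 1e-9 * max(sv$d, 1))
  N <- sv$v[, seq_len(n) > rank, drop = FALSE]
  dim_ns <- ncol(N)
  wrap <- function(samples, degenerate) {
    colnames(samples) <- model$rxns$id
    structure(list(samples = samples, mean = colMeans(samples),
                   sd = apply(samples, 2, stats::sd), n_samples = nrow(samples),
                   condition = condition, degenerate = degenerate, seed = seed),
              class = "flux_samples")
  }
  feasible_point <- function(slack = TRUE) {
    # maximize t : lb + t <= N z <= ub - t (z box-bounded large)
    zbox <- sqrt(n) * max(abs(c(lb, ub)), 1)
    obj <- c(numeric(dim_ns), 1)
    A <- rbind(cbind(N, 1), cbind(-N, 1))
    sense <- rep("<=", 2 * n)
    rhs <- c(ub, -lb)
    sol <- solve_lp(obj, A, sense, rhs,
                    lb = c(rep(-zbox, dim_ns), 0),
                    ub = c(rep(zbox, dim_ns), max(ub - lb) / 2 + 1),
                    maximize = TRUE)
    sol
  }
  if (dim_ns == 0L) {
    return(wrap(matrix(numeric(n), 1, n), degenerate = TRUE))
  }
  start <- feasible_point()
  if (!identical(start$status, "optimal")) {
    stop("flux polytope is empty: bounds are jointly infeasible")
  }
  z0 <- start$x[seq_len(dim_ns)]
  if (start$objval <= 1e-9) {
    return(wrap(matrix(as.numeric(N %*% z0), 1, n, byrow = TRUE), degenerate = TRUE))
  }
  set.seed(seed)
  z <- z0
  out <- matrix(NA_real_, n_samples, n)
  kept <- 0L
  total_steps <- warmup + n_samples * thin
  for (step in seq_len(total_steps)) {
    d <- stats::rnorm(dim_ns)
    d <- d / sqrt(sum(d^2))
    nd <- as.numeric(N %*% d)
    v <- as.numeric(N %*% z)
    alo <- -Inf; ahi <- Inf
    pos <- nd > 1e-12
    neg <- nd < -1e-12
    if (any(pos)) {
      ahi <- min(ahi, min((ub[pos] - v[pos]) / nd[pos]))
      alo <- max(alo, max((lb[pos] - v[pos]) / nd[pos]))
    }
    if (any(neg)) {
      ahi <- min(ahi, min((lb[neg] - v[neg]) / nd[neg]))
      alo <- max(alo, max((ub[neg] - v[neg]) / nd[neg]))
    }
    if (!is.finite(alo) || !is.finite(ahi) || ahi < alo) next
    z <- z + stats::runif(1, alo, ahi) * d
    if (step > warmup && (step - warmup) %% thin == 0L) {
      kept <- kept + 1L
      out[kept, ] <- as.numeric(N %*% z)
      if (kept == n_samples) break
    }
  }
  wrap(out[seq_len(kept), , drop = FALSE], degenerate = FALSE)
}

#' @export
print.flux_samples <- function(x, ...) {
  cat("Flux sample set [", x$condition, "]: ", x$n_samples, " samples x ",
      length(x$mean), " reactions", if (x$degenerate) " (degenerate)", "\n", sep = "")
  invisible(x)
}

#' Transcriptionally regulated reactions between two conditions
#'
#' A reaction is called regulated when both layers agree: its sampled flux
#' is significantly higher in condition B than in A (one-sided rank-sum
#' test on the two sample sets, p < `flux_p`) and at least one associated
#' gene is significantly up-regulated (p < `expr_p`, positive direction).
#' Reactions without gene associations cannot be transcriptionally
#' regulated and are excluded. Results are ranked by the combined
#' significance (Fisher's method over the flux p-value and the best gene
#' p-value).
#'
#' @param samples_a,samples_b `flux_samples` over the same reaction set.
#' @param model the [gem_model] (for gene associations).
#' @param expression data.frame with `gene`, `p`, `direction` (sign).
#' @param flux_p,expr_p significance thresholds (defaults 0.05 / 0.005).
#' @return data.frame ranked by `score`: `reaction_id`, `flux_p`,
#'   `best_gene`, `gene_p`, `called`.
#' @export
regulated_reactions <- function(samples_a, samples_b, model, expression,
                                flux_p = 0.05, expr_p = 0.005) {
  stopifnot(identical(colnames(samples_a$samples), colnames(samples_b$samples)))
  rxns <- colnames(samples_a$samples)
  ep <- stats::setNames(expression$p, expression$gene)
  ed <- stats::setNames(expression$direction, expression$gene)
  rows <- lapply(rxns, function(rid) {
    genes <- gpr_genes(model$gpr[[rid]])
    if (length(genes) == 0L) return(NULL)
    a <- samples_a$samples[, rid]
    b <- samples_b$samples[, rid]
    pf <- if (stats::sd(c(a, b)) < 1e-12) 1 else {
      suppressWarnings(stats::wilcox.test(b, a, alternative = "greater")$p.value)
    }
    up <- genes[!is.na(ep[genes]) & ep[genes] < expr_p & ed[genes] > 0]
    gp <- suppressWarnings(min(ep[genes][ed[genes] > 0], na.rm = TRUE))
    if (!is.finite(gp)) gp <- 1
    data.frame(reaction_id = rid, flux_p = pf,
               best_gene = if (length(up)) up[which.min(ep[up])] else NA_character_,
               gene_p = gp,
               called = pf < flux_p && length(up) > 0,
               score = -2 * (log(max(pf, 1e-300)) + log(max(gp, 1e-300))),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(reaction_id = character(), flux_p = numeric(),
                      best_gene = character(), gene_p = numeric(),
                      called = logical(), score = numeric()))
  }
  out[order(-out$score), , drop = FALSE]
}

#' Reporter Metabolite scores
#'
#' Scores each metabolite by the aggregated transcriptional change of its
#' neighboring genes (the genes associated with reactions that touch it):
#' `Z_met = (1/sqrt(k)) * sum_g qnorm(1 - p_g)` over the k neighbor genes,
#' corrected for neighborhood size by the mean and standard deviation of
#' the same statistic over `n_background` random k-gene sets, so corrected
#' scores are standard normal under the null. Metabolites with no neighbor
#' genes are excluded.
#'
#' @param model a [gem_model], or a named list metabolite -> gene vector
#'   giving the neighborhoods directly.
#' @param expression data.frame with `gene`, `p`.
#' @param n_background background draws per distinct neighborhood size.
#' @param seed RNG seed.
#' @return data.frame sorted by descending `corrected_z`: `metabolite`,
#'   `z`, `corrected_z`, `n_neighbor_genes`, `p_value`.
#' @export
reporter_metabolites <- function(model, expression, n_background = 1000, seed = 1) {
  if (inherits(model, "gem_model")) {
    neighbors <- lapply(model$mets$id, function(met) {
      js <- which(model$S[met, ] != 0)
      sort(unique(unlist(lapply(model$rxns$id[js], function(r) gpr_genes(model$gpr[[r]])))))
    })
    names(neighbors) <- model$mets$id
  } else {
    neighbors <- model
  }
  p <- pmin(pmax(expression$p, 1e-15), 1 - 1e-15)
  zg <- stats::setNames(stats::qnorm(1 - p), expression$gene)
  neighbors <- lapply(neighbors, function(g) intersect(g, names(zg)))
  k <- lengths(neighbors)
  neighbors <- neighbors[k > 0]
  k <- k[k > 0]
  if (length(neighbors) == 0L) {
    return(data.frame(metabolite = character(), z = numeric(),
                      corrected_z = numeric(), n_neighbor_genes = integer(),
                      p_value = numeric()))
  }
  z <- vapply(neighbors, function(g) sum(zg[g]) / sqrt(length(g)), numeric(1))
  set.seed(seed)
  bg <- lapply(sort(unique(k)), function(kk) {
    draws <- vapply(seq_len(n_background), function(i) {
      sum(zg[sample.int(length(zg), kk)]) / sqrt(kk)
    }, numeric(1))
    c(mu = mean(draws), sd = stats::sd(draws))
  })
  names(bg) <- as.character(sort(unique(k)))
  cz <- vapply(seq_along(z), function(i) {
    b <- bg[[as.character(k[i])]]
    (z[i] - b[["mu"]]) / b[["sd"]]
  }, numeric(1))
  out <- data.frame(metabolite = names(neighbors), z = unname(z),
                    corrected_z = cz, n_neighbor_genes = as.integer(k),
                    p_value = 1 - stats::pnorm(cz), stringsAsFactors = FALSE)
  out[order(-out$corrected_z), , drop = FALSE]
}
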