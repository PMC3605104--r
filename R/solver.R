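# Dense two-phase revised simplex + branch-and-bound.
#
# No LP/MILP solver package is available in the target library, so the
# package carries its own: a bounded-box LP is rewritten into standard form
# (shift to lower bounds, slack/surplus columns for inequality rows, one
# upper-bound row per variable), solved by a textbook two-phase simplex with
# Bland's rule (anti-cycling, guaranteed termination), re-factorizing the
# basis at every pivot. That is O(iterations * m^3) — entirely fine for the
# problem sizes this package targets (tens to a few hundred rows) and far
# more robust than a hand-tuned tableau.
#
# All variables must have finite bounds; flux variables always do (default
# box +-1000), auxiliary variables are given explicit boxes by callers.

SIMPLEX_TOL <- 1e-9

simplex_core <- function(cost, A, b, basis, max_iter = 20000L) {
  m <- nrow(A); n <- ncol(A)
  for (iter in seq_len(max_iter)) {
    B <- A[, basis, drop = FALSE]
    xB <- tryCatch(solve(B, b), error = function(e) NULL)
    if (is.null(xB)) return(list(status = "singular"))
    y <- solve(t(B), cost[basis])
    rc <- cost - as.numeric(crossprod(A, y))
    rc[basis] <- 0
    cand <- which(rc < -SIMPLEX_TOL)
    if (length(cand) == 0L) {
      x <- numeric(n); x[basis] <- xB
      return(list(status = "optimal", x = x, basis = basis, y = as.numeric(y)))
    }
    e <- cand[1]  # Bland: smallest index
    w <- as.numeric(solve(B, A[, e]))
    pos <- which(w > SIMPLEX_TOL)
    if (length(pos) == 0L) return(list(status = "unbounded", entering = e))
    ratios <- xB[pos] / w[pos]
    rmin <- min(ratios)
    ties <- pos[ratios <= rmin + SIMPLEX_TOL]
    leave <- ties[which.min(basis[ties])]  # Bland tie-break
    basis[leave] <- e
  }
  list(status = "iteration_limit")
}

#' Solve a linear program
#'
#' Solves `max/min obj' x` subject to `A x (sense) rhs` and box bounds
#' `lb <= x <= ub` (all bounds must be finite). Returns primal solution and
#' row duals; `duals[i]` is d(objective)/d(rhs[i]) in the orientation asked
#' for, so for a maximization a positive dual means relaxing that row
#' upward helps.
#'
#' @param obj objective coefficients.
#' @param A constraint matrix (dense or Matrix; may have 0 rows).
#' @param sense character vector of "=", "<=", ">=" per row.
#' @param rhs right-hand sides.
#' @param lb,ub variable bounds (finite).
#' @param maximize logical.
#' @return list with `status` ("optimal", "infeasible", "unbounded"), `x`,
#'   `objval`, `duals`.
#' @export
solve_lp <- function(obj, A = NULL, sense = NULL, rhs = NULL,
                     lb, ub, maximize = FALSE) {
  n <- length(obj)
  if (is.null(A)) { A <- matrix(0, 0, n); sense <- character(); rhs <- numeric() }
  A <- as.matrix(A)
  m <- nrow(A)
  stopifnot(length(lb) == n, length(ub) == n, length(sense) == m, length(rhs) == m)
  if (any(!is.finite(lb)) || any(!is.finite(ub))) stop("solve_lp needs finite variable bounds")
  if (any(lb > ub + SIMPLEX_TOL)) {
    return(list(status = "infeasible", x = NULL, objval = NA_real_, duals = NULL))
  }
  cost0 <- if (maximize) -obj else obj
  # shift: x = lb + xs, 0 <= xs <= r
  r <- ub - lb
  b1 <- rhs - as.numeric(A %*% lb)
  # columns: xs (n), slacks (one per inequality row), ub-slacks (one per var with r > 0)
  ineq <- which(sense != "=")
  nslack <- length(ineq)
  ubv <- seq_len(n)  # every variable, including fixed ones (r = 0)
  nub <- length(ubv)
  M <- m + nub
  N <- n + nslack + nub
  Afull <- matrix(0, M, N)
  if (m > 0) Afull[seq_len(m), seq_len(n)] <- A
  if (nslack > 0) {
    for (k in seq_along(ineq)) {
      Afull[ineq[k], n + k] <- if (sense[ineq[k]] == "<=") 1 else -1
    }
  }
  bfull <- c(b1, r[ubv])
  for (k in seq_len(nub)) {
    Afull[m + k, ubv[k]] <- 1
    Afull[m + k, n + nslack + k] <- 1
  }
  cfull <- c(cost0, numeric(nslack + nub))
  # make rhs non-negative
  neg <- which(bfull < 0)
  if (length(neg)) { Afull[neg, ] <- -Afull[neg, ]; bfull[neg] <- -bfull[neg] }
  # Phase 1
  Aart <- cbind(Afull, diag(M))
  cart <- c(numeric(N), rep(1, M))
  basis <- N + seq_len(M)
  r1 <- simplex_core(cart, Aart, bfull, basis)
  if (!identical(r1$status, "optimal")) {
    return(list(status = "infeasible", x = NULL, objval = NA_real_, duals = NULL))
  }
  if (sum(cart[r1$basis] * r1$x[r1$basis]) > 1e-7) {
    return(list(status = "infeasible", x = NULL, objval = NA_real_, duals = NULL))
  }
  basis <- r1$basis
  drop_rows <- integer()
  for (i in seq_along(basis)) {
    if (basis[i] > N) {
      # pivot artificial out, or mark its row redundant
      B <- Aart[, basis, drop = FALSE]
      repl <- NA_integer_
      for (j in seq_len(N)) {
        if (j %in% basis) next
        wj <- solve(B, Aart[, j])
        if (abs(wj[i]) > 1e-7) { repl <- j; break }
      }
      if (is.na(repl)) drop_rows <- c(drop_rows, i) else basis[i] <- repl
    }
  }
  if (length(drop_rows)) {
    keep <- setdiff(seq_len(M), drop_rows)
    Afull <- Afull[keep, , drop = FALSE]
    bfull <- bfull[keep]
    basis <- basis[keep]
    row_keep <- keep
  } else row_keep <- seq_len(M)
  # Phase 2
  r2 <- simplex_core(cfull, Afull, bfull, basis)
  if (identical(r2$status, "unbounded")) {
    return(list(status = "unbounded", x = NULL, objval = NA_real_, duals = NULL))
  }
  if (!identical(r2$status, "optimal")) {
    return(list(status = "infeasible", x = NULL, objval = NA_real_, duals = NULL))
  }
  xs <- r2$x[seq_len(n)]
  x <- lb + xs
  objval <- sum(obj * x)
  # duals for original rows: account for row negation and min/max orientation
  yfull <- numeric(M)
  yfull[row_keep] <- r2$y
  sgn <- rep(1, M)
  sgn[neg] <- -1
  y <- (yfull * sgn)[seq_len(m)]
  if (maximize) y <- -y
  list(status = "optimal", x = x, objval = objval, duals = y)
}

#' Solve a mixed-integer linear program by branch and bound
#'
#' Same interface as [solve_lp()] plus `int_vars`, the indices of variables
#' required integral (in practice binary indicator variables of the gap
#' MILPs). Depth-first branch and bound on the most fractional variable,
#' with bound pruning; when `obj_integral` is TRUE the relaxation bound is
#' rounded up (cardinality objectives), which prunes much harder.
#'
#' @inheritParams solve_lp
#' @param int_vars integer indices of integral variables.
#' @param obj_integral TRUE when the objective is provably integral at
#'   integer-feasible points.
#' @param node_limit safety cap on explored nodes.
#' @return list with `status`, `x`, `objval`.
#' @export
solve_milp <- function(obj, A = NULL, sense = NULL, rhs = NULL, lb, ub,
                       int_vars = integer(), maximize = FALSE,
                       obj_integral = FALSE, node_limit = 200000L) {
  best <- NULL
  best_obj <- if (maximize) -Inf else Inf
  stack <- list(list(lb = lb, ub = ub))
  nodes <- 0L
  tol_int <- 1e-6
  better <- function(a, b) if (maximize) a > b + 1e-9 else a < b - 1e-9
  while (length(stack) > 0L) {
    nodes <- nodes + 1L
    if (nodes > node_limit) return(list(status = "node_limit", x = best, objval = best_obj))
    nd <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    rel <- solve_lp(obj, A, sense, rhs, nd$lb, nd$ub, maximize = maximize)
    if (!identical(rel$status, "optimal")) next
    bound <- rel$objval
    if (obj_integral) {
      bound <- if (maximize) floor(bound + 1e-6) else ceiling(bound - 1e-6)
    }
    if (!is.null(best) && !better(bound, best_obj)) next
    frac <- abs(rel$x[int_vars] - round(rel$x[int_vars]))
    if (length(int_vars) == 0L || max(frac) <= tol_int) {
      # Re-solve with the integers pinned at their rounded values: a
      # near-integral y combined with a big-M row can admit O(M * tol)
      # slack, so "looks integral" is not "is feasible when rounded".
      if (length(int_vars)) {
        lbf <- nd$lb; ubf <- nd$ub
        lbf[int_vars] <- ubf[int_vars] <- round(rel$x[int_vars])
        fix <- solve_lp(obj, A, sense, rhs, lbf, ubf, maximize = maximize)
        if (identical(fix$status, "optimal")) {
          if (is.null(best) || better(fix$objval, best_obj)) {
            best <- fix$x
            best_obj <- fix$objval
          }
          next
        }
        # rounding infeasible: branch on the most displaced integer
      } else {
        if (is.null(best) || better(rel$objval, best_obj)) {
          best <- rel$x
          best_obj <- rel$objval
        }
        next
      }
    }
    bv <- int_vars[which.max(frac)]
    xf <- rel$x[bv]
    lo <- nd; lo$ub[bv] <- floor(xf)
    hi <- nd; hi$lb[bv] <- ceiling(xf)
    # explore the rounding nearer the relaxation first
    if (xf - floor(xf) > 0.5) stack <- c(stack, list(lo), list(hi))
    else stack <- c(stack, list(hi), list(lo))
  }
  if (is.null(best)) list(status = "infeasible", x = NULL, objval = NA_real_)
  else list(status = "optimal", x = best, objval = best_obj)
}
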