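# FBA, duals, MoMA, deletions, tasks, parameter fitting, cycle blocking.

test_that("FBA solves the hand LP on FIX5 and respects closed exchanges", {
  fx <- fba(toys$FIX5)
  expect_equal(fx$status, "optimal")
  expect_equal(fx$objective_value, 2)          # 1 glc -> 2 X -> 2 P
  expect_equal(unname(fx$fluxes["r1"]), 1)
  closed <- set_bounds(toys$FIX5, "EX_S", lb = 0, ub = 0)
  expect_equal(fba(closed)$objective_value, 0)
  expect_error(fba(toys$FIX1), "objective")
})

test_that("shadow prices: hand duality on FIX5 and finite-difference match", {
  fx <- fba(toys$FIX5)
  sp <- shadow_prices(fx, c("X[c]", "S[c]", "P[c]"))
  expect_equal(unname(sp["X[c]"]), 1)  # one extra X -> one extra P
  expect_equal(unname(sp["S[c]"]), 2)  # one extra S -> two extra P
  for (met in c("X[c]", "S[c]")) {
    expect_equal(unname(sp[met]), shadow_price_fd(toys$FIX5, met),
                 tolerance = 1e-6)
  }
  # a metabolite not constraining the optimum has marginal value 0; the
  # LP duals are degenerate there, so the finite-difference route is the
  # authoritative cross-check
  m <- set_objective(toys$FIX1, c(EX_C = 1))
  m <- set_bounds(m, "EX_A", lb = -1, ub = 0)
  expect_equal(shadow_price_fd(m, "D[c]"), 0)
})

test_that("primal-dual consistency across fixtures", {
  for (nm in c("FIX5", "FIX4")) {
    m <- toys[[nm]]
    if (length(m$objective) == 0) m <- set_objective(m, c(EX_E = 1))
    fx <- fba(m)
    expect_equal(fx$status, "optimal")
    v <- fx$fluxes[m$rxns$id]
    expect_lte(max(abs(as.matrix(m$S) %*% v)), 1e-6)
    expect_true(all(v >= m$rxns$lb - 1e-6 & v <= m$rxns$ub + 1e-6))
  }
})

test_that("MoMA: identity without perturbation, hand QP with bypass", {
  wt <- fba(toys$FIX5)
  same <- moma(toys$FIX5, wt)
  expect_equal(same$distance, 0, tolerance = 1e-6)
  expect_equal(same$fluxes[names(wt$fluxes)], wt$fluxes, tolerance = 1e-6)
  # delete r2, add bypass X -> P2 -> out; 1-D closed form: flows scale with
  # uptake u, minimize 2(1-u)^2 + 8 + 8u^2
  m <- add_metabolite(toys$FIX5, "P2", "c", formula = "C3H6O3")
  m <- add_reaction(m, "r2b", equation = "X[c] => P2[c]")
  m <- add_reaction(m, "EX_P2", stoich = c(`P2[c]` = -1), lb = 0, ub = 1000)
  m <- set_bounds(m, "r2", lb = 0, ub = 0)
  got <- moma(m, wt)
  expect_equal(got$status, "optimal")
  uhat <- stats::optimize(function(u) 2 * (1 - u)^2 + 8 + 8 * u^2, c(0, 1))
  expect_equal(got$distance, sqrt(uhat$objective), tolerance = 1e-5)
  expect_equal(unname(-got$fluxes["EX_S"]), uhat$minimum, tolerance = 1e-4)
  expect_gte(got$distance, 0)
})

test_that("deletion screens prune and report coupling", {
  # FIX5's only gene gates r1: deleting it kills the objective
  ds <- deletion_screen(toys$FIX5, max_k = 1)
  expect_equal(ds$objective_value, 0)
  # a gene absent from every GPR changes nothing
  m <- toys$FIX5
  m$genes <- c(m$genes, "ghost")
  ds2 <- deletion_screen(m, max_k = 1, genes = "ghost")
  expect_equal(ds2$objective_value, 2)
  # with an isozyme route, single deletions are viable and the double is
  # evaluated (not pruned) and lethal
  m2 <- add_reaction(toys$FIX5, "r1b", equation = "S[c] => 2 X[c]", gpr = "g2")
  ds3 <- deletion_screen(m2, max_k = 2)
  expect_true(all(ds3$objective_value[ds3$k == 1] > 0))
  expect_true("g1;g2" %in% ds3$genes)
  expect_equal(ds3$objective_value[ds3$genes == "g1;g2"], 0)
  # pruning: after a lethal singleton, its supersets are skipped
  ds3b <- deletion_screen(toys$FIX5, max_k = 2)   # g1 alone is lethal...
  expect_equal(nrow(ds3b), 1)                     # ...and FIX5 has one gene anyway
  # MoMA route gives a distribution, fluxes consistent
  ds4 <- deletion_screen(toys$FIX5, max_k = 1, method = "moma")
  expect_equal(nrow(ds4), 1)
  # coupling target reporting equals a direct two-stage LP
  ds5 <- deletion_screen(m2, max_k = 1, coupling_target = "EX_P")
  expect_true(all(is.finite(ds5$target_flux)))
})

test_that("check_tasks runs positive and negative controls independently", {
  tasks <- make_task_table(
    c("C from A", "C from nothing", "bogus metabolite"),
    c("A[c]:10", "", "Q9[c]:1"),
    c("C[c]:0.1", "C[c]:0.1", "C[c]:0.1"),
    c("feasible", "infeasible", "feasible"))
  res <- check_tasks(toys$FIX1, tasks)
  expect_equal(res$pass[1:2], c(TRUE, TRUE))
  expect_true(is.na(res$pass[3]))
  expect_match(res$error[3], "Q9")
  # bound overrides participate
  t2 <- make_task_table("C needs R2", "A[c]:10", "C[c]:0.1", "infeasible",
                        bounds = "R2:0:0")
  expect_true(check_tasks(toys$FIX1, t2)$pass)
})

test_that("maintenance fit recovers planted parameters", {
  exact <- fit_maintenance(make_chemostat())
  expect_equal(exact$m_atp, 4.14, tolerance = 1e-9)
  expect_equal(exact$k_xatp, 104, tolerance = 1e-9)
  expect_error(fit_maintenance(data.frame(mu = 0.1, q_atp = 15)), "two distinct")
  # model-derived q_atp: respiration toy, ATP drain as the maintenance proxy
  resp <- make_respiration_model(3.75)
  tab <- data.frame(mu = c(0.05, 0.1), EX_NADH = c(-1, -2))
  fit <- fit_maintenance(tab, model = resp, atp_rxn = "EX_ATP")
  expect_equal(unname(stats::coef(fit$fit)[2]) > 0, TRUE)
})

test_that("P/O fitting recovers a planted proton stoichiometry", {
  pd <- make_po_data(h_per_atp = 3.75)
  fit <- fit_po_ratio(make_respiration_model(2.5), pd, "SYN", "hout[c]",
                      "EX_NADH", "EX_ATP")
  expect_equal(fit$h_per_atp, 3.75, tolerance = 0.05 + 1e-9)
  expect_true(fit$identifiable)
  expect_false(fit$at_boundary)
  # grid excluding the truth warns about the boundary
  expect_warning(
    fit_po_ratio(make_respiration_model(2.5), pd, "SYN", "hout[c]",
                 "EX_NADH", "EX_ATP", grid = seq(1, 3, 0.25)),
    "boundary")
  # data carrying no P/O signal is flagged non-identifiable: with the
  # synthase disabled the predicted ATP rate is 0 whatever the stoichiometry
  flat <- data.frame(rate = c(-1, -2), q_atp = c(0, 0))
  m0 <- set_bounds(make_respiration_model(2.5), "SYN", lb = 0, ub = 0)
  expect_warning(f0 <- fit_po_ratio(m0, flat, "SYN", "hout[c]",
                                    "EX_NADH", "EX_ATP"), "identifiable")
  expect_false(f0$identifiable)
})

test_that("cofactor-cycle blocking kills the probe and only the probe", {
  probe <- "nadh[c] + nadp[c] <=> nad[c] + nadph[c]"
  res <- block_cofactor_cycles(toys$FIX6, probe)
  expect_equal(res$deleted, "r1")  # deterministic tie-break by id
  # post-condition: probe flux at most tolerance in the returned model
  m2 <- add_reaction(res$model, ".chk", equation = probe, lb = -1000, ub = 1000)
  carbon_ex <- "EX_etoh"
  m2 <- set_bounds(m2, carbon_ex, lb = 0)
  hi <- fba(m2, c(.chk = 1), maximize = TRUE)$objective_value
  lo <- fba(m2, c(.chk = 1), maximize = FALSE)$objective_value
  expect_lte(max(abs(c(hi, lo))), 1e-6)
  # cycle-free model returns unchanged
  m1 <- toys$FIX1
  m1 <- add_metabolite(m1, "nad", "c"); m1 <- add_metabolite(m1, "nadh", "c")
  m1 <- add_metabolite(m1, "nadp", "c"); m1 <- add_metabolite(m1, "nadph", "c")
  res1 <- block_cofactor_cycles(m1, probe)
  expect_equal(res1$deleted, character(0))
  expect_equal(nrow(res1$model$rxns), nrow(m1$rxns))
})

test_that("theoretical yield: FIX5 gives 2.0; relaxing uptake cannot hurt", {
  y <- theoretical_yield(toys$FIX5, "EX_S", "EX_P")
  expect_equal(y$yield, 2)
  # free-ATP probe on a model without ATP does nothing but must not break
  expect_equal(theoretical_yield(toys$FIX5, "EX_S", "EX_P",
                                 uptake_rate = 0.5)$yield, 2)
  # LP monotonicity: yield non-decreasing as medium opens
  m <- add_metabolite(toys$FIX5, "N", "c")
  m <- add_reaction(m, "EX_N", stoich = c(`N[c]` = -1), lb = 0, ub = 1000)
  m <- remove_reactions(m, "r2")
  m <- add_reaction(m, "r2", stoich = c(`X[c]` = -1, `N[c]` = -1, `P[c]` = 1),
                    lb = 0, ub = 1000)
  y_no_n <- theoretical_yield(m, "EX_S", "EX_P")
  y_with_n <- theoretical_yield(m, "EX_S", "EX_P", medium = "EX_N")
  expect_equal(y_no_n$yield, 0)
  expect_true(!is.null(y_no_n$diagnostic))
  expect_gte(y_with_n$yield, y_no_n$yield)
  expect_equal(y_with_n$yield, 2)
})

test_that("pfba removes alternate-optimum churn from reported fluxes", {
  # add a pointless internal loop: A <=> B parallel to R1
  m <- add_reaction(toys$FIX1, "R1b", equation = "A[c] <=> B[c]")
  m <- set_objective(m, c(EX_C = 1))
  m <- set_bounds(m, "EX_A", lb = -1, ub = 0)
  fx <- fba(m, pfba = TRUE)
  # loop flux is zeroed: R1 and R1b cannot both run in circles
  expect_lte(abs(fx$fluxes[["R1b"]]) + abs(fx$fluxes[["R1"]]), 1 + 1e-6)
})
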