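# Exchange fitting, flux-space sampling, regulated reactions, reporters.

test_that("exchange fitting: consistent, inconsistent, and infinite sigma", {
  # consistent: measurements on the FIX5 optimum fit with zero residual
  meas <- data.frame(rxn = c("EX_S", "EX_P"), value = c(-1, 2), sigma = c(1, 1))
  fit <- fit_exchange_fluxes(toys$FIX5, meas)
  expect_equal(unname(fit$residuals), c(0, 0), tolerance = 1e-6)
  expect_equal(fit$sse, 0, tolerance = 1e-9)
  b <- fit$model$rxns
  expect_equal(b$lb[b$id == "EX_P"], 2 - 1e-6, tolerance = 1e-6)
  # inconsistent with the carbon balance (EX_P must be -2 EX_S, uptake <= 1):
  # 1-D closed form min (1-u)^2 + (2u-3)^2 on u in [0,1] hits the bound u=1
  meas2 <- data.frame(rxn = c("EX_S", "EX_P"), value = c(-1, 3), sigma = c(1, 1))
  fit2 <- fit_exchange_fluxes(toys$FIX5, meas2)
  expect_equal(unname(fit2$fitted), c(-1, 2), tolerance = 1e-5)
  expect_equal(fit2$sse, 1, tolerance = 1e-5)
  # sigma -> Inf: measurement ignored, bound untouched
  meas3 <- data.frame(rxn = c("EX_S", "EX_P"), value = c(-1, 3), sigma = c(1, Inf))
  fit3 <- fit_exchange_fluxes(toys$FIX5, meas3)
  b3 <- fit3$model$rxns
  expect_equal(b3$ub[b3$id == "EX_P"], 1000)
  expect_error(fit_exchange_fluxes(toys$FIX5, data.frame(rxn = "zz", value = 1)),
               "unknown")
})

test_that("sampler stays inside the polytope and is seed-reproducible", {
  ss <- sample_flux_space(toys$FIX5, n_samples = 400, seed = 1)
  expect_false(ss$degenerate)
  S <- as.matrix(toys$FIX5$S)
  resid <- apply(ss$samples, 1, function(v) max(abs(S %*% v)))
  expect_lt(max(resid), 1e-8)
  lb <- toys$FIX5$rxns$lb; ub <- toys$FIX5$rxns$ub
  expect_true(all(t(ss$samples) >= lb - 1e-8 & t(ss$samples) <= ub + 1e-8))
  # the FIX5 polytope is one-dimensional: EX_P = -2 EX_S everywhere
  expect_equal(ss$samples[, "EX_P"], -2 * ss$samples[, "EX_S"], tolerance = 1e-8)
  # reproducibility
  ss2 <- sample_flux_space(toys$FIX5, n_samples = 400, seed = 1)
  expect_identical(ss$samples, ss2$samples)
  ss3 <- sample_flux_space(toys$FIX5, n_samples = 400, seed = 2)
  expect_false(identical(ss$samples, ss3$samples))
})

test_that("sampler marginals: free reversible reaction is symmetric about 0", {
  m <- gem_model("sym", c(c = "cytosol"))
  m <- add_metabolite(m, "A", "c")
  m <- add_reaction(m, "in", stoich = c(`A[c]` = 1), lb = -1, ub = 1,
                    exchange = TRUE)
  m <- add_reaction(m, "out", stoich = c(`A[c]` = -1), lb = -1, ub = 1,
                    exchange = TRUE)
  ss <- sample_flux_space(m, n_samples = 2000, seed = 4)
  se <- stats::sd(ss$samples[, "in"]) / sqrt(nrow(ss$samples))
  expect_lt(abs(mean(ss$samples[, "in"])), 3 * se + 1e-3)
})

test_that("degenerate polytopes collapse to a flagged single point", {
  m <- set_bounds(toys$FIX5, "EX_S", lb = -1, ub = -1)
  m <- set_bounds(m, "r1", lb = 1, ub = 1)
  m <- set_bounds(m, "r2", lb = 2, ub = 2)
  m <- set_bounds(m, "EX_P", lb = 2, ub = 2)
  ss <- sample_flux_space(m, n_samples = 100, seed = 1)
  expect_true(ss$degenerate)
  expect_equal(nrow(ss$samples), 1L)
})

test_that("regulated reactions need both flux shift and gene up-regulation", {
  fx <- make_expression_and_fluxes(planted = TRUE, seed = 1)
  sa <- sample_flux_space(fx$model_a, 300, seed = 11, warmup = 300, thin = 3,
                          condition = "A")
  sb <- sample_flux_space(fx$model_b, 300, seed = 12, warmup = 300, thin = 3,
                          condition = "B")
  rr <- regulated_reactions(sa, sb, fx$model_a, fx$expression)
  expect_true(rr$called[rr$reaction_id == "rA"])
  expect_equal(rr$reaction_id[1], "rA")  # top-ranked by combined score
  # same flux shift but the gene goes DOWN: the conjunction fails
  expr_down <- fx$expression
  expr_down$direction[expr_down$gene == "gA"] <- -1
  rr2 <- regulated_reactions(sa, sb, fx$model_a, expr_down)
  expect_false(rr2$called[rr2$reaction_id == "rA"])
  # reactions without genes are excluded entirely
  expect_false(any(grepl("^EX_", rr$reaction_id)))
})

test_that("reporter scores: planted signal tops the list, weak gene is null", {
  neighbors <- list(hot = c("h1", "h2", "h3"), cold1 = c("n1", "n2", "n3"),
                    cold2 = c("n4", "n5", "n6"), lonely = "n7")
  expr <- data.frame(gene = c("h1", "h2", "h3", paste0("n", 1:7)),
                     p = c(1e-6, 1e-6, 1e-6, rep(0.5, 7)))
  rs <- reporter_metabolites(neighbors, expr, n_background = 2000, seed = 1)
  expect_equal(rs$metabolite[1], "hot")
  expect_lt(rs$p_value[1], 0.01)
  expect_equal(rs$z[rs$metabolite == "lonely"], 0, tolerance = 1e-9)
  # gene->reaction->metabolite neighborhoods derive from the model
  m <- toys$FIX5
  expr2 <- data.frame(gene = "g1", p = 0.01)
  rs2 <- reporter_metabolites(m, expr2, n_background = 500, seed = 1)
  expect_setequal(rs2$metabolite, c("S[c]", "X[c]"))  # r1 touches S and X
  expect_true(all(rs2$n_neighbor_genes == 1))
})

test_that("reporter background correction standardizes null scores", {
  rn <- make_reporter_null(n_mets = 400, n_genes = 600, seed = 2)
  rs <- reporter_metabolites(rn$neighbors, rn$expression,
                             n_background = 3000, seed = 3)
  expect_lt(abs(mean(rs$corrected_z)), 0.1)
  expect_lt(abs(stats::sd(rs$corrected_z) - 1), 0.1)
})
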