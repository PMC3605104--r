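# Deterministic fixture generators: small metabolic worlds with known
# analytic answers, synthetic chemostat / expression data, and the biomass
# composition table. Everything is a pure function of its parameters and
# seed, so tests need no stored data.

#' Toy model fixtures
#'
#' Builds the suite of small networks used throughout the package's tests
#' and examples:
#' \describe{
#'   \item{FIX1}{balanced linear chain A -> B -> C (-> D dead end) with an
#'     open A exchange and a C export; mass-conserving, so no free lunch.}
#'   \item{FIX2}{FIX1 plus the unbalanced duplication B -> 2B (a free
#'     lunch).}
#'   \item{FIX2R5}{FIX2 plus 2C -> C (a mass sink).}
#'   \item{FIX3}{chain with the B -> C step missing; `FIX3_template`
#'     supplies that step and a two-reaction bypass, so minimal gap filling
#'     has a strictly better and a strictly worse option.}
#'   \item{FIX4}{four-gene chain for localization (see
#'     [fix4_localization_scores()]); `FIX4_2C` is a hand-compartmentalized
#'     two-compartment version with one C transport.}
#'   \item{FIX5}{yield toy: S -> 2X -> 2P with substrate uptake capped at
#'     1, so the maximal product yield is exactly 2 mol/mol.}
#'   \item{FIX6}{paired NAD/NADP alcohol dehydrogenases forming a futile
#'     transhydrogenase cycle, for cofactor-cycle blocking.}
#' }
#' @return named list of [gem_model]s.
#' @export
make_toy_models <- function() {
  glc <- "C6H12O6"
  tri <- "C3H6O3"

  fix1 <- gem_model("FIX1", c(c = "cytosol"))
  for (m in c("A", "B", "C", "D")) fix1 <- add_metabolite(fix1, m, "c", formula = glc)
  fix1 <- add_reaction(fix1, "EX_A", stoich = c(`A[c]` = -1), lb = -1000, ub = 1000,
                       evidence = "spontaneous")
  fix1 <- add_reaction(fix1, "R1", equation = "A[c] => B[c]", gpr = "t1",
                       evidence = "orthology")
  fix1 <- add_reaction(fix1, "R2", equation = "B[c] => C[c]", gpr = "t2",
                       evidence = "orthology")
  fix1 <- add_reaction(fix1, "R3", equation = "C[c] => D[c]")
  fix1 <- add_reaction(fix1, "EX_C", stoich = c(`C[c]` = -1), lb = 0, ub = 1000,
                       evidence = "spontaneous")

  fix2 <- add_reaction(fix1, "R4", equation = "B[c] => 2 B[c]")
  fix2$id <- "FIX2"
  fix2r5 <- add_reaction(fix2, "R5", equation = "2 C[c] => C[c]")
  fix2r5$id <- "FIX2R5"

  fix3 <- gem_model("FIX3", c(c = "cytosol"))
  for (m in c("A", "B", "C")) fix3 <- add_metabolite(fix3, m, "c", formula = glc)
  fix3 <- add_reaction(fix3, "EX_A", stoich = c(`A[c]` = -1), lb = -1000, ub = 1000,
                       evidence = "spontaneous")
  fix3 <- add_reaction(fix3, "R1", equation = "A[c] => B[c]")
  fix3t <- gem_model("FIX3_template", c(c = "cytosol"))
  for (m in c("B", "C", "D")) fix3t <- add_metabolite(fix3t, m, "c", formula = glc)
  fix3t <- add_reaction(fix3t, "R2", equation = "B[c] => C[c]")
  fix3t <- add_reaction(fix3t, "R2a", equation = "B[c] => D[c]")
  fix3t <- add_reaction(fix3t, "R2b", equation = "D[c] => C[c]")

  fix4 <- gem_model("FIX4", c(c = "cytosol"))
  for (m in c("A", "B", "C", "D", "E")) fix4 <- add_metabolite(fix4, m, "c", formula = glc)
  fix4 <- add_reaction(fix4, "EX_A", stoich = c(`A[c]` = -1), lb = -1000, ub = 1000,
                       evidence = "spontaneous")
  fix4 <- add_reaction(fix4, "r1", equation = "A[c] => B[c]", gpr = "g1")
  fix4 <- add_reaction(fix4, "r2", equation = "B[c] => C[c]", gpr = "g2")
  fix4 <- add_reaction(fix4, "r3", equation = "C[c] => D[c]", gpr = "g3")
  fix4 <- add_reaction(fix4, "r4", equation = "D[c] => E[c]", gpr = "g4")
  fix4 <- add_reaction(fix4, "EX_E", stoich = c(`E[c]` = -1), lb = 0, ub = 1000,
                       evidence = "spontaneous")

  fix4c <- gem_model("FIX4_2C", c(c = "cytosol", m = "mitochondrion"))
  for (m in c("A", "B", "C")) fix4c <- add_metabolite(fix4c, m, "c", formula = glc)
  for (m in c("C", "D", "E")) fix4c <- add_metabolite(fix4c, m, "m", formula = glc)
  fix4c <- add_reaction(fix4c, "EX_A", stoich = c(`A[c]` = -1), lb = -1000, ub = 1000,
                        evidence = "spontaneous")
  fix4c <- add_reaction(fix4c, "r1", equation = "A[c] => B[c]", gpr = "g1")
  fix4c <- add_reaction(fix4c, "r2", equation = "B[c] => C[c]", gpr = "g2")
  fix4c <- add_reaction(fix4c, "T_C", equation = "C[c] <=> C[m]")
  fix4c <- add_reaction(fix4c, "r3", equation = "C[m] => D[m]", gpr = "g3")
  fix4c <- add_reaction(fix4c, "r4", equation = "D[m] => E[m]", gpr = "g4")
  fix4c <- add_reaction(fix4c, "EX_E", stoich = c(`E[m]` = -1), lb = 0, ub = 1000,
                        evidence = "spontaneous")

  fix5 <- gem_model("FIX5", c(c = "cytosol"))
  fix5 <- add_metabolite(fix5, "S", "c", formula = glc)
  fix5 <- add_metabolite(fix5, "X", "c", formula = tri)
  fix5 <- add_metabolite(fix5, "P", "c", formula = tri)
  fix5 <- add_reaction(fix5, "EX_S", stoich = c(`S[c]` = -1), lb = -1, ub = 0,
                       evidence = "spontaneous")
  fix5 <- add_reaction(fix5, "r1", equation = "S[c] => 2 X[c]", gpr = "g1")
  fix5 <- add_reaction(fix5, "r2", equation = "X[c] => P[c]")
  fix5 <- add_reaction(fix5, "EX_P", stoich = c(`P[c]` = -1), lb = 0, ub = 1000,
                       evidence = "spontaneous")
  fix5 <- set_objective(fix5, c(EX_P = 1))

  fix6 <- gem_model("FIX6", c(c = "cytosol"))
  fix6 <- add_metabolite(fix6, "etoh", "c", formula = "C2H6O")
  fix6 <- add_metabolite(fix6, "acd", "c", formula = "C2H4O")
  fix6 <- add_metabolite(fix6, "h", "c", formula = "H")
  fix6 <- add_metabolite(fix6, "nad", "c", formula = "C21H27N7O14P2")
  fix6 <- add_metabolite(fix6, "nadh", "c", formula = "C21H28N7O14P2")
  fix6 <- add_metabolite(fix6, "nadp", "c", formula = "C21H28N7O17P3")
  fix6 <- add_metabolite(fix6, "nadph", "c", formula = "C21H29N7O17P3")
  fix6 <- add_reaction(fix6, "EX_etoh", stoich = c(`etoh[c]` = -1), lb = -1000,
                       ub = 1000, evidence = "spontaneous")
  fix6 <- add_reaction(fix6, "r1",
                       equation = "etoh[c] + nad[c] => acd[c] + nadh[c] + h[c]",
                       gpr = "adh1")
  fix6 <- add_reaction(fix6, "r2",
                       equation = "acd[c] + nadph[c] + h[c] => etoh[c] + nadp[c]",
                       gpr = "adh2")

  list(FIX1 = fix1, FIX2 = fix2, FIX2R5 = fix2r5, FIX3 = fix3,
       FIX3_template = fix3t, FIX4 = fix4, FIX4_2C = fix4c, FIX5 = fix5,
       FIX6 = fix6)
}

#' Planted localization scores for FIX4
#'
#' Genes g1, g2 score 0.9 cytosolic / 0.1 mitochondrial and g3, g4 the
#' reverse, so the exhaustively verified optimum at transport cost 0.1 is
#' the split \{g1,g2 -> c; g3,g4 -> m\} with one C transport and fitness
#' 4 x 0.9 - 0.1 x 1 = 3.5.
#' @return matrix genes x compartments of normalized scores.
#' @export
fix4_localization_scores <- function() {
  sc <- rbind(c(0.9, 0.1), c(0.9, 0.1), c(0.1, 0.9), c(0.1, 0.9))
  dimnames(sc) <- list(c("g1", "g2", "g3", "g4"), c("c", "m"))
  sc
}

#' Synthetic glucose-limited chemostat series
#'
#' Emulates maintenance-ATP chemostat experiments: across dilution rates
#' `mu` (1/h) the network-supported ATP production follows
#' `q_ATP = m_atp + k_xatp * mu`, measured with relative Gaussian noise.
#' Defaults are the filamentous-fungus regime: dilution rates 0.025-0.2/h
#' (below the ~0.2/h maximal specific growth rate of industrial strains),
#' maintenance 4.14 mmol ATP/gDW/h and growth-associated cost 104 mmol
#' ATP/gDW.
#'
#' @param n_rates number of dilution rates.
#' @param m_atp,k_xatp planted maintenance parameters.
#' @param noise_sd relative measurement noise (0.05 = 5%).
#' @param mu dilution-rate grid (default evenly spaced 0.025-0.2).
#' @param seed RNG seed.
#' @return data.frame with `mu`, `q_atp` and (when `noise_sd > 0`) `sigma`.
#' @export
make_chemostat <- function(n_rates = 8, m_atp = 4.14, k_xatp = 104,
                           noise_sd = 0, mu = NULL, seed = 1) {
  if (is.null(mu)) mu <- seq(0.025, 0.2, length.out = n_rates)
  q_true <- m_atp + k_xatp * mu
  if (noise_sd > 0) {
    set.seed(seed)
    sigma <- noise_sd * q_true
    data.frame(mu = mu, q_atp = q_true + stats::rnorm(length(mu), 0, sigma),
               sigma = sigma)
  } else {
    data.frame(mu = mu, q_atp = q_true)
  }
}

#' Respiratory toy model for P/O fitting
#'
#' A minimal oxidative-phosphorylation cartoon: the electron transport
#' chain oxidizes NADH with O2 and pumps 10 protons; the ATP synthase makes
#' ATP from `h_per_atp` pumped protons. The maximal ATP rate per NADH is
#' therefore 10 / h_per_atp, which is what the grid search in
#' [fit_po_ratio()] inverts.
#'
#' @param h_per_atp planted synthase proton stoichiometry.
#' @return a [gem_model] with reactions `EX_NADH`, `EX_O2`, `ETC`, `SYN`,
#'   `EX_ATP`.
#' @export
make_respiration_model <- function(h_per_atp = 3.75) {
  m <- gem_model("RESP", c(c = "cytosol"))
  for (x in c("nadh", "nad", "o2", "h2o", "hout", "adp", "atp")) {
    m <- add_metabolite(m, x, "c")
  }
  m <- add_reaction(m, "EX_NADH", stoich = c(`nadh[c]` = -1), lb = -1000, ub = 0,
                    evidence = "spontaneous")
  m <- add_reaction(m, "EX_NAD", stoich = c(`nad[c]` = -1), lb = 0, ub = 1000,
                    evidence = "spontaneous")
  m <- add_reaction(m, "EX_O2", stoich = c(`o2[c]` = -1), lb = -1000, ub = 0,
                    evidence = "spontaneous")
  m <- add_reaction(m, "EX_H2O", stoich = c(`h2o[c]` = -1), lb = 0, ub = 1000,
                    evidence = "spontaneous")
  m <- add_reaction(m, "EX_ADP", stoich = c(`adp[c]` = -1), lb = -1000, ub = 0,
                    evidence = "spontaneous")
  m <- add_reaction(m, "ETC",
                    equation = "nadh[c] + 0.5 o2[c] => nad[c] + h2o[c] + 10 hout[c]")
  m <- add_reaction(m, "SYN",
                    stoich = c(`adp[c]` = -1, `hout[c]` = -h_per_atp, `atp[c]` = 1),
                    lb = 0, ub = 1000)
  # proton leak across the membrane (uncoupling): keeps the model feasible
  # when the synthase cannot run at the pumped rate
  m <- add_reaction(m, "LEAK", stoich = c(`hout[c]` = -1), lb = 0, ub = 1000,
                    exchange = TRUE)
  m <- add_reaction(m, "EX_ATP", stoich = c(`atp[c]` = -1), lb = 0, ub = 1000,
                    evidence = "spontaneous")
  m
}

#' Synthetic measured ATP rates for P/O fitting
#'
#' Runs [make_respiration_model()] at the planted stoichiometry over a set
#' of NADH feed rates and records the maximal ATP rate; noise-free by
#' default so the grid search must recover the planted value exactly (up to
#' grid resolution).
#'
#' @param h_per_atp planted value.
#' @param rates NADH uptake rates (negative, exchange convention).
#' @return data.frame with `rate` and `q_atp`.
#' @export
make_po_data <- function(h_per_atp = 3.75, rates = -(1:4)) {
  m <- make_respiration_model(h_per_atp)
  q <- vapply(rates, function(r) {
    mi <- set_bounds(m, "EX_NADH", lb = r, ub = r)
    fba(mi, c(EX_ATP = 1))$objective_value
  }, numeric(1))
  data.frame(rate = rates, q_atp = q)
}

#' Two-condition sampling/expression fixture
#'
#' A branched uptake network (S can go to P1 via `rA` or to P2 via `rB`)
#' in two conditions: in the planted case condition B caps the `rB` branch,
#' forcing sampled `rA` flux up, and gives rA's gene a strongly significant
#' up-regulation; null genes get uniform p-values. In the null case both
#' conditions are identical and all p-values uniform.
#'
#' @param planted TRUE for the shifted/regulated pair, FALSE for the null.
#' @param n_null_genes extra unassociated genes in the expression table.
#' @param seed RNG seed (expression p-values).
#' @return list with `model_a`, `model_b`, `expression` (gene, p,
#'   direction, log_fc), `planted` (reaction ids truly regulated).
#' @export
make_expression_and_fluxes <- function(planted = TRUE, n_null_genes = 8, seed = 1) {
  base <- gem_model("OMX", c(c = "cytosol"))
  for (m in c("S", "P1", "P2")) base <- add_metabolite(base, m, "c", formula = "C3H6O3")
  base <- add_reaction(base, "EX_S", stoich = c(`S[c]` = -1), lb = -1, ub = 0,
                       evidence = "spontaneous")
  base <- add_reaction(base, "rA", equation = "S[c] => P1[c]", gpr = "gA")
  base <- add_reaction(base, "rB", equation = "S[c] => P2[c]", gpr = "gB")
  base <- add_reaction(base, "EX_P1", stoich = c(`P1[c]` = -1), lb = 0, ub = 1000,
                       evidence = "spontaneous")
  base <- add_reaction(base, "EX_P2", stoich = c(`P2[c]` = -1), lb = 0, ub = 1000,
                       evidence = "spontaneous")
  model_b <- if (planted) set_bounds(base, "rB", ub = 0.15) else base
  set.seed(seed)
  genes <- c("gA", "gB", paste0("gn", seq_len(n_null_genes)))
  p <- stats::runif(length(genes))
  dirn <- sample(c(-1, 1), length(genes), replace = TRUE)
  if (planted) {
    p[1] <- 1e-4; dirn[1] <- 1     # gA up-regulated
    p[2] <- stats::runif(1, 0.3, 0.9)
  }
  expression <- data.frame(gene = genes, p = p, direction = dirn,
                           log_fc = dirn * abs(stats::rnorm(length(genes))),
                           stringsAsFactors = FALSE)
  list(model_a = base, model_b = model_b, expression = expression,
       planted = if (planted) "rA" else character())
}

#' Random bipartite neighborhood fixture for Reporter-Metabolite calibration
#'
#' Draws `n_mets` metabolite neighborhoods of 3-8 genes from a pool of
#' `n_genes` genes plus uniform p-values: the null world in which corrected
#' reporter scores must be standard normal.
#'
#' @param n_mets,n_genes sizes; @param seed RNG seed.
#' @return list with `neighbors` (named list met -> genes) and `expression`.
#' @export
make_reporter_null <- function(n_mets = 300, n_genes = 500, seed = 1) {
  set.seed(seed)
  genes <- paste0("g", seq_len(n_genes))
  neighbors <- lapply(seq_len(n_mets), function(i) {
    sample(genes, sample(3:8, 1))
  })
  names(neighbors) <- paste0("met", seq_len(n_mets))
  expression <- data.frame(gene = genes, p = stats::runif(n_genes),
                           direction = 1, stringsAsFactors = FALSE)
  list(neighbors = neighbors, expression = expression)
}

#' Biomass composition table
#'
#' The macromolecular biomass composition of an industrial penicillin
#' producer, in g per g dry weight: the drains the biomass pseudo-reaction
#' imposes. The printed total of the source table is 0.90 g/gDW, with 8%
#' of dry weight ash and the remaining 2% other soluble metabolites (note:
#' the printed top-level components sum to 0.92; the 0.02 discrepancy sits
#' in the soluble pool, whose printed subcomponents sum to 0.06).
#'
#' @return named numeric of top-level components, with attributes `total`
#'   (0.90) and `ash` (0.08).
#' @export
biomass_table <- function() {
  x <- c(protein = 0.45, rna = 0.08, dna = 0.01, lipids = 0.05,
         carbohydrates = 0.25, soluble_pool = 0.08)
  attr(x, "total") <- 0.90
  attr(x, "ash") <- 0.08
  x
}
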