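# Predictor parsing and annealed compartment assignment.

test_that("predictor output parsing normalizes and aliases", {
  f <- tempfile()
  writeLines(c("g1 mito 20, cyto 5",
               "g2 cyto: 9, mito: 1",
               "g3 cyto_mito 10"), f)
  sc <- parse_predictor_output(f, "wolfpsort", compartments = c("c", "m"),
                               aliases = c(mito = "m", cyto = "c",
                                           cyto_mito = "c,m"),
                               genes = c("g1", "g2", "g3", "g4"))
  expect_equal(unname(sc["g1", ]), c(0.2, 0.8))
  expect_equal(unname(sc["g2", ]), c(0.9, 0.1))
  expect_equal(unname(sc["g3", ]), c(0.5, 0.5))  # split alias
  expect_equal(unname(sc["g4", ]), c(0.5, 0.5))  # absent gene: uniform
  expect_equal(unname(rowSums(sc)), rep(1, 4))
  # unknown label without alias errors, naming the label
  writeLines("g9 nucleus 3", f)
  expect_error(parse_predictor_output(f, "wolfpsort", c("c", "m")), "nucleus")
  # cello dialect
  f2 <- tempfile()
  writeLines(c("gene\tcompartment\tscore", "g1\tm\t3", "g1\tc\t1"), f2)
  sc2 <- parse_predictor_output(f2, "cello", c("c", "m"))
  expect_equal(unname(sc2["g1", ]), c(0.25, 0.75))
})

test_that("annealing reaches the exhaustively verified FIX4 optimum", {
  oracle <- fix4_exhaustive_optimum(0.1)
  expect_equal(oracle$fitness, 3.5)  # 4 x 0.9 - 0.1 x 1
  expect_equal(unname(oracle$assignment), c("c", "c", "m", "m"))
  sol <- predict_localization(toys$FIX4, fix4_localization_scores(), c("c", "m"),
                              anneal_config(seed = 1))
  expect_equal(sol$fitness, oracle$fitness)
  expect_equal(sol$assignment, oracle$assignment)
  expect_equal(nrow(sol$transports), 1L)
  expect_equal(sol$transports$met, "C")
  # reported fitness recomputes exactly from assignment + transports
  sc <- fix4_localization_scores()
  expect_equal(sol$fitness,
               sum(sc[cbind(names(sol$assignment), sol$assignment)]) -
                 0.1 * nrow(sol$transports))
})

test_that("annealing finds the optimum in >= 2 of 3 seeded runs", {
  oracle <- fix4_exhaustive_optimum(0.1)
  hits <- sum(vapply(1:3, function(s) {
    sol <- predict_localization(toys$FIX4, fix4_localization_scores(),
                                c("c", "m"), anneal_config(seed = s))
    abs(sol$fitness - oracle$fitness) < 1e-9
  }, logical(1)))
  expect_gte(hits, 2)
})

test_that("transport-cost limits: 0 gives per-gene argmax, large keeps one pot", {
  sc <- fix4_localization_scores()
  free <- predict_localization(toys$FIX4, sc, c("c", "m"),
                               anneal_config(transport_cost = 0, seed = 1))
  argmax <- colnames(sc)[apply(sc, 1, which.max)]
  expect_equal(unname(free$assignment), argmax)
  allin <- predict_localization(toys$FIX4, sc, c("c", "m"),
                                anneal_config(transport_cost = 1e6, seed = 1))
  expect_equal(length(unique(allin$assignment)), 1L)
  expect_equal(nrow(allin$transports), 0L)
})

test_that("optimal fitness is non-increasing in transport cost", {
  fits <- vapply(c(0, 0.1, 0.5, 1e6), function(tc) {
    fix4_exhaustive_optimum(tc)$fitness
  }, numeric(1))
  expect_true(all(diff(fits) <= 1e-12))
})

test_that("returned model satisfies the connectivity predicate", {
  sol <- predict_localization(toys$FIX4, fix4_localization_scores(), c("c", "m"),
                              anneal_config(seed = 1))
  m <- sol$model
  exch <- is_exchange(m)
  exch_mets <- unique(m$mets$base_id[Matrix::rowSums(
    abs(m$S[, exch, drop = FALSE])) > 0])
  for (i in seq_len(nrow(m$mets))) {
    if (m$mets$base_id[i] %in% exch_mets) next
    row <- m$S[i, ]
    js <- which(row != 0)
    rev <- m$rxns$lb[js] < 0
    produced <- any(row[js] > 0 | rev)
    consumed <- any(row[js] < 0 | rev)
    expect_true(produced && consumed, label = m$mets$id[i])
  }
  # isolated metabolites are impossible to connect and refused up front
  iso <- add_metabolite(toys$FIX4, "Z", "c")
  expect_error(predict_localization(iso, fix4_localization_scores(), c("c", "m")),
               "isolated")
})
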