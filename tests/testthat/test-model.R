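# Model container, formulas, GPRs, editing.

test_that("formula parsing handles Hill notation and generic tokens", {
  expect_equal(parse_formula("C6H12O6"), c(C = 6, H = 12, O = 6))
  expect_equal(parse_formula("H"), c(H = 1))
  expect_equal(parse_formula("C21H28N7O17P3"),
               c(C = 21, H = 28, N = 7, O = 17, P = 3))
  expect_null(parse_formula("RC2H4"))        # generic R group
  expect_null(parse_formula("(C6H10O5)n"))   # polymer
  expect_null(parse_formula("Xx12"))         # not an element
  expect_null(parse_formula(""))
  expect_null(parse_formula(NA_character_))
})

test_that("gene association parsing, formatting and evaluation", {
  a <- parse_gpr("(g1 and g2) or g3")
  expect_setequal(vapply(a, paste, character(1), collapse = "+"),
                  c("g1+g2", "g3"))
  expect_true(evaluate_gpr(a, "g1"))           # g3 survives
  expect_false(evaluate_gpr(a, c("g1", "g3")))
  expect_true(evaluate_gpr(list(), c("anything")))  # orphan reaction stays
  # distribution: a and (b or c) => {a,b} | {a,c}
  d <- parse_gpr("a and (b or c)")
  expect_setequal(vapply(d, paste, character(1), collapse = "+"),
                  c("a+b", "a+c"))
  # round trip
  expect_equal(parse_gpr(format_gpr(a)), a)
  expect_error(parse_gpr("g1 and"), "parse error")
  expect_error(parse_gpr("(g1 or g2"), "parse error")
})

test_that("equation parsing: coefficients, reversibility, both-sides merge", {
  pe <- parse_equation("2 A[c] + B[c] <=> C[m]")
  expect_equal(pe$stoich, c(`A[c]` = -2, `B[c]` = -1, `C[m]` = 1))
  expect_true(pe$reversible)
  expect_false(parse_equation("A[c] => B[c]")$reversible)
  # metabolite on both sides nets out but is remembered for exchange logic
  pe2 <- parse_equation("B[c] => 2 B[c]")
  expect_equal(pe2$stoich, c(`B[c]` = 1))
  expect_error(parse_equation("A[c] B[c]"), "arrow")
})

test_that("exchange status is an attribute, not a column property", {
  ex <- is_exchange(toys$FIX2)
  expect_true(ex[["EX_A"]])
  expect_true(ex[["EX_C"]])
  expect_false(ex[["R4"]])  # B => 2B nets to one metabolite but is internal
  expect_false(ex[["R1"]])
})

test_that("model editing: bounds, objective, removal, duplicates", {
  m <- toys$FIX1
  m2 <- set_bounds(m, "R1", lb = 0, ub = 5)
  expect_equal(m2$rxns$ub[m2$rxns$id == "R1"], 5)
  expect_error(set_bounds(m, "R1", lb = 10, ub = 5), "exceeds")
  m3 <- set_objective(m, c(EX_C = 1))
  expect_equal(m3$objective, c(EX_C = 1))
  expect_error(set_objective(m, c(nope = 1)), "unknown")
  expect_error(add_reaction(m, "R1", equation = "A[c] => B[c]"), "duplicate")
  m4 <- remove_reactions(m, "R3")
  expect_false("R3" %in% m4$rxns$id)
  expect_silent(validate_model(m4))
  expect_error(remove_metabolites(m, "A[c]"), "cascade")
  m5 <- remove_metabolites(m, "A[c]", cascade = TRUE)
  expect_false(any(c("EX_A", "R1") %in% m5$rxns$id))
  # edit_model dispatcher applies ops in order
  m6 <- edit_model(m, list(list(op = "set_bounds", rxn_ids = "R1", ub = 7),
                           list(op = "set_objective", objective = c(EX_C = 1))))
  expect_equal(m6$rxns$ub[m6$rxns$id == "R1"], 7)
  expect_equal(m6$objective, c(EX_C = 1))
})

test_that("merging compartments removes identity transports", {
  m <- toys$FIX4_2C
  expect_true("T_C" %in% m$rxns$id)
  merged <- merge_compartments(m, c("c", "m"), into = "c")
  expect_false("T_C" %in% merged$rxns$id)
  expect_equal(length(merged$compartments), 1L)
  expect_equal(sum(merged$mets$base_id == "C"), 1L)
  expect_silent(validate_model(merged))
  # chain still works end to end
  merged <- set_objective(merged, c(EX_E = 1))
  expect_equal(fba(merged)$objective_value, 1000)
})

test_that("elemental balance equals hand-computed signed sums", {
  bal <- elemental_balance(toys$FIX2)
  expect_equal(bal$status[bal$reaction_id == "R1"], "balanced")
  r4 <- bal[bal$reaction_id == "R4", ]
  expect_equal(r4$status, "unbalanced")
  expect_equal(r4$balance[[1]], c(C = 6, H = 12, O = 6))  # net +1 B per element
  expect_equal(bal$status[bal$reaction_id == "EX_A"], "unbalanced_by_design")
  # formula-less participant
  m <- add_metabolite(toys$FIX1, "Q", "c")  # no formula
  m <- add_reaction(m, "RQ", equation = "A[c] => Q[c]")
  expect_equal(elemental_balance(m, "RQ")$status, "unknown_composition")
  # hand check on every fixture: balance == S-weighted formula sums
  for (nm in c("FIX1", "FIX5", "FIX6")) {
    mod <- toys[[nm]]
    bal <- elemental_balance(mod)
    for (i in seq_len(nrow(bal))) {
      if (bal$status[i] == "unbalanced_by_design") next
      rid <- bal$reaction_id[i]
      col <- mod$S[, rid]
      nz <- which(col != 0)
      hand <- Reduce(`+`, lapply(nz, function(j) {
        f <- parse_formula(mod$mets$formula[j])
        all_el <- c("C", "H", "O", "N", "P", "S")
        v <- stats::setNames(numeric(6), all_el)
        v[names(f)] <- f * col[j]
        v
      }))
      expect_true(all(abs(hand) <= 1e-9) == (bal$status[i] == "balanced"),
                  label = paste(nm, rid))
    }
  }
})

test_that("validate_model catches broken invariants", {
  m <- toys$FIX1
  m$rxns$lb[1] <- 10; m$rxns$ub[1] <- 0
  expect_error(validate_model(m), "bound")
  m <- toys$FIX1
  m$genes <- character()  # GPR references now dangle
  expect_error(validate_model(m), "gene")
})
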