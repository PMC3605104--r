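# Gap-analysis MILP suite against brute-force enumeration.

test_that("make/consume_something equal brute force on all small fixtures", {
  for (nm in c("FIX1", "FIX2", "FIX2R5", "FIX3", "FIX5", "FIX6")) {
    model <- toys[[nm]]
    for (dir in c("make", "consume")) {
      oracle <- brute_force_free_lunch(model, dir)
      got <- if (dir == "make") make_something(model) else consume_something(model)
      if (is.na(oracle$size)) {
        expect_equal(got$solver_status, "infeasible", label = paste(nm, dir))
      } else {
        expect_equal(got$solver_status, "optimal", label = paste(nm, dir))
        expect_equal(got$objective_size, oracle$size, label = paste(nm, dir))
      }
    }
  }
})

test_that("free-lunch examples: FIX2 makes via R4, FIX2R5 consumes via R5", {
  expect_equal(make_something(toys$FIX2)$reaction_ids, "R4")
  expect_equal(consume_something(toys$FIX2R5)$reaction_ids, "R5")
  expect_equal(make_something(toys$FIX1)$solver_status, "infeasible")
  expect_equal(consume_something(toys$FIX1)$solver_status, "infeasible")
  # reversible duplication is found running in reverse
  m <- toys$FIX1
  m <- add_reaction(m, "Rrev", stoich = c(`B[c]` = -1), lb = -1000, ub = 1000,
                    exchange = FALSE)  # 2B <=> B written backwards: net -1 B
  got <- consume_something(m)
  expect_equal(got$reaction_ids, "Rrev")
  expect_equal(make_something(m)$reaction_ids, "Rrev")  # reverse direction
})

test_that("remove_bad_reactions strips unbalanced free lunches and stops", {
  rb <- remove_bad_reactions(toys$FIX2R5)
  expect_setequal(rb$removed, c("R4", "R5"))
  expect_equal(rb$unresolved, character(0))
  expect_equal(make_something(rb$model)$solver_status, "infeasible")
  expect_equal(consume_something(rb$model)$solver_status, "infeasible")
  # clean model: nothing removed
  rb1 <- remove_bad_reactions(toys$FIX1)
  expect_equal(rb1$removed, character(0))
  # a formula-less free lunch needs the explicit permission flag
  m <- toys$FIX1
  m <- add_metabolite(m, "U", "c")  # unknown composition
  m <- add_reaction(m, "RU1", equation = "A[c] => U[c]")
  m <- add_reaction(m, "RU2", equation = "U[c] => 2 U[c]")
  cautious <- remove_bad_reactions(m, allow_removing_unknown = FALSE)
  expect_true(length(cautious$unresolved) > 0)
  permissive <- remove_bad_reactions(m, allow_removing_unknown = TRUE)
  expect_true("RU2" %in% permissive$removed)
  expect_equal(make_something(permissive$model)$solver_status, "infeasible")
})

test_that("can_produce respects user-opened exchanges", {
  expect_true(all(can_produce(toys$FIX1)))        # EX_A open by default
  closed <- set_bounds(toys$FIX1, "EX_A", lb = 0, ub = 0)
  expect_false(any(can_produce(closed)))
  # graph-reachability oracle on the loop-free chain: producible iff
  # reachable from an open uptake
  reach <- c("A[c]", "B[c]", "C[c]", "D[c]")  # chain from A
  half <- set_bounds(toys$FIX1, "EX_A", lb = -1, ub = 0)
  expect_equal(names(which(can_produce(half))), reach)
  expect_error(can_produce(toys$FIX1, "nope[c]"), "unknown")
})

test_that("can_consume mirrors can_produce", {
  # with EX_C open for export, everything upstream of C is consumable
  cc <- can_consume(toys$FIX1)
  expect_true(cc[["A[c]"]])
  expect_true(cc[["C[c]"]])
  expect_false(cc[["D[c]"]])  # D has no consumer
})

test_that("check_production finds minimal enabling sets with unlock maps", {
  closed <- set_bounds(toys$FIX1, "EX_A", lb = 0, ub = 0)
  chk <- check_production(closed)
  expect_equal(chk$enabled, "A[c]")
  expect_setequal(chk$unlocks[["A[c]"]], c("B[c]", "C[c]", "D[c]"))
  # brute force over candidate subsets agrees on minimality
  np <- names(which(!can_produce(closed)))
  sizes <- vapply(seq_along(np), function(k) {
    any(vapply(utils::combn(np, k, simplify = FALSE), function(ss) {
      m <- closed
      for (met in ss) {
        m <- add_reaction(m, paste0("src_", met),
                          stoich = stats::setNames(1, met), lb = 0, ub = 1000,
                          exchange = FALSE)
      }
      all(can_produce(m))
    }, logical(1)))
  }, logical(1))
  expect_equal(min(which(sizes)), length(chk$enabled))
  # fully producible model needs nothing
  expect_equal(check_production(toys$FIX1)$enabled, character(0))
  # two disconnected chains need one enabler each
  two <- gem_model("two", c(c = "cytosol"))
  for (x in c("A", "B", "X", "Y")) two <- add_metabolite(two, x, "c")
  two <- add_reaction(two, "r1", equation = "A[c] => B[c]")
  two <- add_reaction(two, "r2", equation = "X[c] => Y[c]")
  chk2 <- check_production(two)
  expect_equal(length(chk2$enabled), 2L)
  # isolated metabolite is reported, not silently failed
  iso <- add_metabolite(toys$FIX1, "Z", "c")
  expect_equal(check_production(iso)$status, "isolated_metabolites")
})

test_that("have_flux classifies blocked reactions by cause", {
  hf <- have_flux(toys$FIX1)
  st <- stats::setNames(hf$status, hf$reaction_id)
  expect_equal(unname(st[c("EX_A", "R1", "R2", "EX_C")]), rep("can_carry", 4))
  expect_equal(unname(st[["R3"]]), "blocked_downstream")
  # adding a sink for D unblocks R3
  withD <- add_reaction(toys$FIX1, "EX_D", stoich = c(`D[c]` = -1),
                        lb = 0, ub = 1000)
  hf2 <- have_flux(withD)
  expect_equal(hf2$status[hf2$reaction_id == "R3"], "can_carry")
  # upstream block: an orphan consumer whose substrate cannot be made
  m <- add_metabolite(toys$FIX1, "W", "c", formula = "C6H12O6")
  m <- add_reaction(m, "RW", equation = "W[c] => B[c]")
  hf3 <- have_flux(m)
  expect_equal(hf3$status[hf3$reaction_id == "RW"], "blocked_upstream")
  # classification is invariant under positive scaling of all bounds
  scaled <- toys$FIX1
  scaled$rxns$lb <- scaled$rxns$lb * 7
  scaled$rxns$ub <- scaled$rxns$ub * 7
  hf4 <- have_flux(scaled)
  expect_equal(hf4$status, hf$status)
})

test_that("subnetwork decomposition via the bipartite graph", {
  sub1 <- get_subnetworks(toys$FIX1)
  expect_equal(length(sub1), 1L)
  m <- add_metabolite(toys$FIX1, "X", "c")
  m <- add_metabolite(m, "Y", "c")
  m <- add_reaction(m, "iso", equation = "X[c] => Y[c]")
  sub2 <- get_subnetworks(m)
  expect_equal(length(sub2), 2L)
  expect_equal(sub2[[2]]$reactions, "iso")
  # order permutation does not change the decomposition
  perm <- m
  ord <- rev(seq_len(nrow(perm$rxns)))
  perm$rxns <- perm$rxns[ord, ]; rownames(perm$rxns) <- NULL
  perm$S <- perm$S[, ord]
  perm$gpr <- perm$gpr[perm$rxns$id]
  sub3 <- get_subnetworks(perm)
  expect_equal(lapply(sub3, `[[`, "reactions"), lapply(sub2, `[[`, "reactions"))
  # currency-metabolite removal splits components glued only by cofactors
  g <- gem_model("cur", c(c = "cytosol"))
  for (x in c("A", "B", "X", "Y", "h2o")) g <- add_metabolite(g, x, "c")
  g <- add_reaction(g, "r1", equation = "A[c] => B[c] + h2o[c]")
  g <- add_reaction(g, "r2", equation = "X[c] + h2o[c] => Y[c]")
  expect_equal(length(get_subnetworks(g)), 1L)
  expect_equal(length(get_subnetworks(g, currency_mets = "h2o")), 2L)
})

test_that("fill_gaps picks the minimal template subset (vs brute force)", {
  fg <- fill_gaps(toys$FIX3, toys$FIX3_template, goal = "produce_all",
                  targets = "C[c]")
  expect_equal(fg$status, "optimal")
  expect_equal(fg$added, "R2")  # one step beats the two-step bypass
  oracle <- brute_force_fill(toys$FIX3, toys$FIX3_template, "C[c]")
  expect_equal(length(fg$added), oracle$size)
  expect_true(can_produce(fg$model, "C[c]"))
  expect_equal(unname(fg$provenance), "FIX3_template")
  expect_equal(fg$model$rxns$evidence[fg$model$rxns$id == "R2"], "connectivity")
  # goal already satisfied: nothing added; idempotence
  again <- fill_gaps(fg$model, toys$FIX3_template, goal = "produce_all")
  expect_equal(again$added, character(0))
})

test_that("fill_gaps goal=unblock_all adds the missing sink", {
  tmpl <- gem_model("sink_template", c(c = "cytosol"))
  tmpl <- add_metabolite(tmpl, "D", "c", formula = "C6H12O6")
  tmpl <- add_reaction(tmpl, "EX_D", stoich = c(`D[c]` = -1), lb = 0, ub = 1000)
  fg <- fill_gaps(toys$FIX1, tmpl, goal = "unblock_all")
  expect_equal(fg$added, "EX_D")
  hf <- have_flux(fg$model)
  expect_true(all(hf$status == "can_carry"))
})

test_that("fill_gaps reports an infeasibility certificate", {
  # template cannot help: C is simply absent from it
  tmpl <- gem_model("useless", c(c = "cytosol"))
  tmpl <- add_metabolite(tmpl, "Q", "c")
  tmpl <- add_reaction(tmpl, "RQ", stoich = c(`Q[c]` = 1), lb = 0, ub = 10,
                       exchange = FALSE)
  fg <- fill_gaps(toys$FIX3, tmpl, goal = "produce_all", targets = "C[c]")
  expect_equal(fg$status, "infeasible")
  expect_true(length(fg$failing) > 0)
  expect_equal(fg$added, character(0))
})

test_that("mass conservation: balanced models never make something", {
  for (nm in c("FIX1", "FIX4", "FIX5", "FIX6")) {
    bal <- elemental_balance(toys[[nm]])
    internal <- bal$status[bal$status != "unbalanced_by_design"]
    expect_true(all(internal == "balanced"), label = nm)
    expect_equal(make_something(toys[[nm]])$solver_status, "infeasible", label = nm)
  }
})
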