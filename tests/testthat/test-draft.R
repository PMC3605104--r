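# Orthology-driven draft reconstruction.

mk_hits <- function(query, subject, evalue = 1e-50, identity = 80,
                    length = 300, bitscore = 500, coverage = 90) {
  n <- base::length(query)
  data.frame(query = query, subject = subject,
             identity = rep_len(identity, n), length = rep_len(length, n),
             evalue = rep_len(evalue, n), bitscore = rep_len(bitscore, n),
             coverage = rep_len(coverage, n), stringsAsFactors = FALSE)
}

test_that("default thresholds are the published orthology cutoffs", {
  th <- orthology_thresholds()
  expect_equal(th$e_value, 1e-30)
  expect_equal(th$identity, 40)
  expect_equal(th$coverage, 50)
  expect_equal(th$length, 200)
})

test_that("bidirectional best hits: reciprocity, thresholds, ties", {
  # mutual best: kept
  bb <- bidirectional_best_hits(mk_hits("a", "b"), mk_hits("b", "a"))
  expect_equal(bb, data.frame(a = "a", b = "b", stringsAsFactors = FALSE),
               ignore_attr = TRUE)
  # a's best is b, but b's best is a2: dropped (brute-force over the toy
  # table: no reciprocal pair exists)
  ab <- mk_hits(c("a", "a2"), c("b", "b"), evalue = c(1e-60, 1e-80))
  ba <- mk_hits("b", "a2", evalue = 1e-80)
  expect_equal(nrow(bidirectional_best_hits(ab, ba)), 1)  # only (a2, b)
  expect_equal(bidirectional_best_hits(ab, ba)$a, "a2")
  # failing any threshold removes the pair
  weak <- mk_hits("a", "b", evalue = 1e-10)
  expect_equal(nrow(bidirectional_best_hits(weak, mk_hits("b", "a"))), 0)
  short <- mk_hits("a", "b", length = 150)
  expect_equal(nrow(bidirectional_best_hits(short, mk_hits("b", "a"))), 0)
  # co-best ties keep all pairs
  tie_ab <- mk_hits("a", c("b1", "b2"))
  tie_ba <- rbind(mk_hits("b1", "a"), mk_hits("b2", "a"))
  expect_equal(nrow(bidirectional_best_hits(tie_ab, tie_ba)), 2)
  # empty tables
  empty <- mk_hits(character(), character())
  expect_equal(nrow(bidirectional_best_hits(empty, empty)), 0)
})

test_that("threshold relaxation never shrinks the orthologue set", {
  set.seed(3)
  ab <- mk_hits(rep(paste0("a", 1:4), each = 2), rep(paste0("b", 1:4), 2),
                evalue = 10^-runif(8, 20, 60), identity = runif(8, 30, 90),
                length = sample(100:400, 8), coverage = runif(8, 30, 95))
  ba <- mk_hits(ab$subject, ab$query, evalue = ab$evalue,
                identity = ab$identity, length = ab$length,
                coverage = ab$coverage)
  strict <- orthology_thresholds()
  relaxed <- list(e_value = 1e-10, identity = 20, coverage = 20, length = 50)
  p_strict <- bidirectional_best_hits(ab, ba, strict)
  p_rel <- bidirectional_best_hits(ab, ba, relaxed)
  key <- function(p) paste(p$a, p$b)
  expect_true(all(key(p_strict) %in% key(p_rel)))
})

test_that("hit-table reader: dialect round trip and malformed rows", {
  f <- tempfile()
  writeLines(c(paste(c("q1", "s1", 80, 300, 5, 0, 1, 300, 1, 300, "1e-50", 500, 90),
                     collapse = "\t"),
               "broken row"), f)
  expect_warning(h <- read_hit_table(f), "malformed")
  expect_equal(nrow(h), 1)
  expect_equal(h$coverage, 90)
  expect_equal(h$evalue, 1e-50)
  # without coverage column the criterion is skipped with a warning
  writeLines(paste(c("q1", "s1", 80, 300, 5, 0, 1, 300, 1, 300, "1e-50", 500),
                   collapse = "\t"), f)
  h2 <- read_hit_table(f)
  expect_true(is.na(h2$coverage))
  expect_warning(bb <- bidirectional_best_hits(h2, mk_hits("s1", "q1")),
                 "coverage")
  expect_equal(nrow(bb), 1)
})

test_that("template drafts rewrite GPRs and keep only supported reactions", {
  # R1 (gene t1) transfers via p1<->t1; R2 (t2) has no orthologue
  dr <- draft_from_templates(toys$FIX1, data.frame(a = "p1", b = "t1"))
  expect_equal(dr$rxns$id, "R1")
  expect_equal(dr$genes, "p1")
  expect_equal(dr$rxns$evidence, "orthology")
  expect_true(evaluate_gpr(dr$gpr$R1, character()))
  # complexes: both members need orthologues
  tm <- gem_model("T", c(c = "cytosol"))
  tm <- add_metabolite(tm, "A", "c"); tm <- add_metabolite(tm, "B", "c")
  tm <- add_reaction(tm, "RC", equation = "A[c] => B[c]", gpr = "t1 and t2")
  half <- draft_from_templates(tm, data.frame(a = "p1", b = "t1"))
  expect_equal(nrow(half$rxns), 0)
  both <- draft_from_templates(tm, data.frame(a = c("p1", "p2"), b = c("t1", "t2")))
  expect_equal(both$gpr$RC, list(c("p1", "p2")))
  # one template gene with two orthologues expands to isozyme options
  multi <- draft_from_templates(tm, data.frame(a = c("p1", "p1b", "p2"),
                                               b = c("t1", "t1", "t2")))
  expect_setequal(vapply(multi$gpr$RC, paste, character(1), collapse = "+"),
                  c("p1+p2", "p1b+p2"))
})

test_that("identical reactions from two templates merge with union GPR", {
  t1 <- toys$FIX1
  t2 <- toys$FIX1; t2$id <- "FIX1b"
  t2$gpr$R1 <- parse_gpr("t9")
  t2$genes <- sort(unique(c(t2$genes, "t9")))
  dr <- draft_from_templates(list(t1, t2),
                             list(data.frame(a = "p1", b = "t1"),
                                  data.frame(a = "p9", b = "t9")))
  expect_equal(nrow(dr$rxns), 1)  # same stoichiometry: merged
  expect_setequal(unlist(dr$gpr$R1), c("p1", "p9"))
  # union property: multi-template draft = union of per-template drafts
  d1 <- draft_from_templates(t1, data.frame(a = "p1", b = "t1"))
  d2 <- draft_from_templates(t2, data.frame(a = "p9", b = "t9"))
  expect_setequal(dr$rxns$id, union(d1$rxns$id, d2$rxns$id))
  expect_setequal(dr$genes, union(d1$genes, d2$genes))
})

test_that("group-database drafts honor cutoffs, flags, and conservation", {
  db <- list(
    groups = data.frame(group_id = c("K1", "K2", "K3"),
                        reaction_ids = c("ra,rb", "rc", "rd"),
                        stringsAsFactors = FALSE),
    reactions = data.frame(id = c("ra", "rb", "rc", "rd"),
                           equation = c("A[c] => B[c]", "B[c] <=> C[c]",
                                        "C[c] => D[c]", "D[c] => E[c]"),
                           stringsAsFactors = FALSE),
    flags = data.frame(reaction_id = "rb", flag = "general",
                       stringsAsFactors = FALSE))
  scores <- data.frame(gene = c("g1", "g2", "g3"),
                       group_id = c("K1", "K2", "K3"),
                       score = c(1e-60, 1e-10, 1e-55), stringsAsFactors = FALSE)
  # cutoff 1e-50 admits K1 and K3; flag 'general' drops rb
  m <- draft_from_group_db(db, scores, cutoff = 1e-50)
  expect_setequal(m$rxns$id, c("ra", "rd"))
  expect_equal(unlist(m$gpr$ra), "g1")
  # conservation: no cutoff, no flags -> the whole database
  all_in <- draft_from_group_db(db, scores, cutoff = Inf,
                                exclude_flags = character())
  expect_setequal(all_in$rxns$id, db$reactions$id)
  # unknown reaction reference errors
  db_bad <- db
  db_bad$groups$reaction_ids[1] <- "ra,zz"
  expect_error(draft_from_group_db(db_bad, scores), "zz")
  # reversibility from the arrow
  expect_lt(all_in$rxns$lb[all_in$rxns$id == "rb"], 0)
})

test_that("external search wrapper: real run if available, loud error if not", {
  withr::with_envvar(c(PATH = ""), {
    expect_error(run_external_search("q.fa", "d.fa"), "external tool unavailable")
  })
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">p1", "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQAPILSRVGDGTQDNLSGAEKAVQVKVKALPDAQFEVVHSLAKWKRQTLGQHDFSAGEGLYTHMKALRPDEDRLSPLHSVYVDQWDWERVMGDGER",
               ">p2", "MSEQNNTEMTFQIQRIYTKDISFEAPNAPHVFQKDWQPEVKLDLDTASSQLADDVYEVVLRVTVTASLGEETAFLCEVQQAGIFSIAGIEGTQMAHCLGAYCPNILFPYARECITSMVSRGTFPQLNLAPVNFDALFMNYLQQ"), fa)
  out <- run_external_search(fa, fa)
  h <- read_hit_table(out)
  self <- h[h$query == h$subject, ]
  expect_gte(nrow(self), 2)
  expect_true(all(self$identity == 100))
  # round trip: the emitted dialect feeds bidirectional_best_hits unchanged
  bb <- bidirectional_best_hits(out, out,
                                thresholds = list(e_value = 1e-5, identity = 90,
                                                  coverage = 50, length = 50))
  expect_true(all(bb$a == bb$b))
})
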