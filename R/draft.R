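# Draft reconstruction from protein homology.
#
# Two routes: (1) template-based — bidirectional best hits between the
# target proteome and the proteomes of curated template models transfer
# reactions whose gene associations can be rewritten onto target genes;
# (2) database-based — per-gene scores against orthology groups (KO-style)
# pull in the reactions of every group with a significant match.

#' Default orthology thresholds
#'
#' Proteins count as orthologues when E-value < 1e-30, identity > 40%,
#' query coverage > 50% and alignment length > 200 amino acids.
#' @return list with `e_value`, `identity`, `coverage`, `length`.
#' @export
orthology_thresholds <- function() {
  list(e_value = 1e-30, identity = 40, coverage = 50, length = 200)
}

#' Read a tab-separated homology hit table
#'
#' The 12-column BLAST outfmt-6 layout (query, subject, identity, length,
#' mismatches, gaps, qstart, qend, sstart, send, evalue, bitscore) with an
#' optional 13th coverage column (percent of query aligned). Malformed rows
#' are skipped with a warning.
#'
#' @param path hit table file.
#' @return data.frame with columns query, subject, identity, length,
#'   evalue, bitscore, coverage (NA when absent).
#' @export
read_hit_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  rows <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(rows) >= 12L
  if (any(!ok)) {
    warning(sum(!ok), " malformed hit row(s) skipped")
    rows <- rows[ok]
  }
  if (length(rows) == 0L) {
    return(data.frame(query = character(), subject = character(),
                      identity = numeric(), length = integer(),
                      evalue = numeric(), bitscore = numeric(),
                      coverage = numeric(), stringsAsFactors = FALSE))
  }
  m <- do.call(rbind, rows)
  data.frame(query = m[, 1], subject = m[, 2],
             identity = as.numeric(m[, 3]), length = as.integer(m[, 4]),
             evalue = as.numeric(m[, 11]), bitscore = as.numeric(m[, 12]),
             coverage = if (ncol(m) >= 13L) as.numeric(m[, 13]) else NA_real_,
             stringsAsFactors = FALSE)
}

pass_thresholds <- function(hits, thresholds) {
  ok <- hits$evalue < thresholds$e_value &
    hits$identity > thresholds$identity &
    hits$length > thresholds$length
  cov_known <- !is.na(hits$coverage)
  if (any(!cov_known) && nrow(hits)) {
    warning("hit table lacks a coverage column; coverage criterion not applied")
  }
  ok & (!cov_known | hits$coverage > thresholds$coverage)
}

#' Bidirectional best hits
#'
#' A pair (a, b) is orthologous iff b is a best hit of a in the A-to-B
#' table, a is a best hit of b in the B-to-A table, and both supporting
#' hits pass the thresholds. "Best" means lowest E-value, ties broken by
#' highest bitscore, with all co-best hits kept so paralogous ties are not
#' silently dropped. Best hits are determined before threshold filtering:
#' this keeps the orthologue set monotone (relaxing any threshold can only
#' grow it), whereas filter-then-best would let a relaxed cutoff promote a
#' different best hit and silently drop previously accepted pairs.
#'
#' @param hits_ab,hits_ba hit tables (data.frames from [read_hit_table()]
#'   or file paths).
#' @param thresholds as [orthology_thresholds()].
#' @return data.frame with columns `a`, `b`.
#' @export
bidirectional_best_hits <- function(hits_ab, hits_ba,
                                    thresholds = orthology_thresholds()) {
  if (is.character(hits_ab)) hits_ab <- read_hit_table(hits_ab)
  if (is.character(hits_ba)) hits_ba <- read_hit_table(hits_ba)
  best_of <- function(h) {
    if (nrow(h) == 0L) return(h)
    out <- do.call(rbind, lapply(split(h, h$query), function(g) {
      g <- g[g$evalue <= min(g$evalue), , drop = FALSE]
      g[g$bitscore >= max(g$bitscore), , drop = FALSE]
    }))
    out[pass_thresholds(out, thresholds), , drop = FALSE]
  }
  ab <- best_of(hits_ab)
  ba <- best_of(hits_ba)
  if (nrow(ab) == 0L || nrow(ba) == 0L) {
    return(data.frame(a = character(), b = character(), stringsAsFactors = FALSE))
  }
  fwd <- paste(ab$query, ab$subject, sep = "\r")
  rev <- paste(ba$subject, ba$query, sep = "\r")
  keep <- fwd %in% rev
  out <- unique(data.frame(a = ab$query[keep], b = ab$subject[keep],
                           stringsAsFactors = FALSE))
  out[order(out$a, out$b), , drop = FALSE]
}

#' Draft model from template models
#'
#' For each template, reactions whose gene association can be rewritten
#' onto target genes (every complex member must have at least one
#' orthologue; members are replaced by the disjunction of their
#' orthologues) are copied with stoichiometry, bounds and compartments
#' intact and evidence set to "orthology". Stoichiometrically identical
#' reactions arriving from several templates are merged with the union of
#' their rewritten associations. Metabolite identity collisions (same id,
#' different formula) are reported with the first template winning.
#'
#' @param templates list of template [gem_model]s.
#' @param orthologue_pairs one data.frame (a = target gene, b = template
#'   gene) per template, as from [bidirectional_best_hits()].
#' @param id id of the draft model.
#' @return a [gem_model].
#' @export
draft_from_templates <- function(templates, orthologue_pairs, id = "draft") {
  if (inherits(templates, "gem_model")) templates <- list(templates)
  if (is.data.frame(orthologue_pairs)) orthologue_pairs <- list(orthologue_pairs)
  stopifnot(length(templates) == length(orthologue_pairs))
  comps <- stats::setNames(character(), character())
  for (tm in templates) comps[names(tm$compartments)] <- tm$compartments
  draft <- gem_model(id, comps)
  sig2id <- character()
  met_formula <- character()
  for (t in seq_along(templates)) {
    tm <- templates[[t]]
    pairs <- orthologue_pairs[[t]]
    t2targets <- split(pairs$a, pairs$b)
    for (i in seq_len(n_rxns(tm))) {
      rid <- tm$rxns$id[i]
      assoc <- tm$gpr[[rid]]
      if (length(assoc) == 0L) next
      new_assoc <- list()
      for (cx in assoc) {
        opts <- lapply(cx, function(g) t2targets[[g]])
        if (any(vapply(opts, is.null, logical(1)))) next
        combos <- expand.grid(opts, stringsAsFactors = FALSE)
        for (j in seq_len(nrow(combos))) {
          new_assoc <- c(new_assoc, list(sort(unique(as.character(combos[j, ])))))
        }
      }
      new_assoc <- unique(new_assoc)
      if (length(new_assoc) == 0L) next
      sig <- rxn_signature(tm, rid)
      col <- tm$S[, rid]
      nz <- which(col != 0)
      for (iid in tm$mets$id[nz]) {
        f <- tm$mets$formula[match(iid, tm$mets$id)]
        if (iid %in% names(met_formula) && !identical(met_formula[[iid]], f)) {
          warning("metabolite ", sQuote(iid), " has conflicting formulas across templates; ",
                  "keeping the first (", sQuote(met_formula[[iid]]), ")")
        } else met_formula[iid] <- f
      }
      if (sig %in% names(sig2id)) {
        ex <- sig2id[[sig]]
        draft$gpr[[ex]] <- unique(c(draft$gpr[[ex]], new_assoc))
        draft$genes <- sort(union(draft$genes, gpr_genes(new_assoc)))
        next
      }
      did <- rid
      while (did %in% draft$rxns$id) did <- paste0(did, "_d")
      st <- stats::setNames(col[nz], tm$mets$id[nz])
      for (iid in names(st)) {
        p <- parse_met_instance(iid)
        if (!iid %in% draft$mets$id) {
          draft <- add_metabolite(draft, p$base_id, p$compartment,
                                  name = tm$mets$name[match(iid, tm$mets$id)],
                                  formula = met_formula[[iid]])
        }
      }
      draft <- add_reaction(draft, did, stoich = st, lb = tm$rxns$lb[i],
                            ub = tm$rxns$ub[i], gpr = new_assoc,
                            name = tm$rxns$name[i],
                            subsystem = tm$rxns$subsystem[i],
                            ec = tm$rxns$ec[i], evidence = "orthology",
                            add_mets = FALSE, exchange = tm$rxns$exchange[i])
      sig2id[sig] <- did
    }
  }
  validate_model(draft)
  draft
}

#' Read an orthology-group reaction database from flat files
#'
#' Three delimited tables in a directory: `groups.tsv` (group_id,
#' reaction_ids comma-separated), `reactions.tsv` (id, equation, optional
#' name), `flags.tsv` (reaction_id, flag; optional file). No network access
#' ever: the database is a committed snapshot.
#'
#' @param path directory.
#' @return list of class `group_db` with `groups`, `reactions`, `flags`.
#' @export
read_group_db <- function(path) {
  groups <- utils::read.delim(file.path(path, "groups.tsv"), stringsAsFactors = FALSE)
  reactions <- utils::read.delim(file.path(path, "reactions.tsv"), stringsAsFactors = FALSE)
  ff <- file.path(path, "flags.tsv")
  flags <- if (file.exists(ff)) utils::read.delim(ff, stringsAsFactors = FALSE)
           else data.frame(reaction_id = character(), flag = character())
  if (anyDuplicated(reactions$id)) stop("duplicate reaction ids in database")
  structure(list(groups = groups, reactions = reactions, flags = flags),
            class = "group_db")
}

#' Draft model from an orthology-group database
#'
#' Includes the reactions of every group to which at least one gene scores
#' at or below `cutoff` (scores are E-value-like: lower is better), minus
#' any reaction carrying an excluded flag. Matching genes are attached as
#' isozymes. The draft lives in a single cytosol-like compartment.
#'
#' @param db a `group_db` from [read_group_db()] (or an equivalent list).
#' @param scores data.frame with `gene`, `group_id`, `score`; the best
#'   score per (gene, group) is used.
#' @param cutoff inclusion threshold (default 1e-50, the conservative
#'   choice for de-novo reconstruction; 1e-30 suits re-annotation of
#'   well-studied organisms).
#' @param exclude_flags reactions carrying any of these flags are dropped
#'   (e.g. c("general", "incomplete")).
#' @param id draft model id.
#' @return a [gem_model].
#' @export
draft_from_group_db <- function(db, scores, cutoff = 1e-50,
                                exclude_flags = c("general", "incomplete"),
                                id = "draft_db") {
  ids <- trimws(unlist(strsplit(db$groups$reaction_ids, ",")))
  unknown <- setdiff(ids[nzchar(ids)], db$reactions$id)
  if (length(unknown)) {
    stop("group references unknown reaction id(s): ",
         paste(unknown, collapse = ", "))
  }
  bad_rxns <- unique(db$flags$reaction_id[db$flags$flag %in% exclude_flags])
  scores <- scores[order(scores$score), , drop = FALSE]
  scores <- scores[!duplicated(paste(scores$gene, scores$group_id)), , drop = FALSE]
  hit <- scores[scores$score <= cutoff, , drop = FALSE]
  # an infinite cutoff means "take the whole database", including groups no
  # gene ever scored against (conservation: the draft then equals the db)
  take <- if (is.infinite(cutoff)) db$groups$group_id else unique(hit$group_id)
  rxn_genes <- list()
  for (g in take) {
    row <- db$groups[db$groups$group_id == g, , drop = FALSE]
    if (nrow(row) == 0L) next
    rids <- trimws(strsplit(row$reaction_ids, ",")[[1]])
    genes <- hit$gene[hit$group_id == g]
    for (r in rids) {
      rxn_genes[[r]] <- sort(union(rxn_genes[[r]], genes))
    }
  }
  keep <- setdiff(names(rxn_genes), bad_rxns)
  model <- gem_model(id, c(c = "cytosol"))
  for (r in sort(keep)) {
    i <- match(r, db$reactions$id)
    model <- add_reaction(model, r, equation = db$reactions$equation[i],
                          ub = 1000, gpr = lapply(rxn_genes[[r]], identity),
                          evidence = "orthology", add_mets = TRUE)
  }
  validate_model(model)
  model
}

#' Run an external protein similarity search (optional wrapper)
#'
#' Wraps `makeblastdb` + `blastp` to produce a hit table in the dialect of
#' [read_hit_table()] (outfmt 6 plus a qcovs coverage column). If the
#' tools are not on the PATH the operation fails loudly — precomputed hit
#' tables are the supported offline route.
#'
#' @param query_fasta,db_fasta protein FASTA files.
#' @param out output hit-table path.
#' @return `out`, invisibly.
#' @export
run_external_search <- function(query_fasta, db_fasta, out = tempfile(fileext = ".tsv")) {
  if (Sys.which("blastp") == "" || Sys.which("makeblastdb") == "") {
    stop("external tool unavailable: blastp/makeblastdb not on PATH. ",
         "Install NCBI BLAST+ or supply a precomputed hit table.")
  }
  dbdir <- tempfile("blastdb")
  dir.create(dbdir)
  dbp <- file.path(dbdir, "db")
  st1 <- system2("makeblastdb", c("-in", shQuote(db_fasta), "-dbtype", "prot",
                                  "-out", shQuote(dbp)), stdout = FALSE, stderr = FALSE)
  if (st1 != 0) stop("makeblastdb failed with status ", st1)
  st2 <- system2("blastp", c("-query", shQuote(query_fasta), "-db", shQuote(dbp),
                             "-outfmt", shQuote("6 qseqid sseqid pident length mismatch gapopen qstart qend sstart send evalue bitscore qcovs"),
                             "-out", shQuote(out)), stdout = FALSE, stderr = FALSE)
  if (st2 != 0) stop("blastp failed with status ", st2)
  invisible(out)
}
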