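# Tabular workbook dialect.
#
# A model is four sheets: RXNS (id, name, equation, lb, ub,
# gene_association, subsystem, ec, evidence, objective), METS (id,
# compartment, name, formula, charge), COMPS (id, name), GENES (id).
# Equations use "=>" / "<=>" arrows and "[compartment]" suffixes; a
# reversible arrow implies a negative default lower bound, explicit lb/ub
# columns override. The on-disk form is either a directory of TSV files
# (RXNS.tsv, ...; written and read bit-exactly, no spreadsheet engine
# involved) or an .xlsx workbook with the same sheet names (read-only,
# via readxl).

#' Read a model from the tabular dialect
#'
#' @param path a directory of TSV sheets or an `.xlsx` workbook.
#' @return a [gem_model].
#' @export
read_tabular_model <- function(path) {
  if (dir.exists(path)) {
    sheet <- function(nm, required = TRUE) {
      f <- file.path(path, paste0(nm, ".tsv"))
      if (!file.exists(f)) {
        if (required) stop("missing sheet ", nm, ".tsv in ", path)
        return(NULL)
      }
      utils::read.delim(f, stringsAsFactors = FALSE, check.names = FALSE,
                        na.strings = character())
    }
  } else if (grepl("\\.xlsx$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading .xlsx workbooks needs the readxl package")
    }
    sheets <- readxl::excel_sheets(path)
    sheet <- function(nm, required = TRUE) {
      if (!nm %in% sheets) {
        if (required) stop("missing sheet ", nm, " in ", path)
        return(NULL)
      }
      as.data.frame(readxl::read_excel(path, sheet = nm),
                    stringsAsFactors = FALSE)
    }
  } else {
    stop("path must be a sheet directory or an .xlsx workbook: ", path)
  }
  comps <- sheet("COMPS")
  mets <- sheet("METS")
  rxns <- sheet("RXNS")
  genes <- sheet("GENES", required = FALSE)
  names(comps) <- tolower(names(comps))
  names(mets) <- tolower(names(mets))
  names(rxns) <- tolower(names(rxns))
  model <- gem_model(basename(sub("/+$", "", path)),
                     stats::setNames(
                       if ("name" %in% names(comps)) comps$name else comps$id,
                       comps$id))
  colv <- function(df, nm, default) {
    if (nm %in% names(df)) df[[nm]] else rep(default, nrow(df))
  }
  for (i in seq_len(nrow(mets))) {
    model <- add_metabolite(model, mets$id[i], mets$compartment[i],
                            name = colv(mets, "name", mets$id)[i],
                            formula = as.character(colv(mets, "formula", "")[i]),
                            charge = suppressWarnings(as.integer(colv(mets, "charge", NA)[i])))
  }
  for (i in seq_len(nrow(rxns))) {
    eq <- rxns$equation[i]
    pe <- tryCatch(parse_equation(eq), error = function(e) {
      stop("reaction ", sQuote(rxns$id[i]), ": ", conditionMessage(e))
    })
    lb <- suppressWarnings(as.numeric(colv(rxns, "lb", NA)[i]))
    ub <- suppressWarnings(as.numeric(colv(rxns, "ub", NA)[i]))
    if (is.na(lb)) lb <- if (pe$reversible) -1000 else 0
    if (is.na(ub)) ub <- 1000
    exch <- colv(rxns, "exchange", NA)[i]
    exch <- if (is.na(exch)) NULL else as.logical(exch)
    model <- tryCatch(
      add_reaction(model, rxns$id[i], stoich = pe$stoich, lb = lb, ub = ub,
                   gpr = as.character(colv(rxns, "gene_association", "")[i]),
                   name = as.character(colv(rxns, "name", rxns$id)[i]),
                   subsystem = as.character(colv(rxns, "subsystem", "")[i]),
                   ec = as.character(colv(rxns, "ec", "")[i]),
                   evidence = as.character(colv(rxns, "evidence", "literature")[i]),
                   add_mets = FALSE, exchange = exch),
      error = function(e) stop("reaction ", sQuote(rxns$id[i]), ": ",
                               conditionMessage(e)))
  }
  objcol <- suppressWarnings(as.numeric(colv(rxns, "objective", NA)))
  if (any(!is.na(objcol) & objcol != 0)) {
    k <- which(!is.na(objcol) & objcol != 0)
    model <- set_objective(model, stats::setNames(objcol[k], rxns$id[k]))
  }
  if (!is.null(genes)) {
    names(genes) <- tolower(names(genes))
    model$genes <- sort(union(model$genes, genes$id))
  }
  validate_model(model)
  model
}

#' Write a model in the tabular dialect
#'
#' Writes the four TSV sheets into `path` (created if needed). The written
#' form round-trips bit-exactly through [read_tabular_model()].
#'
#' @param model a [gem_model].
#' @param path output directory.
#' @return `path`, invisibly.
#' @export
write_tabular_model <- function(model, path) {
  stopifnot(inherits(model, "gem_model"))
  validate_model(model)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, nm) {
    utils::write.table(df, file.path(path, paste0(nm, ".tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wr(data.frame(id = names(model$compartments),
                name = unname(model$compartments)), "COMPS")
  wr(data.frame(id = model$mets$base_id, compartment = model$mets$compartment,
                name = model$mets$name, formula = model$mets$formula,
                charge = model$mets$charge), "METS")
  obj <- stats::setNames(numeric(n_rxns(model)), model$rxns$id)
  obj[names(model$objective)] <- model$objective
  wr(data.frame(
    id = model$rxns$id, name = model$rxns$name,
    equation = vapply(model$rxns$id, function(r) format_equation(model, r), character(1)),
    lb = model$rxns$lb, ub = model$rxns$ub,
    gene_association = vapply(model$gpr[model$rxns$id], format_gpr, character(1)),
    subsystem = model$rxns$subsystem, ec = model$rxns$ec,
    evidence = model$rxns$evidence, exchange = model$rxns$exchange,
    objective = unname(obj)), "RXNS")
  wr(data.frame(id = model$genes), "GENES")
  invisible(path)
}
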