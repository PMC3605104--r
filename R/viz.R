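# Flux/expression overlays on pre-drawn pathway maps.
#
# Maps are SBML files carrying the Level-3 layout package (the subset
# CellDesigner and other editors can export): reactionGlyph and
# speciesGlyph elements with bounding boxes, each reaction glyph keyed by
# the model reaction id it depicts. Overlays are written as standalone SVG
# (a text vector format every browser renders), with reactions colored on
# a symmetric green-red log2 fold-change scale.

#' Parse a layout-annotated SBML map
#'
#' @param path SBML file with a layout extension.
#' @return object of class `map_document`: `rxn_glyphs` /
#'   `species_glyphs` data.frames (id, x, y, width, height), `canvas`
#'   (width, height).
#' @export
parse_map <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("map parse error: ", conditionMessage(e)))
  layouts <- xml2::xml_find_all(doc, ".//*[local-name()='layout']")
  if (length(layouts) == 0L) {
    stop("no layout extension found in ", path,
         " (the map must carry SBML layout annotations)")
  }
  lay <- layouts[[1]]
  read_glyphs <- function(what, refattr) {
    gl <- xml2::xml_find_all(lay, paste0(".//*[local-name()='", what, "']"))
    if (length(gl) == 0L) {
      return(data.frame(id = character(), x = numeric(), y = numeric(),
                        width = numeric(), height = numeric()))
    }
    ids <- vapply(gl, function(g) {
      a <- xml2::xml_attrs(g)
      v <- attr_any(a, c(paste0("layout:", refattr), refattr, "id"))
      as.character(v)
    }, character(1))
    geom <- t(vapply(gl, function(g) {
      dims <- xml2::xml_find_first(g, ".//*[local-name()='dimensions']")
      pos <- xml2::xml_find_first(g, ".//*[local-name()='position']")
      gx <- function(node, keys) {
        if (inherits(node, "xml_missing")) return(NA_real_)
        as.numeric(attr_any(xml2::xml_attrs(node), keys))
      }
      c(gx(pos, c("layout:x", "x")), gx(pos, c("layout:y", "y")),
        gx(dims, c("layout:width", "width")), gx(dims, c("layout:height", "height")))
    }, numeric(4)))
    data.frame(id = ids, x = geom[, 1], y = geom[, 2], width = geom[, 3],
               height = geom[, 4], stringsAsFactors = FALSE)
  }
  dims <- xml2::xml_find_first(lay, "./*[local-name()='dimensions']")
  cw <- if (inherits(dims, "xml_missing")) NA_real_ else
    as.numeric(attr_any(xml2::xml_attrs(dims), c("layout:width", "width")))
  ch <- if (inherits(dims, "xml_missing")) NA_real_ else
    as.numeric(attr_any(xml2::xml_attrs(dims), c("layout:height", "height")))
  structure(list(rxn_glyphs = read_glyphs("reactionGlyph", "reaction"),
                 species_glyphs = read_glyphs("speciesGlyph", "species"),
                 canvas = c(width = cw, height = ch)),
            class = "map_document")
}

#' @export
print.map_document <- function(x, ...) {
  cat("Map document:", nrow(x$rxn_glyphs), "reaction glyphs,",
      nrow(x$species_glyphs), "species glyphs\n")
  invisible(x)
}

# symmetric green-red scale on log2 fold change, capped
flux_color <- function(lfc, cap = 3) {
  if (is.na(lfc)) return("#bdbdbd")
  v <- max(-1, min(1, lfc / cap))
  if (v >= 0) {
    # white -> green
    g <- 1
    rb <- 1 - v
    grDevices::rgb(rb, 1, rb)
  } else {
    rb <- 1 + v
    grDevices::rgb(1, rb, rb)
  }
}

#' Render a flux-change overlay as SVG
#'
#' Colors each reaction glyph by the log2 fold change of |flux| between a
#' reference and a test flux distribution on a symmetric green (higher in
#' test) to red (lower) scale capped at +-`cap`; zero-to-nonzero
#' transitions are drawn at the cap with an infinity marker. Reactions
#' active in either condition get their numeric fluxes printed. With
#' `expression` (data.frame gene/p/direction) small tiles per associated
#' gene — taken from the model's gene associations, not from the map — are
#' drawn beside each reaction. Glyph ids that do not resolve in the model
#' are rendered neutral and listed, and model reactions absent from the
#' map are reported, so coverage is auditable.
#'
#' @param map a `map_document`.
#' @param model the [gem_model] the fluxes refer to.
#' @param flux_ref,flux_test named flux vectors or `gem_flux` objects.
#' @param expression optional expression table.
#' @param file output SVG path.
#' @param cap color-scale cap on |log2 FC|.
#' @return invisibly, list with `file`, `unresolved` (glyph ids not in the
#'   model), `uncovered` (model reactions not on the map).
#' @export
render_overlay <- function(map, model, flux_ref, flux_test, expression = NULL,
                           file, cap = 3) {
  if (inherits(flux_ref, "gem_flux")) flux_ref <- flux_ref$fluxes
  if (inherits(flux_test, "gem_flux")) flux_test <- flux_test$fluxes
  g <- map$rxn_glyphs
  unresolved <- setdiff(g$id, model$rxns$id)
  uncovered <- setdiff(model$rxns$id, g$id)
  W <- if (is.na(map$canvas[["width"]])) max(g$x + g$width, 100) + 20 else map$canvas[["width"]]
  H <- if (is.na(map$canvas[["height"]])) max(g$y + g$height, 100) + 20 else map$canvas[["height"]]
  esc <- function(s) gsub("&", "&amp;", gsub("<", "&lt;", s))
  out <- c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%g" height="%g">', W, H))
  for (i in seq_len(nrow(g))) {
    rid <- g$id[i]
    known <- rid %in% model$rxns$id
    vr <- if (known && rid %in% names(flux_ref)) abs(flux_ref[[rid]]) else NA_real_
    vt <- if (known && rid %in% names(flux_test)) abs(flux_test[[rid]]) else NA_real_
    inf_marker <- FALSE
    lfc <- if (!known || is.na(vr) || is.na(vt)) NA_real_
    else if (vr <= 1e-12 && vt <= 1e-12) 0
    else if (vr <= 1e-12) { inf_marker <- TRUE; cap }
    else if (vt <= 1e-12) { inf_marker <- TRUE; -cap }
    else log2(vt / vr)
    col <- flux_color(lfc, cap)
    out <- c(out, sprintf(
      '<rect x="%g" y="%g" width="%g" height="%g" fill="%s" stroke="#333333" data-reaction="%s" data-lfc="%s"/>',
      g$x[i], g$y[i], g$width[i], g$height[i], col, esc(rid),
      if (is.na(lfc)) "NA" else format(lfc, digits = 4)))
    label <- esc(rid)
    if (!is.na(vr) && !is.na(vt) && (vr > 1e-12 || vt > 1e-12)) {
      label <- sprintf("%s %.3g/%.3g%s", label, vr, vt,
                       if (inf_marker) " ∞" else "")
    }
    out <- c(out, sprintf(
      '<text x="%g" y="%g" font-size="8" font-family="sans-serif">%s</text>',
      g$x[i] + 2, g$y[i] + g$height[i] / 2 + 3, label))
    if (!is.null(expression) && known) {
      genes <- gpr_genes(model$gpr[[rid]])
      for (k in seq_along(genes)) {
        row <- expression[expression$gene == genes[k], , drop = FALSE]
        ecol <- if (nrow(row) == 0L) "#bdbdbd" else {
          flux_color(sign(row$direction[1]) * min(-log10(max(row$p[1], 1e-12)), cap), cap)
        }
        out <- c(out, sprintf(
          '<rect x="%g" y="%g" width="6" height="6" fill="%s" stroke="#666666" data-gene="%s"/>',
          g$x[i] + g$width[i] + 2 + (k - 1) * 8, g$y[i], ecol, esc(genes[k])))
      }
    }
  }
  out <- c(out, "</svg>")
  writeLines(out, file)
  invisible(list(file = file, unresolved = unresolved, uncovered = uncovered))
}

#' Write a toy layout map for a model
#'
#' Emits a minimal layout-SBML map (one rectangular glyph per requested
#' reaction, laid out on a grid) — useful for tests and as a template for
#' the dialect [parse_map()] expects.
#'
#' @param model a [gem_model].
#' @param path output file.
#' @param rxn_ids reactions to place (default all).
#' @return `path`, invisibly.
#' @export
write_toy_map <- function(model, path, rxn_ids = model$rxns$id) {
  ns_layout <- "http://www.sbml.org/sbml/level3/version1/layout/version1"
  n <- length(rxn_ids)
  ncol_ <- ceiling(sqrt(n))
  doc <- xml2::xml_new_root("sbml", xmlns = sbml_ns[["sbml"]],
                            "xmlns:layout" = ns_layout, level = "3", version = "1",
                            "layout:required" = "false")
  mdl <- xml2::xml_add_child(doc, "model", id = sanitize_sid(model$id))
  lol <- xml2::xml_add_child(mdl, "layout:listOfLayouts")
  lay <- xml2::xml_add_child(lol, "layout:layout", "layout:id" = "layout1")
  xml2::xml_add_child(lay, "layout:dimensions",
                      "layout:width" = as.character(ncol_ * 120 + 20),
                      "layout:height" = as.character(ceiling(n / ncol_) * 40 + 20))
  lorg <- xml2::xml_add_child(lay, "layout:listOfReactionGlyphs")
  for (i in seq_len(n)) {
    rg <- xml2::xml_add_child(lorg, "layout:reactionGlyph",
                              "layout:id" = paste0("rg", i),
                              "layout:reaction" = rxn_ids[i])
    bb <- xml2::xml_add_child(rg, "layout:boundingBox")
    xml2::xml_add_child(bb, "layout:position",
                        "layout:x" = as.character(10 + ((i - 1) %% ncol_) * 120),
                        "layout:y" = as.character(10 + ((i - 1) %/% ncol_) * 40))
    xml2::xml_add_child(bb, "layout:dimensions",
                        "layout:width" = "100", "layout:height" = "24")
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
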