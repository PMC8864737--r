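# Standardized pathway-map rendering and linting.
#
# A map is described declaratively (YAML): hand-placed metabolite nodes,
# reaction edges routed through waypoints, pathway/"other" boxes, optional
# compartment regions. The renderer turns this into SVG 1.1 following the
# shared visual conventions: black enzymatic edges, green transport edges,
# gene labels in blue with "|" between OR alternatives and "&" within AND
# chains, co-reactants in orange, a grayscale pathway-count square and
# transport-class circles beside every metabolite, and a legend appended to
# every map. Elements carry stable class attributes (wp-gene, wp-met,
# wp-coreactant, wp-legend) so extraction and styling are structural, not
# color-based. Rendering is deterministic: the same inputs produce
# byte-identical SVG.

SVG_NS <- "http://www.w3.org/2000/svg"
XLINK_NS <- "http://www.w3.org/1999/xlink"

#' Map rendering style configuration
#'
#' Colors follow the shared map conventions (black enzymatic edges, green
#' transport edges, blue gene labels, orange co-reactants); exact hex values
#' are configurable defaults. `grayscale_bins` are the square fills for
#' pathway counts 1, 2, 3 and >= 4; `circle_colors` color the two transport
#' classes. `link_template` builds metabolite hyperlink targets from the
#' `{met}` placeholder (default: local anchors).
#'
#' @param color_enzymatic_edge,color_transport_edge,color_gene_label,color_coreactant
#'   hex colors for the four element classes.
#' @param grayscale_bins four hex grays, light to dark.
#' @param circle_colors named hex colors for `C_E` and `M_C`.
#' @param font_family,font_size label font.
#' @param link_template hyperlink pattern with a `{met}` placeholder.
#' @return an object of class `wp_style`.
#' @export
wp_style <- function(color_enzymatic_edge = "#000000",
                     color_transport_edge = "#008000",
                     color_gene_label = "#0000FF",
                     color_coreactant = "#FF8C00",
                     grayscale_bins = c("#D9D9D9", "#969696", "#636363", "#252525"),
                     circle_colors = c(C_E = "#984EA3", M_C = "#17BECF"),
                     font_family = "Helvetica",
                     font_size = 12,
                     link_template = "#met-{met}") {
  style <- list(color_enzymatic_edge = color_enzymatic_edge,
                color_transport_edge = color_transport_edge,
                color_gene_label = color_gene_label,
                color_coreactant = color_coreactant,
                grayscale_bins = grayscale_bins,
                circle_colors = circle_colors,
                font_family = font_family,
                font_size = font_size,
                link_template = link_template)
  cols <- c(style$color_enzymatic_edge, style$color_transport_edge,
            style$color_gene_label, style$color_coreactant,
            style$grayscale_bins, style$circle_colors)
  if (!all(grepl("^#[0-9A-Fa-f]{6}$", cols))) {
    wp_domain_error("all style colors must be 6-digit hex values")
  }
  if (length(style$grayscale_bins) != 4L) {
    wp_domain_error("grayscale_bins must have exactly 4 entries")
  }
  structure(style, class = "wp_style")
}

yaml_num <- function(x, what) {
  if (is.null(x) || length(x) != 1L || !is.numeric(x)) {
    wp_parse_error(sprintf("map definition: %s must be a single number", what))
  }
  as.numeric(x)
}

#' Load a map definition
#'
#' Reads the YAML map-definition dialect: top-level keys `map` (id, title,
#' level, category, canvas width/height), `nodes` (met, x, y, optional
#' terminal / main_terminus flags), `edges` (reaction, waypoints, optional
#' label anchor and `genes` display override), `boxes` (kind pathway|other,
#' optional target and met anchor, x, y), `regions`, and an optional
#' `reactions` list naming the reactions that belong to this map's pathway.
#' Coordinates are pixels, origin top-left, y growing downward.
#'
#' When `model` is supplied, metabolite and reaction references are
#' resolved: in strict mode an unresolved reference is an error; in lenient
#' mode the definition loads and the problems are carried as pending lint
#' issues (picked up by [lint_map()]).
#'
#' @param path YAML file.
#' @param model optional `metabolic_model` for reference resolution.
#' @param strict error on unresolved references (default TRUE when a model
#'   is given).
#' @return an object of class `map_definition`.
#' @export
load_map_definition <- function(path, model = NULL, strict = !is.null(model)) {
  if (!file.exists(path)) wp_io_error(sprintf("file not found: %s", path))
  doc <- tryCatch(yaml::read_yaml(path),
                  error = function(e) wp_parse_error(
                    sprintf("malformed map document %s: %s", path,
                            conditionMessage(e))))
  if (!is.list(doc) || is.null(doc$map)) {
    wp_parse_error(sprintf("map document %s: missing top-level 'map' key", path))
  }
  m <- doc$map
  for (fld in c("id", "title", "level", "category")) {
    if (is.null(m[[fld]])) {
      wp_parse_error(sprintf("map document %s: map.%s missing", path, fld))
    }
  }
  level <- check_level(m$level)
  canvas <- list(width = yaml_num(m$canvas$width, "canvas.width"),
                 height = yaml_num(m$canvas$height, "canvas.height"))

  nodes <- do.call(rbind, lapply(doc$nodes, function(nd) {
    if (is.null(nd$met)) wp_parse_error("map node without 'met'")
    data.frame(met = nd$met,
               x = yaml_num(nd$x, "node x"), y = yaml_num(nd$y, "node y"),
               terminal = isTRUE(nd$terminal),
               main_terminus = isTRUE(nd$main_terminus),
               stringsAsFactors = FALSE)
  }))
  if (is.null(nodes)) {
    nodes <- data.frame(met = character(0), x = numeric(0), y = numeric(0),
                        terminal = logical(0), main_terminus = logical(0))
  }
  if (any(nodes$x < 0 | nodes$x > canvas$width |
          nodes$y < 0 | nodes$y > canvas$height)) {
    wp_parse_error(sprintf("map %s: node coordinates outside canvas", m$id))
  }

  edges <- lapply(doc$edges, function(ed) {
    if (is.null(ed$reaction)) wp_parse_error("map edge without 'reaction'")
    wps <- ed$waypoints
    if (is.null(wps) || length(wps) < 2L) {
      wp_parse_error(sprintf("edge %s: at least two waypoints required", ed$reaction))
    }
    wp_mat <- do.call(rbind, lapply(wps, function(p) {
      if (length(p) != 2L) wp_parse_error("waypoint must be an [x, y] pair")
      as.numeric(p)
    }))
    label <- if (!is.null(ed$label)) as.numeric(ed$label) else colMeans(wp_mat)
    list(reaction = ed$reaction, waypoints = wp_mat, label = label,
         genes = if (is.null(ed$genes)) NA_character_ else as.character(ed$genes))
  })

  boxes <- do.call(rbind, lapply(doc$boxes, function(bx) {
    kind <- bx$kind
    if (is.null(kind) || !kind %in% c("pathway", "other")) {
      wp_parse_error("box kind must be 'pathway' or 'other'")
    }
    if (kind == "pathway" && is.null(bx$target)) {
      wp_parse_error("pathway box without 'target'")
    }
    data.frame(kind = kind,
               target = if (is.null(bx$target)) NA_character_ else bx$target,
               met = if (is.null(bx$met)) NA_character_ else bx$met,
               x = yaml_num(bx$x, "box x"), y = yaml_num(bx$y, "box y"),
               stringsAsFactors = FALSE)
  }))
  if (is.null(boxes)) {
    boxes <- data.frame(kind = character(0), target = character(0),
                        met = character(0), x = numeric(0), y = numeric(0))
  }

  regions <- do.call(rbind, lapply(doc$regions, function(rg) {
    data.frame(label = rg$label, x = yaml_num(rg$x, "region x"),
               y = yaml_num(rg$y, "region y"),
               width = yaml_num(rg$width, "region width"),
               height = yaml_num(rg$height, "region height"),
               stringsAsFactors = FALSE)
  }))
  if (is.null(regions)) {
    regions <- data.frame(label = character(0), x = numeric(0), y = numeric(0),
                          width = numeric(0), height = numeric(0))
  }

  mapdef <- structure(
    list(map = list(id = m$id, title = m$title, level = level,
                    category = m$category, canvas = canvas),
         nodes = nodes, edges = edges, boxes = boxes, regions = regions,
         reactions = as.character(unlist(doc$reactions))),
    class = "map_definition"
  )

  if (!is.null(model)) {
    pending <- resolve_map_refs(mapdef, model)
    if (strict && nrow(pending) > 0L) {
      wp_reference_error(sprintf(
        "map %s: unresolved reference(s): %s", m$id,
        paste(pending$subject, collapse = ", ")))
    }
    attr(mapdef, "pending_issues") <- pending
  }
  mapdef
}

# unresolved node/edge references against a model -> lint-shaped rows
resolve_map_refs <- function(mapdef, model) {
  rows <- list()
  bad_mets <- setdiff(mapdef$nodes$met, model$metabolites$ref)
  for (bm in bad_mets) {
    rows[[length(rows) + 1L]] <- lint_row("ERROR", "MET_UNRESOLVED",
      mapdef$map$id, bm, sprintf("node metabolite %s not in model", bm))
  }
  eids <- vapply(mapdef$edges, function(e) e$reaction, "")
  bad_rxns <- setdiff(eids, names(model$reactions))
  for (br in bad_rxns) {
    rows[[length(rows) + 1L]] <- lint_row("ERROR", "REACTION_UNRESOLVED",
      mapdef$map$id, br, sprintf("edge reaction %s not in model", br))
  }
  bind_lint_rows(rows)
}

#' @export
print.map_definition <- function(x, ...) {
  cat(sprintf("<map_definition> %s ('%s', level %d: %s): %d nodes, %d edges, %d boxes\n",
              x$map$id, x$map$title, x$map$level, x$map$category,
              nrow(x$nodes), length(x$edges), nrow(x$boxes)))
  invisible(x)
}

#' Assemble a metabolite hover card
#'
#' Each metabolite on a map is backed by a card stacking its full chemical
#' name, formula and structure image. When no structure image is available
#' (`structure_ref` is `NONE` or empty, or the referenced file is missing)
#' the card carries the exact placeholder text `Structure not available`.
#'
#' @param met a metabolite record: a one-row slice of
#'   `model$metabolites` or any list with `met_id` (or `ref`), `name`,
#'   `formula`, `structure_ref`.
#' @param image_dir optional directory against which `structure_ref` is
#'   resolved for the existence check.
#' @return an object of class `metabolite_card` with fields `met`, `name`,
#'   `formula`, `structure` (image ref or the placeholder) and
#'   `has_structure`.
#' @export
build_metabolite_card <- function(met, image_dir = NULL) {
  met <- as.list(met)
  ref <- if (!is.null(met$ref)) met$ref else met$met_id
  sref <- met$structure_ref
  sref <- if (is.null(sref) || is.na(sref)) "" else wp_trim(sref)
  has <- nzchar(sref) && !identical(toupper(sref), "NONE")
  missing_file <- FALSE
  if (has && !is.null(image_dir)) {
    fp <- file.path(image_dir, sref)
    if (!file.exists(fp)) {
      has <- FALSE
      missing_file <- TRUE
    }
  }
  structure(
    list(met = ref,
         name = if (is.null(met$name)) "" else met$name,
         formula = if (is.null(met$formula) || is.na(met$formula)) "" else met$formula,
         structure = if (has) sref else "Structure not available",
         has_structure = has,
         missing_file = missing_file),
    class = "metabolite_card"
  )
}

#' @export
print.metabolite_card <- function(x, ...) {
  cat(sprintf("<metabolite_card> %s: %s%s | %s\n", x$met, x$name,
              if (nzchar(x$formula)) paste0(" (", x$formula, ")") else "",
              x$structure))
  invisible(x)
}

svg_child <- function(parent, name, text = NULL, ...) {
  nd <- xml2::xml_add_child(parent, name, ...)
  if (!is.null(text)) xml2::xml_text(nd) <- text
  nd
}

fmt_px <- function(x) {
  # fixed numeric formatting so output never depends on options(digits=)
  sub("\\.?0+$", "", sprintf("%.3f", x))
}

#' Render a pathway map to SVG
#'
#' Produces a well-formed SVG 1.1 document from a map definition following
#' the standard conventions: enzymatic edges in the enzymatic color,
#' transport edges in the transport color, one blue gene label per edge
#' (OR alternatives joined by `|`, AND chains by `&`), orange co-reactant
#' labels at edge midpoints, metabolite text anchors wrapped in hyperlinks
#' and carrying hover-card metadata as `title` elements, a grayscale
#' pathway-count square and transport circles beside every node, labeled
#' pathway/"other" boxes, compartment regions, and exactly one legend
#' group. Output is deterministic for fixed inputs.
#'
#' @param mapdef a `map_definition`.
#' @param model a `metabolic_model`.
#' @param aset an `annotation_set` (drives pathway counts).
#' @param style a [wp_style()].
#' @param box_threshold passed through to connectivity queries.
#' @param rxn_pathways optional explicit reaction-to-pathway table.
#' @param strict error on unresolved references (default TRUE); when FALSE
#'   unresolved nodes/edges are rendered as plain labels.
#' @return an `xml2::xml_document`; serialise with [xml2::write_xml()] or
#'   [write_map_svg()].
#' @export
render_map <- function(mapdef, model, aset, style = wp_style(),
                       box_threshold = 2, rxn_pathways = NULL, strict = TRUE) {
  stopifnot(inherits(mapdef, "map_definition"),
            inherits(model, "metabolic_model"),
            inherits(aset, "annotation_set"),
            inherits(style, "wp_style"))
  pending <- resolve_map_refs(mapdef, model)
  if (strict && nrow(pending) > 0L) {
    wp_reference_error(sprintf("map %s: unresolved reference(s): %s",
                               mapdef$map$id,
                               paste(pending$subject, collapse = ", ")))
  }
  if (is.null(rxn_pathways) && length(mapdef$reactions) > 0L) {
    rxn_pathways <- stats::setNames(
      rep(list(mapdef$map$category), length(mapdef$reactions)),
      mapdef$reactions)
  }

  doc <- xml2::xml_new_root(
    "svg", xmlns = SVG_NS, `xmlns:xlink` = XLINK_NS, version = "1.1",
    width = fmt_px(mapdef$map$canvas$width),
    height = fmt_px(mapdef$map$canvas$height))
  svg_child(doc, "title", sprintf("%s (Level %d: %s)", mapdef$map$title,
                                  mapdef$map$level, mapdef$map$category))

  # compartment regions first, behind everything else
  g_regions <- svg_child(doc, "g", class = "wp-regions")
  for (i in seq_len(nrow(mapdef$regions))) {
    rg <- mapdef$regions[i, ]
    svg_child(g_regions, "rect", x = fmt_px(rg$x), y = fmt_px(rg$y),
              width = fmt_px(rg$width), height = fmt_px(rg$height),
              fill = "none", stroke = "#BBBBBB", `stroke-dasharray` = "6,4")
    svg_child(g_regions, "text", rg$label,
              x = fmt_px(rg$x + 6), y = fmt_px(rg$y + 16),
              fill = "#BBBBBB", `font-family` = style$font_family,
              `font-size` = fmt_px(style$font_size), class = "wp-region-label")
  }

  g_edges <- svg_child(doc, "g", class = "wp-edges")
  for (ed in mapdef$edges) {
    rxn <- model$reactions[[ed$reaction]]
    edge_color <- if (!is.null(rxn) && rxn$rtype == "transport")
      style$color_transport_edge else style$color_enzymatic_edge
    edge_class <- if (!is.null(rxn) && rxn$rtype == "transport")
      "wp-edge wp-edge-transport" else "wp-edge wp-edge-enzymatic"
    g_edge <- svg_child(g_edges, "g", class = edge_class,
                        `data-reaction` = ed$reaction)
    pts <- paste(apply(ed$waypoints, 1L, function(p)
      paste0(fmt_px(p[1]), ",", fmt_px(p[2]))), collapse = " ")
    svg_child(g_edge, "polyline", points = pts, fill = "none",
              stroke = edge_color, `stroke-width` = "1.5")
    label_txt <- if (!is.na(ed$genes)) ed$genes
      else if (!is.null(rxn) && !is.null(rxn$rule)) format(rxn$rule)
      else NA_character_
    if (!is.na(label_txt)) {
      svg_child(g_edge, "text", label_txt,
                x = fmt_px(ed$label[1]), y = fmt_px(ed$label[2]),
                fill = style$color_gene_label, class = "wp-gene",
                `font-family` = style$font_family,
                `font-size` = fmt_px(style$font_size))
    }
    if (!is.null(rxn) && length(rxn$co_reactants) > 0L) {
      svg_child(g_edge, "text", paste(rxn$co_reactants, collapse = ", "),
                x = fmt_px(ed$label[1]), y = fmt_px(ed$label[2] + style$font_size),
                fill = style$color_coreactant, class = "wp-coreactant",
                `font-family` = style$font_family,
                `font-size` = fmt_px(style$font_size * 0.85))
    }
  }

  g_nodes <- svg_child(doc, "g", class = "wp-nodes")
  for (i in seq_len(nrow(mapdef$nodes))) {
    nd <- mapdef$nodes[i, ]
    abbr <- bare_abbr(nd$met)
    resolved <- nd$met %in% model$metabolites$ref
    g_node <- svg_child(g_nodes, "g", class = "wp-met-node",
                        `data-met` = nd$met)
    href <- gsub("{met}", nd$met, style$link_template, fixed = TRUE)
    a <- svg_child(g_node, "a", `xlink:href` = href)
    svg_child(a, "text", abbr, x = fmt_px(nd$x), y = fmt_px(nd$y),
              fill = "#000000", class = "wp-met",
              `font-family` = style$font_family,
              `font-size` = fmt_px(style$font_size),
              `text-anchor` = "middle")
    if (resolved) {
      card <- build_metabolite_card(
        model$metabolites[model$metabolites$ref == nd$met, ])
      svg_child(a, "title", paste(c(card$name,
                                    if (nzchar(card$formula)) card$formula,
                                    card$structure), collapse = " | "))
      # grayscale square: number of pathways the metabolite connects to
      count <- metabolite_pathway_count(model, aset, nd$met,
                                        level = mapdef$map$level,
                                        rxn_pathways = rxn_pathways)
      bin <- pathway_count_bin(count)
      svg_child(g_node, "rect", class = "wp-pcount",
                x = fmt_px(nd$x - 22), y = fmt_px(nd$y - 8),
                width = "8", height = "8",
                fill = if (is.na(bin)) "#FFFFFF" else style$grayscale_bins[bin],
                stroke = "#000000", `stroke-width` = "0.5",
                `data-count` = as.character(count))
      # transport-class circles
      classes <- transport_classes(model, abbr)
      offset <- 0
      for (cls in WP_TRANSPORT_CLASSES) {
        if (!cls %in% classes) next
        svg_child(g_node, "circle", class = paste0("wp-transport wp-transport-", cls),
                  cx = fmt_px(nd$x + 18 + offset), cy = fmt_px(nd$y - 4),
                  r = "4", fill = style$circle_colors[[cls]])
        offset <- offset + 10
      }
    }
  }

  g_boxes <- svg_child(doc, "g", class = "wp-boxes")
  for (i in seq_len(nrow(mapdef$boxes))) {
    bx <- mapdef$boxes[i, ]
    label <- if (bx$kind == "other") "other" else bx$target
    g_box <- svg_child(g_boxes, "g",
                       class = paste0("wp-box wp-box-", bx$kind))
    svg_child(g_box, "rect", x = fmt_px(bx$x), y = fmt_px(bx$y),
              width = "120", height = "24", fill = "#FFFFFF",
              stroke = "#000000", rx = "4")
    svg_child(g_box, "text", label, x = fmt_px(bx$x + 60),
              y = fmt_px(bx$y + 16), `text-anchor` = "middle",
              `font-family` = style$font_family,
              `font-size` = fmt_px(style$font_size * 0.85))
  }

  add_legend(doc, style, mapdef$map$canvas)
  doc
}

# the key appended to every map: edge colors, label colors, count squares,
# transport circles
add_legend <- function(doc, style, canvas) {
  x0 <- 10
  y0 <- canvas$height - 96
  g <- svg_child(doc, "g", class = "wp-legend")
  svg_child(g, "rect", x = fmt_px(x0 - 4), y = fmt_px(y0 - 14),
            width = "230", height = "104", fill = "#FFFFFF",
            stroke = "#888888", `stroke-width` = "0.5")
  svg_child(g, "text", "Legend", x = fmt_px(x0), y = fmt_px(y0),
            `font-family` = style$font_family, `font-size` = "11",
            `font-weight` = "bold")
  entry <- function(row, draw, label) {
    y <- y0 + 14 * row
    draw(y)
    svg_child(g, "text", label, x = fmt_px(x0 + 40), y = fmt_px(y + 4),
              `font-family` = style$font_family, `font-size` = "10")
  }
  entry(1, function(y) svg_child(g, "line", x1 = fmt_px(x0), y1 = fmt_px(y),
        x2 = fmt_px(x0 + 30), y2 = fmt_px(y),
        stroke = style$color_enzymatic_edge, `stroke-width` = "1.5"),
        "enzymatic reaction")
  entry(2, function(y) svg_child(g, "line", x1 = fmt_px(x0), y1 = fmt_px(y),
        x2 = fmt_px(x0 + 30), y2 = fmt_px(y),
        stroke = style$color_transport_edge, `stroke-width` = "1.5"),
        "transport reaction")
  entry(3, function(y) svg_child(g, "text", "gene", x = fmt_px(x0),
        y = fmt_px(y + 4), fill = style$color_gene_label,
        `font-family` = style$font_family, `font-size` = "10"),
        "gene (OR: |, AND: &)")
  entry(4, function(y) svg_child(g, "text", "co-reactant", x = fmt_px(x0),
        y = fmt_px(y + 4), fill = style$color_coreactant,
        `font-family` = style$font_family, `font-size` = "10"),
        "co-reactant")
  entry(5, function(y) {
    for (b in 1:4) {
      svg_child(g, "rect", x = fmt_px(x0 + (b - 1) * 9), y = fmt_px(y - 4),
                width = "8", height = "8", fill = style$grayscale_bins[b],
                stroke = "#000000", `stroke-width` = "0.5")
    }
  }, "pathways: 1 / 2 / 3 / 4+")
  entry(6, function(y) {
    svg_child(g, "circle", cx = fmt_px(x0 + 4), cy = fmt_px(y), r = "4",
              fill = style$circle_colors[["C_E"]])
    svg_child(g, "circle", cx = fmt_px(x0 + 16), cy = fmt_px(y), r = "4",
              fill = style$circle_colors[["M_C"]])
  }, "transport: cyt-extracell / mito-cyt")
  g
}

#' Write a rendered map to an SVG file
#' @param doc an `xml2::xml_document` from [render_map()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_map_svg <- function(doc, path) {
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Extract gene ids from a rendered map
#'
#' Parses an SVG produced by [render_map()] (or following its class
#' conventions) and returns the set of genes appearing in gene-labeled text
#' elements, splitting `|`/`&` labels into their constituent genes.
#'
#' @param svg_path path to the SVG file.
#' @return sorted character vector of gene ids.
#' @export
extract_map_genes <- function(svg_path) {
  doc <- tryCatch(xml2::read_xml(svg_path),
                  error = function(e) wp_parse_error(
                    sprintf("not well-formed XML: %s", svg_path)))
  nodes <- xml2::xml_find_all(
    doc, "//*[local-name() = 'text'][@class = 'wp-gene']")
  labels <- xml2::xml_text(nodes)
  genes <- unlist(strsplit(labels, "[|&]"), use.names = FALSE)
  sort_c(unique(wp_trim(genes[nzchar(wp_trim(genes))])))
}

# ---- linting --------------------------------------------------------------

lint_row <- function(severity, code, map_id, subject, message) {
  data.frame(severity = severity, code = code, map_id = map_id,
             subject = subject, message = message, stringsAsFactors = FALSE)
}

bind_lint_rows <- function(rows) {
  if (length(rows) == 0L) {
    return(data.frame(severity = character(0), code = character(0),
                      map_id = character(0), subject = character(0),
                      message = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Lint a map against the model and annotation tables
#'
#' Cross-references every element of a map definition with the metabolic
#' model and the master annotation table, the consistency pass applied to
#' draft maps before release. Issue codes (stable, machine-readable):
#' \describe{
#'   \item{MET_UNRESOLVED}{node metabolite not in the model (ERROR)}
#'   \item{REACTION_UNRESOLVED}{edge reaction not in the model (ERROR)}
#'   \item{DUP_NODE}{the same metabolite placed twice (ERROR)}
#'   \item{RULE_PARSE_ERROR}{a gene label override fails the rule grammar
#'     (ERROR)}
#'   \item{GENE_NOT_IN_ANNOTATIONS}{a gene on the map is absent from the
#'     annotation table (ERROR)}
#'   \item{GENE_LEVEL_MISMATCH}{a gene on the map is not annotated to this
#'     map's category at its level (WARNING)}
#'   \item{TERMINAL_RULE_VIOLATION}{a terminal's drawn boxes/transport
#'     disagree with [classify_terminal()] (WARNING)}
#'   \item{ORPHAN_NODE}{a placed node with no incident edge (WARNING)}
#' }
#'
#' @param mapdef a `map_definition`.
#' @param model a `metabolic_model`.
#' @param aset an `annotation_set`.
#' @param box_threshold terminal-box threshold, see [classify_terminal()].
#' @param rxn_pathways optional explicit reaction-to-pathway table; defaults
#'   to the map's own `reactions` list when present.
#' @return an object of class `lint_report`: a data frame with columns
#'   severity, code, map_id, subject, message (zero rows iff fully
#'   consistent).
#' @export
lint_map <- function(mapdef, model, aset, box_threshold = 2,
                     rxn_pathways = NULL) {
  stopifnot(inherits(mapdef, "map_definition"),
            inherits(model, "metabolic_model"),
            inherits(aset, "annotation_set"))
  if (is.null(rxn_pathways) && length(mapdef$reactions) > 0L) {
    rxn_pathways <- stats::setNames(
      rep(list(mapdef$map$category), length(mapdef$reactions)),
      mapdef$reactions)
  }
  mid <- mapdef$map$id
  rows <- list()
  add <- function(severity, code, subject, message) {
    rows[[length(rows) + 1L]] <<- lint_row(severity, code, mid, subject, message)
  }

  # unresolved references
  pend <- resolve_map_refs(mapdef, model)
  for (i in seq_len(nrow(pend))) {
    add(pend$severity[i], pend$code[i], pend$subject[i], pend$message[i])
  }

  # duplicate nodes
  dup <- unique(mapdef$nodes$met[duplicated(mapdef$nodes$met)])
  for (d in dup) add("ERROR", "DUP_NODE", d, sprintf("metabolite %s placed more than once", d))

  # collect map genes: resolved reaction rules plus label overrides
  map_genes <- character(0)
  for (ed in mapdef$edges) {
    if (!is.na(ed$genes)) {
      parsed <- tryCatch(parse_gene_rule(ed$genes), error = function(e) e)
      if (inherits(parsed, "error")) {
        add("ERROR", "RULE_PARSE_ERROR", ed$reaction,
            sprintf("gene label '%s' does not parse: %s", ed$genes,
                    conditionMessage(parsed)))
      } else {
        map_genes <- c(map_genes, rule_genes(parsed))
      }
    } else {
      rxn <- model$reactions[[ed$reaction]]
      if (!is.null(rxn)) map_genes <- c(map_genes, rule_genes(rxn$rule))
    }
  }
  map_genes <- unique(map_genes)

  # cross-reference against the master table
  lvl_col <- LEVEL_COLS[mapdef$map$level]
  for (g in sort_c(setdiff(map_genes, aset$universe))) {
    add("ERROR", "GENE_NOT_IN_ANNOTATIONS", g,
        sprintf("gene %s on map %s is not in the annotation table", g, mid))
  }
  for (g in sort_c(intersect(map_genes, aset$universe))) {
    cats <- aset$records[[lvl_col]][aset$records$gene_id == g]
    if (!mapdef$map$category %in% cats) {
      add("WARNING", "GENE_LEVEL_MISMATCH", g,
          sprintf("gene %s is not annotated to '%s' at level %d",
                  g, mapdef$map$category, mapdef$map$level))
    }
  }

  # orphan nodes: no incident edge displays this metabolite
  incident <- unique(unlist(lapply(mapdef$edges, function(ed) {
    rxn <- model$reactions[[ed$reaction]]
    if (is.null(rxn)) character(0) else reaction_met_refs(rxn)
  }), use.names = FALSE))
  for (m in mapdef$nodes$met) {
    if (!m %in% model$metabolites$ref) next  # already MET_UNRESOLVED
    if (!m %in% incident) {
      add("WARNING", "ORPHAN_NODE", m,
          sprintf("node %s has no incident edge on map %s", m, mid))
    }
  }

  # terminal-rule conformance
  terminals <- mapdef$nodes$met[mapdef$nodes$terminal]
  for (m in terminals) {
    if (!m %in% model$metabolites$ref) next  # already MET_UNRESOLVED
    cls <- classify_terminal(model, aset, mapdef, m,
                             box_threshold = box_threshold,
                             rxn_pathways = rxn_pathways)
    drawn_targets <- mapdef$boxes$target[mapdef$boxes$kind == "pathway"]
    has_other_box <- any(mapdef$boxes$kind == "other" &
                           (is.na(mapdef$boxes$met) | mapdef$boxes$met == m))
    incident_transport <- any(vapply(mapdef$edges, function(ed) {
      rxn <- model$reactions[[ed$reaction]]
      !is.null(rxn) && rxn$rtype == "transport" && met_in_reaction(rxn, m)
    }, logical(1)))
    viol <- NULL
    if (cls$kind == "PATHWAY_BOXES" &&
        !any(cls$pathways %in% drawn_targets)) {
      viol <- sprintf("terminal %s connects to %s but no pathway box is drawn",
                      m, paste(cls$pathways, collapse = "; "))
    } else if (cls$kind == "TRANSPORT_ENDPOINT" && !incident_transport) {
      viol <- sprintf("terminal %s should end in a transport but none is drawn", m)
    } else if (cls$kind == "OTHER_BOX" && !has_other_box) {
      viol <- sprintf("terminal %s needs an 'other' box (reactions not mapped yet)", m)
    } else if (cls$kind == "LINK_ONLY" &&
               any(cls$pathways %in% drawn_targets)) {
      viol <- sprintf("terminal %s connects to %d pathways; boxes should be suppressed",
                      m, length(cls$pathways))
    }
    if (!is.null(viol)) add("WARNING", "TERMINAL_RULE_VIOLATION", m, viol)
  }

  report <- bind_lint_rows(rows)
  class(report) <- c("lint_report", class(report))
  report
}

#' @export
print.lint_report <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("<lint_report> clean: no issues\n")
  } else {
    cat(sprintf("<lint_report> %d issue(s): %d ERROR, %d WARNING\n",
                nrow(x), sum(x$severity == "ERROR"),
                sum(x$severity == "WARNING")))
    print.data.frame(x, row.names = FALSE)
  }
  invisible(x)
}

#' Write a lint report as TSV
#' @param report a `lint_report`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_lint_report <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
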