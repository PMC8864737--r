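test_that("map definitions load, validate, and resolve references", {
  fx <- toy_fixture()
  mi <- fx$manifest$maps[[1]]
  md <- load_map_definition(file.path(fx$dir, mi$file), model = fx$model)
  expect_s3_class(md, "map_definition")
  expect_identical(md$map$id, mi$id)
  expect_equal(nrow(md$nodes), fx$spec$chain_len)
  expect_length(md$edges, fx$spec$chain_len - 1L)
  expect_equal(nrow(attr(md, "pending_issues")), 0L)

  # corrupt a node reference: strict load fails, lenient carries the issue
  doc <- yaml::read_yaml(file.path(fx$dir, mi$file))
  doc$nodes[[2]]$met <- "xxx[c]"
  bad <- tempfile(fileext = ".yaml")
  yaml::write_yaml(doc, bad)
  expect_error(load_map_definition(bad, model = fx$model, strict = TRUE),
               class = "wp_reference_error")
  lenient <- load_map_definition(bad, model = fx$model, strict = FALSE)
  expect_identical(attr(lenient, "pending_issues")$code, "MET_UNRESOLVED")

  # malformed documents are parse errors
  nox <- tempfile(fileext = ".yaml")
  writeLines("nodes:\n  - met: a", nox)
  expect_error(load_map_definition(nox), class = "wp_parse_error")
})

test_that("rendering follows the visual conventions and is deterministic", {
  fx <- toy_fixture()
  # the transport-endpoint map carries chain_len-1 enzymatic + 1 transport edge
  tmap <- Filter(function(t) t$kind == "TRANSPORT_ENDPOINT",
                 fx$manifest$terminals)[[1]]
  md <- load_map_definition(file.path(fx$dir, tmap$file), model = fx$model)
  doc <- render_map(md, fx$model, fx$aset)
  style <- wp_style()

  transport_strokes <- xml2::xml_find_all(doc, sprintf(
    "//*[local-name()='polyline'][@stroke='%s']", style$color_transport_edge))
  enzymatic_strokes <- xml2::xml_find_all(doc, sprintf(
    "//*[local-name()='polyline'][@stroke='%s']", style$color_enzymatic_edge))
  # one legend line per color also uses the stroke; count polylines only
  expect_length(transport_strokes, 1L)
  expect_length(enzymatic_strokes, fx$spec$chain_len - 1L)

  # exactly one legend group, and the SVG is well-formed by construction
  svg <- tempfile(fileext = ".svg")
  write_map_svg(doc, svg)
  reread <- xml2::read_xml(svg)
  expect_length(xml2::xml_find_all(
    reread, "//*[local-name()='g'][@class='wp-legend']"), 1L)

  # deterministic: rendering twice is byte-identical
  svg2 <- tempfile(fileext = ".svg")
  write_map_svg(render_map(md, fx$model, fx$aset), svg2)
  expect_identical(readLines(svg), readLines(svg2))

  # unresolved references in strict mode refuse to render
  bad <- md
  bad$nodes$met[2] <- "xxx[c]"
  expect_error(render_map(bad, fx$model, fx$aset, strict = TRUE),
               class = "wp_reference_error")
  expect_s3_class(render_map(bad, fx$model, fx$aset, strict = FALSE),
                  "xml_document")
})

test_that("OR/AND gene labels render as single flat strings", {
  genes <- c("pck-1", "pck-2", "pck-3", "pdha-1", "pdhb-1")
  mets <- data.frame(met_id = c("pep", "oaa", "pyr", "accoa"),
                     compartment = "c")
  rxns <- rbind(
    tiny_rxn("R1", "pep[c] <=> oaa[c]", gene_rule = "pck-1|pck-2|pck-3"),
    tiny_rxn("R2", "pyr[c] -> accoa[c]", gene_rule = "pdha-1&pdhb-1",
             co_reactants = "pyr[c]"))
  paths <- write_tiny_model(genes, mets, rxns)
  model <- load_model(paths$genes, paths$metabolites, paths$reactions)
  aset <- load_annotations(write_tiny_annotations(data.frame(
    gene_id = genes, level1 = "carbohydrates", level2 = "glycolysis",
    level3 = "", level4 = "")))
  ydoc <- list(
    map = list(id = "gly", title = "glycolysis", level = 2,
               category = "glycolysis",
               canvas = list(width = 400, height = 300)),
    nodes = list(list(met = "pep[c]", x = 50, y = 100),
                 list(met = "oaa[c]", x = 200, y = 100),
                 list(met = "pyr[c]", x = 50, y = 200),
                 list(met = "accoa[c]", x = 200, y = 200)),
    edges = list(list(reaction = "R1", waypoints = list(c(70, 95), c(180, 95))),
                 list(reaction = "R2", waypoints = list(c(70, 195), c(180, 195)))))
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(ydoc, path)
  md <- load_map_definition(path, model = model)
  svg <- tempfile(fileext = ".svg")
  write_map_svg(render_map(md, model, aset), svg)

  labels <- xml2::xml_text(xml2::xml_find_all(
    xml2::read_xml(svg), "//*[local-name()='text'][@class='wp-gene']"))
  expect_setequal(labels, c("pck-1|pck-2|pck-3", "pdha-1&pdhb-1"))
  # extraction splits them back into constituent genes
  expect_identical(extract_map_genes(svg), sort(genes))
  # co-reactant label present in its own class
  co <- xml2::xml_text(xml2::xml_find_all(
    xml2::read_xml(svg), "//*[local-name()='text'][@class='wp-coreactant']"))
  expect_identical(co, "pyr[c]")
})

test_that("extract_map_genes round-trips every fixture map", {
  fx <- toy_fixture()
  for (mi in fx$manifest$maps) {
    md <- load_map_definition(file.path(fx$dir, mi$file), model = fx$model)
    svg <- tempfile(fileext = ".svg")
    write_map_svg(render_map(md, fx$model, fx$aset), svg)
    # the genes on the rendered map are exactly the union over its reactions
    expected <- sort(unique(unlist(
      lapply(vapply(md$edges, function(e) e$reaction, ""),
             function(rid) genes_of_reaction(fx$model, rid)))))
    expect_identical(extract_map_genes(svg), expected, info = mi$id)
    expect_identical(extract_map_genes(svg), unlist(mi$genes), info = mi$id)
  }
  # degenerate inputs
  empty_svg <- tempfile(fileext = ".svg")
  writeLines('<svg xmlns="http://www.w3.org/2000/svg"/>', empty_svg)
  expect_length(extract_map_genes(empty_svg), 0L)
  not_xml <- tempfile()
  writeLines("not xml <<<", not_xml)
  expect_error(extract_map_genes(not_xml), class = "wp_parse_error")
})

test_that("metabolite cards stack name, formula and structure or placeholder", {
  fx <- toy_fixture()
  mets <- fx$model$metabolites
  with_img <- mets[mets$structure_ref != "NONE", ][1, ]
  plain <- mets[mets$structure_ref == "NONE", ][1, ]

  card <- build_metabolite_card(with_img)
  expect_identical(card$structure, with_img$structure_ref)
  expect_true(card$has_structure)

  card <- build_metabolite_card(plain)
  expect_identical(card$structure, "Structure not available")
  expect_false(card$has_structure)

  # a dangling image reference degrades to the placeholder
  card <- build_metabolite_card(with_img, image_dir = tempfile("noimg"))
  expect_identical(card$structure, "Structure not available")
  expect_true(card$missing_file)

  # empty formula renders without error
  card <- build_metabolite_card(list(met_id = "x", name = "xylose",
                                     formula = "", structure_ref = "NONE"))
  expect_identical(card$formula, "")
})

test_that("clean fixture maps lint clean", {
  fx <- toy_fixture()
  for (mi in fx$manifest$maps) {
    md <- load_map_definition(file.path(fx$dir, mi$file), model = fx$model)
    report <- lint_map(md, fx$model, fx$aset)
    expect_equal(nrow(report), 0L, info = mi$id)
  }
})

test_that("each planted mutation yields exactly its issue code", {
  fx <- toy_fixture()
  muts <- lint_mutations(fx)
  for (code in names(muts)) {
    report <- lint_mutated_map(fx, muts[[code]])
    expect_identical(unique(report$code), code, info = code)
    expect_equal(nrow(report), 1L, info = code)
  }
  # severities follow the contract
  expect_identical(lint_mutated_map(fx, muts$GENE_NOT_IN_ANNOTATIONS)$severity, "ERROR")
  expect_identical(lint_mutated_map(fx, muts$TERMINAL_RULE_VIOLATION)$severity, "WARNING")
})
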