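# a small hand-built model: one "his"-like chain with a c<->e exporter, one
# metabolite shuttled between mitochondria and cytosol, one untransported
make_conn_model <- function(shuffle = FALSE) {
  genes <- c("hisd-1", "hisd-2", "amx-1", "slc-1")
  mets <- data.frame(
    met_id = c("his", "hsn", "hsn", "akg", "akg", "oaa"),
    compartment = c("c", "c", "e", "c", "m", "c"))
  rxns <- rbind(
    tiny_rxn("R1", "his[c] -> hsn[c]", gene_rule = "hisd-1|hisd-2"),
    tiny_rxn("R2", "akg[c] -> oaa[c]", gene_rule = "amx-1"),
    tiny_rxn("T1", "hsn[c] -> hsn[e]", rtype = "transport", gene_rule = "slc-1"),
    tiny_rxn("T2", "akg[c] <=> akg[m]", rtype = "transport")
  )
  if (shuffle) rxns <- rxns[c(3, 1, 4, 2), ]
  paths <- write_tiny_model(genes, mets, rxns)
  load_model(paths$genes, paths$metabolites, paths$reactions)
}

conn_aset <- function() {
  load_annotations(write_tiny_annotations(data.frame(
    gene_id = c("hisd-1", "hisd-2", "amx-1", "slc-1"),
    level1 = "amino acids",
    level2 = c("histidine degradation", "histidine degradation",
               "glutamate metabolism", "histidine degradation"),
    level3 = "", level4 = "")))
}

test_that("transport_classes reads the legend pairs only", {
  model <- make_conn_model()
  expect_identical(transport_classes(model, "hsn"), "C_E")
  expect_identical(transport_classes(model, "akg"), "M_C")
  expect_length(transport_classes(model, "his"), 0L)
  expect_error(transport_classes(model, "nope"), class = "wp_lookup_error")

  # both classes at once
  genes <- "g1"
  mets <- data.frame(met_id = rep("x", 3), compartment = c("c", "e", "m"))
  rxns <- rbind(tiny_rxn("T1", "x[c] -> x[e]", rtype = "transport"),
                tiny_rxn("T2", "x[m] -> x[c]", rtype = "transport"))
  paths <- write_tiny_model(genes, mets, rxns)
  both <- load_model(paths$genes, paths$metabolites, paths$reactions)
  expect_identical(transport_classes(both, "x"), c("C_E", "M_C"))
})

test_that("transport_classes is invariant under reaction reordering", {
  a <- make_conn_model(shuffle = FALSE)
  b <- make_conn_model(shuffle = TRUE)
  for (met in c("hsn", "akg", "his", "oaa")) {
    expect_identical(transport_classes(a, met), transport_classes(b, met))
  }
})

test_that("pathway counts come from gene annotations, self-edges excluded", {
  model <- make_conn_model()
  aset <- conn_aset()
  # hsn: R1 (histidine degradation) + T1 is a self-edge -> 1 pathway
  expect_equal(metabolite_pathway_count(model, aset, "hsn", level = 2), 1L)
  # akg: R2 only (T2 self-edge ignored)
  expect_equal(metabolite_pathway_count(model, aset, "akg", level = 2), 1L)
  expect_equal(metabolite_pathway_count(model, aset, "oaa", level = 2), 1L)
  expect_error(metabolite_pathway_count(model, aset, "nope"),
               class = "wp_lookup_error")

  # an explicit reaction->pathway table wins over gene inference
  expect_equal(metabolite_pathway_count(
    model, aset, "akg", level = 2,
    rxn_pathways = list(R2 = c("glutamate metabolism", "TCA cycle"))), 2L)
})

test_that("fixture pathway counts equal the generator's planted truth", {
  fx <- toy_fixture()
  truth <- fx$manifest$met_pathway_counts
  rxn_pathways <- fx$manifest$rxn_pathways
  for (abbr in names(truth)) {
    expect_equal(
      metabolite_pathway_count(fx$model, fx$aset, abbr, level = 4,
                               rxn_pathways = rxn_pathways),
      truth[[abbr]], info = abbr)
  }
  # at least one metabolite planted in exactly 2 pathways exists
  expect_true(any(unlist(truth) == 2L))
})

test_that("classify_terminal reproduces every archetype on the fixtures", {
  fx <- toy_fixture()
  for (t in fx$manifest$terminals) {
    md <- load_map_definition(file.path(fx$dir, t$file), model = fx$model)
    cls <- classify_terminal(fx$model, fx$aset, md, t$met,
                             rxn_pathways = fx$manifest$rxn_pathways)
    expect_identical(cls$kind, t$kind, info = t$map_id)
    if (t$kind %in% c("PATHWAY_BOXES", "LINK_ONLY")) {
      expect_setequal(cls$pathways, unlist(t$pathways))
    }
    # the pathway's defining start metabolite
    start <- md$nodes$met[md$nodes$main_terminus][1]
    expect_identical(
      classify_terminal(fx$model, fx$aset, md, start,
                        rxn_pathways = fx$manifest$rxn_pathways)$kind,
      "MAIN_TERMINUS")
    # non-terminal interior nodes are a contract violation
    interior <- md$nodes$met[!md$nodes$terminal][1]
    expect_error(classify_terminal(fx$model, fx$aset, md, interior),
                 class = "wp_contract_error")
  }
})

test_that("the box threshold is configurable: a hub can regain its boxes", {
  fx <- toy_fixture()
  hub <- Filter(function(t) t$kind == "LINK_ONLY", fx$manifest$terminals)[[1]]
  md <- load_map_definition(file.path(fx$dir, hub$file), model = fx$model)
  rp <- fx$manifest$rxn_pathways
  expect_identical(
    classify_terminal(fx$model, fx$aset, md, hub$met, box_threshold = 2,
                      rxn_pathways = rp)$kind, "LINK_ONLY")
  expect_identical(
    classify_terminal(fx$model, fx$aset, md, hub$met, box_threshold = 5,
                      rxn_pathways = rp)$kind, "PATHWAY_BOXES")
})
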