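test_that("gene rule grammar parses OR-of-AND with & binding tighter than |", {
  r <- parse_gene_rule("pck-1|pck-2|pck-3")
  expect_length(r, 3L)
  expect_equal(unclass(r), list("pck-1", "pck-2", "pck-3"))

  r <- parse_gene_rule("pdha-1&pdhb-1")
  expect_length(r, 1L)
  expect_equal(r[[1]], c("pdha-1", "pdhb-1"))

  expect_equal(unclass(parse_gene_rule("metr-1")), list("metr-1"))

  # mixed rule: AND chains are the OR alternatives
  r <- parse_gene_rule("a&b|c")
  expect_equal(unclass(r), list(c("a", "b"), "c"))

  # whitespace around separators is ignored, tokens kept verbatim
  r <- parse_gene_rule("  pck-1 | pck-2 & pck-3 ")
  expect_equal(unclass(r), list("pck-1", c("pck-2", "pck-3")))
})

test_that("malformed gene rules are rejected with positional messages", {
  expect_error(parse_gene_rule("a||b"), class = "wp_parse_error")
  expect_error(parse_gene_rule("a||b"), "position 2")
  expect_error(parse_gene_rule("a|b|"), class = "wp_parse_error")
  expect_error(parse_gene_rule("a&"), class = "wp_parse_error")
  expect_error(parse_gene_rule("&a"), class = "wp_parse_error")
  expect_error(parse_gene_rule("   "), class = "wp_parse_error")
  expect_error(parse_gene_rule("(a|b)&c"), class = "wp_parse_error")
})

test_that("parse o format is the identity on canonical rule strings", {
  set.seed(7)
  genes <- sprintf("%s-%d", c("abc", "def", "ghi", "jkl"), 1:4)
  for (rep in 1:50) {
    n_chain <- sample(1:4, 1)
    chains <- vapply(seq_len(n_chain), function(i) {
      paste(sample(genes, sample(1:3, 1)), collapse = "&")
    }, "")
    canonical <- paste(chains, collapse = "|")
    expect_identical(format(parse_gene_rule(canonical)), canonical)
  }
})

test_that("load_model round-trips the generated fixture and validates counts", {
  fx <- toy_fixture()
  model <- fx$model
  expect_s3_class(model, "metabolic_model")
  expect_identical(nrow(model$genes), fx$manifest$counts$genes)
  expect_identical(nrow(model$metabolites), fx$manifest$counts$metabolite_rows)
  expect_identical(length(model$reactions), fx$manifest$counts$reactions)
  # every transport reaction moves one abbreviation between two compartments
  for (rxn in model$reactions) {
    if (rxn$rtype != "transport") next
    shared <- intersect(rxn$substrates$met, rxn$products$met)
    expect_true(length(shared) >= 1L)
    comps <- unique(c(rxn$substrates$compartment[rxn$substrates$met %in% shared],
                      rxn$products$compartment[rxn$products$met %in% shared]))
    expect_true(length(comps) >= 2L)
  }
})

test_that("load_model rejects broken inputs with classed errors", {
  mets <- data.frame(met_id = c("pep", "oaa"), compartment = "c")
  paths <- write_tiny_model(c("pck-1"), mets,
                            tiny_rxn("R1", "pep[c] -> xxx[c]", gene_rule = "pck-1"))
  expect_error(load_model(paths$genes, paths$metabolites, paths$reactions),
               class = "wp_reference_error")

  # duplicate (id, compartment)
  mets2 <- data.frame(met_id = c("pep", "pep"), compartment = c("c", "c"))
  paths2 <- write_tiny_model("pck-1", mets2, tiny_rxn("R1", "pep[c] -> pep[c]"))
  expect_error(load_model(paths2$genes, paths2$metabolites, paths2$reactions),
               class = "wp_schema_error")

  # unresolved gene in a rule
  paths3 <- write_tiny_model("pck-1", mets,
                             tiny_rxn("R1", "pep[c] -> oaa[c]", gene_rule = "nope-9"))
  expect_error(load_model(paths3$genes, paths3$metabolites, paths3$reactions),
               class = "wp_reference_error")

  # missing column is a schema error naming the column
  bad <- tempfile(fileext = ".tsv")
  writeLines("gene_id\npck-1", bad)
  expect_error(load_model(bad, paths$metabolites, paths$reactions),
               "aliases", class = "wp_schema_error")

  # a "transport" that does not change compartment
  paths4 <- write_tiny_model("pck-1", mets,
                             tiny_rxn("R1", "pep[c] -> oaa[c]", rtype = "transport"))
  expect_error(load_model(paths4$genes, paths4$metabolites, paths4$reactions),
               class = "wp_schema_error")
})

test_that("genes_of_reaction returns the flat union of the rule", {
  genes <- c("pck-1", "pck-2", "pck-3", "a", "b", "c")
  mets <- data.frame(met_id = c("pep", "oaa"), compartment = "c")
  mets2 <- data.frame(met_id = "his", compartment = c("c", "e"))
  rxns <- rbind(
    tiny_rxn("R1", "pep[c] -> oaa[c]", gene_rule = "pck-1|pck-2|pck-3"),
    tiny_rxn("R2", "oaa[c] -> pep[c]", gene_rule = "a&b|c"),
    tiny_rxn("T1", "his[c] <=> his[e]", rtype = "transport")
  )
  paths <- write_tiny_model(genes, rbind(mets, mets2), rxns)
  model <- load_model(paths$genes, paths$metabolites, paths$reactions)
  expect_setequal(genes_of_reaction(model, "R1"), c("pck-1", "pck-2", "pck-3"))
  expect_setequal(genes_of_reaction(model, "R2"), c("a", "b", "c"))
  expect_length(genes_of_reaction(model, "T1"), 0L)  # orphan transport
  expect_error(genes_of_reaction(model, "R999"), class = "wp_lookup_error")
})

test_that("aliases resolve through the model", {
  dir <- tempfile("alias")
  dir.create(dir)
  utils::write.table(
    data.frame(gene_id = c("acdh-1", "pck-1"), aliases = c("K01.1,ACDH1", "")),
    file.path(dir, "genes.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(met_id = "pep", compartment = "c", name = "pep", formula = "",
               structure_ref = "NONE"),
    file.path(dir, "metabolites.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(tiny_rxn("R1", "pep[c] -> pep[c]"),
    file.path(dir, "reactions.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  model <- load_model(file.path(dir, "genes.tsv"),
                      file.path(dir, "metabolites.tsv"),
                      file.path(dir, "reactions.tsv"))
  al <- model_aliases(model)
  expect_identical(unname(al["K01.1"]), "acdh-1")
  expect_identical(unname(al["ACDH1"]), "acdh-1")
})
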