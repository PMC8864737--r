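# Shared fixtures, built in code and memoised for the test run.

.wp_cache <- new.env(parent = emptyenv())

wp_cached <- function(key, build) {
  if (!exists(key, envir = .wp_cache)) assign(key, build(), envir = .wp_cache)
  get(key, envir = .wp_cache)
}

# small default fixture set (100 genes, 4 maps, planted enrichment)
toy_fixture <- function() {
  wp_cached("toy", function() {
    spec <- toy_model_spec(seed = 101L,
                           planted_genes = c("alh-2" = 3L))
    dir <- file.path(tempdir(), "wp-toy-fixture")
    manifest <- generate_toy_model(spec, dir)
    list(spec = spec, dir = dir, manifest = manifest,
         model = load_model(file.path(dir, "genes.tsv"),
                            file.path(dir, "metabolites.tsv"),
                            file.path(dir, "reactions.tsv")),
         aset = load_annotations(file.path(dir, "annotations.tsv")))
  })
}

# reference-shaped fixture (1314 genes, 10/61/79/85 categories, 62 maps)
master_fixture <- function() {
  wp_cached("master", function() {
    spec <- master_shaped_spec(seed = 42L)
    dir <- file.path(tempdir(), "wp-master-fixture")
    manifest <- generate_toy_model(spec, dir)
    list(spec = spec, dir = dir, manifest = manifest,
         aset = load_annotations(file.path(dir, "annotations.tsv")))
  })
}

# write a tiny hand-built model into a tempdir; returns the three paths.
# genes: character vector; mets: data.frame(met_id, compartment, ...);
# rxns: data.frame(rxn_id, equation, rtype, gene_rule, co_reactants)
write_tiny_model <- function(genes, mets, rxns, dir = tempfile("tiny")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gdf <- data.frame(gene_id = genes, aliases = "", stringsAsFactors = FALSE)
  if (is.null(mets$name)) mets$name <- paste("met", mets$met_id)
  if (is.null(mets$formula)) mets$formula <- ""
  if (is.null(mets$structure_ref)) mets$structure_ref <- "NONE"
  paths <- list(genes = file.path(dir, "genes.tsv"),
                metabolites = file.path(dir, "metabolites.tsv"),
                reactions = file.path(dir, "reactions.tsv"))
  utils::write.table(gdf, paths$genes, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(mets[, c("met_id", "compartment", "name", "formula",
                              "structure_ref")],
                     paths$metabolites, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(rxns, paths$reactions, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths
}

tiny_rxn <- function(rxn_id, equation, rtype = "enzymatic", gene_rule = "",
                     co_reactants = "") {
  data.frame(rxn_id = rxn_id, equation = equation, rtype = rtype,
             gene_rule = gene_rule, co_reactants = co_reactants,
             stringsAsFactors = FALSE)
}

# write an annotation TSV from a data.frame(gene_id, level1..level4)
write_tiny_annotations <- function(records, path = tempfile(fileext = ".tsv")) {
  utils::write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# ---- planted lint mutations ------------------------------------------------
# Each mutation takes a clean fixture map (as a YAML document list) and
# corrupts it in exactly one way; `code` is the single issue the linter must
# report. `map_idx` picks the archetype map the mutation needs.

lint_mutations <- function(fx) {
  bg_met <- names(fx$manifest$met_pathway_counts)
  # a resolved metabolite that is on no map edge: background mets sit at the
  # end of the metabolite table
  orphan_met <- utils::tail(fx$model$metabolites$ref, 1L)
  other_leaf_gene <- local({
    # a gene annotated to a leaf that is not map-03's category
    cat3 <- fx$manifest$maps[[3]]$category
    recs <- fx$aset$records
    g <- recs$gene_id[recs$level4 != cat3]
    setdiff(g, recs$gene_id[recs$level4 == cat3])[1]
  })
  list(
    GENE_NOT_IN_ANNOTATIONS = list(map_idx = 3L, mutate = function(doc) {
      doc$edges[[2]]$genes <- "acdh-9x"
      doc
    }),
    GENE_LEVEL_MISMATCH = list(map_idx = 3L, mutate = function(doc) {
      doc$edges[[2]]$genes <- other_leaf_gene
      doc
    }),
    MET_UNRESOLVED = list(map_idx = 3L, mutate = function(doc) {
      doc$nodes[[2]]$met <- "xxx[c]"
      doc
    }),
    REACTION_UNRESOLVED = list(map_idx = 3L, mutate = function(doc) {
      doc$edges[[2]]$reaction <- "R9999"
      # keep the explicit pathway list pointing at real reactions only
      doc$reactions <- setdiff(unlist(doc$reactions), "R9999")
      doc
    }),
    RULE_PARSE_ERROR = list(map_idx = 3L, mutate = function(doc) {
      doc$edges[[2]]$genes <- "a||b"
      doc
    }),
    TERMINAL_RULE_VIOLATION = list(map_idx = 1L, mutate = function(doc) {
      doc$boxes <- list()  # drop the required pathway box
      doc
    }),
    ORPHAN_NODE = list(map_idx = 3L, mutate = function(doc) {
      doc$nodes <- c(doc$nodes, list(list(met = orphan_met, x = 50, y = 300)))
      doc
    }),
    DUP_NODE = list(map_idx = 3L, mutate = function(doc) {
      doc$nodes <- c(doc$nodes, list(list(met = doc$nodes[[2]]$met,
                                          x = 60, y = 300)))
      doc
    })
  )
}

# apply one mutation to a fixture map and lint it
lint_mutated_map <- function(fx, mutation) {
  src <- file.path(fx$dir, fx$manifest$maps[[mutation$map_idx]]$file)
  doc <- yaml::read_yaml(src)
  doc <- mutation$mutate(doc)
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(doc, path)
  md <- load_map_definition(path, model = fx$model, strict = FALSE)
  lint_map(md, fx$model, fx$aset)
}
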