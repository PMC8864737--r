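# Deterministic synthetic fixture generator.
#
# Generates a complete input set - model tables, a 4-level annotation table,
# map definitions and PEA gene lists - with every truth planted and recorded
# in a manifest, so each module is testable end-to-end without any
# downloads. The generator emulates the statistical shape of the reference
# annotation table (category counts per level, the fraction of
# multi-pathway genes, an iCEL1314-sized universe when asked) and the
# structural conventions of the maps (reaction chains with a defining start
# metabolite and a terminal exercising each terminal-metabolite archetype).
# Generation is a pure function of the spec: identical specs give
# byte-identical files.

# run expr under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

# split total into n positive integer parts (n <= total)
distribute_among <- function(total, n) {
  base <- rep(total %/% n, n)
  extra <- total %% n
  if (extra > 0L) base[seq_len(extra)] <- base[seq_len(extra)] + 1L
  base
}

WP_L1_NAMES <- c("amino acids", "carbohydrates", "cofactors and vitamins",
                 "energy", "lipids", "nucleotides", "one-carbon cycle",
                 "reactive oxygen species", "other amino acids", "other")

# deterministic stream of unique pathway-ish names (uses the current RNG)
make_namer <- function() {
  subs <- c("alanine", "arginine", "aspartate", "cysteine", "glutamate",
            "glycine", "histidine", "isoleucine", "leucine", "lysine",
            "methionine", "phenylalanine", "proline", "serine", "threonine",
            "tryptophan", "tyrosine", "valine", "propionate", "butyrate",
            "acetate", "folate", "biotin", "riboflavin", "thiamine",
            "pyridoxine", "cobalamin", "ascorbate", "glucose", "fructose",
            "galactose", "trehalose", "glycogen", "chitin", "cholesterol",
            "sphingolipid", "ascaroside", "collagen", "heme", "purine",
            "pyrimidine", "urea", "glyoxylate", "pantothenate", "mevalonate",
            "ceramide", "inositol", "choline", "taurine", "carnitine")
  procs <- c("degradation", "biosynthesis", "metabolism", "salvage",
             "cycle", "remodeling", "oxidation", "elongation")
  pool <- sample(as.vector(outer(subs, procs, paste)))
  i <- 0L
  function() {
    i <<- i + 1L
    if (i <= length(pool)) pool[i] else sprintf("pathway %03d", i)
  }
}

# grow a category tree level by level; returns a data.frame with one row per
# level-4 leaf and columns level1..level4 (names globally unique except where
# a non-subdivided branch carries its name down = redundancy)
build_category_tree <- function(n_cats, namer) {
  n1 <- n_cats[1]
  l1 <- if (n1 <= length(WP_L1_NAMES)) WP_L1_NAMES[seq_len(n1)] else
    c(WP_L1_NAMES, sprintf("metabolic class %02d",
                           seq_len(n1 - length(WP_L1_NAMES))))
  df <- data.frame(level1 = l1, stringsAsFactors = FALSE)
  df$current <- df$level1
  for (k in 2:4) {
    target <- n_cats[k]
    gain <- target - nrow(df)
    col <- LEVEL_COLS[k]
    if (gain == 0L) {
      df[[col]] <- df$current
    } else {
      s <- min(gain, nrow(df))
      chosen <- sort(sample(nrow(df), s))
      gains <- distribute_among(gain, s)
      pieces <- vector("list", nrow(df))
      for (i in seq_len(nrow(df))) {
        row <- df[i, , drop = FALSE]
        if (i %in% chosen) {
          n_child <- gains[match(i, chosen)] + 1L
          kids <- vapply(seq_len(n_child), function(z) namer(), "")
          piece <- row[rep(1L, n_child), , drop = FALSE]
          piece[[col]] <- kids
        } else {
          piece <- row
          piece[[col]] <- row$current
        }
        pieces[[i]] <- piece
      }
      df <- do.call(rbind, pieces)
    }
    df$current <- df[[col]]
    rownames(df) <- NULL
  }
  df$current <- NULL
  df
}

# unique C. elegans-like gene ids ("tgn-12"), avoiding `reserved`
make_gene_ids <- function(n, reserved = character(0)) {
  cons <- c("b", "c", "d", "f", "g", "h", "k", "l", "m", "n",
            "p", "r", "s", "t", "v", "w", "y", "z")
  vows <- c("a", "e", "i", "o", "u")
  trip <- as.vector(outer(as.vector(outer(cons, vows, paste0)), cons, paste0))
  prefs <- sample(trip, min(length(trip), 400L))
  ids <- character(0)
  i <- 0L
  while (length(ids) < n) {
    i <- i + 1L
    id <- sprintf("%s-%d", prefs[((i - 1L) %% length(prefs)) + 1L],
                  ((i - 1L) %/% length(prefs)) + 1L)
    if (!id %in% reserved) ids <- c(ids, id)
  }
  ids
}

# unique BiGG-like metabolite abbreviations, avoiding `reserved`
make_met_abbrs <- function(n, reserved = character(0)) {
  out <- character(0)
  tries <- 0L
  while (length(out) < n) {
    tries <- tries + 1L
    len <- sample(3:5, 1L)
    tok <- paste(sample(c(letters, as.character(0:9)), len,
                        replace = TRUE, prob = c(rep(4, 26), rep(1, 10))), collapse = "")
    if (grepl("^[a-z]", tok) && !tok %in% reserved && !tok %in% out) {
      out <- c(out, tok)
    }
    if (tries > 100L * n) wp_domain_error("cannot generate enough metabolite ids")
  }
  out
}

#' Specify a synthetic toy model
#'
#' Declares the shape of a generated fixture set: universe size, metabolite
#' and reaction counts, the four per-level category counts, the fraction of
#' genes planted into more than one pathway, transport classes to plant,
#' the enriched category for PEA recovery tests, and the number of pathway
#' maps (each map exercises one terminal-metabolite archetype: the first
#' four maps get a pathway-box terminal, a transport endpoint, an "other"
#' box, and a hub terminal with five connections; further maps end in
#' "other" boxes).
#'
#' @param seed single integer; the only source of randomness.
#' @param n_genes,n_mets,n_reactions counts (n_mets counts metabolite table
#'   rows, i.e. compartmentalised species).
#' @param n_categories integer vector of length 4, non-decreasing: category
#'   counts at Levels 1-4.
#' @param multi_fraction target fraction of genes annotated to more than one
#'   pathway (planted exactly as `round(multi_fraction * n_genes)` genes).
#' @param planted_transport character vector over `c("C_E","M_C")`; one
#'   transportable metabolite is planted per entry.
#' @param enriched `NULL` or `list(n =, k =, N =)`: size of the planted
#'   level-4 enrichment target, genes of it put into the PEA input list, and
#'   the total number of metabolic hits in that list.
#' @param planted_genes named integer vector: extra genes planted with an
#'   exact number of distinct pathway assignments (e.g. `c("alh-2" = 4)`).
#' @param n_maps number of map definitions to generate (>= 4 to cover all
#'   terminal archetypes).
#' @param chain_len metabolites per map chain (>= 2).
#' @return an object of class `toy_model_spec`.
#' @export
toy_model_spec <- function(seed = 1L,
                           n_genes = 100L, n_mets = 60L, n_reactions = 80L,
                           n_categories = c(4L, 8L, 12L, 16L),
                           multi_fraction = 0.25,
                           planted_transport = c("C_E", "M_C"),
                           enriched = list(n = 10L, k = 10L, N = 20L),
                           planted_genes = NULL,
                           n_maps = 4L, chain_len = 4L) {
  spec <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
               n_mets = as.integer(n_mets), n_reactions = as.integer(n_reactions),
               n_categories = as.integer(n_categories),
               multi_fraction = multi_fraction,
               planted_transport = planted_transport,
               enriched = enriched, planted_genes = planted_genes,
               n_maps = as.integer(n_maps), chain_len = as.integer(chain_len))
  if (length(spec$n_categories) != 4L || any(spec$n_categories < 1L) ||
      any(diff(spec$n_categories) < 0L)) {
    wp_domain_error("n_categories must be 4 non-decreasing positive counts")
  }
  if (spec$multi_fraction < 0 || spec$multi_fraction > 1) {
    wp_domain_error("multi_fraction must be in [0, 1]")
  }
  if (!all(spec$planted_transport %in% WP_TRANSPORT_CLASSES)) {
    wp_domain_error("planted_transport entries must be 'C_E' or 'M_C'")
  }
  if (spec$n_maps < 1L || spec$chain_len < 2L) {
    wp_domain_error("need n_maps >= 1 and chain_len >= 2")
  }
  n4 <- spec$n_categories[4]
  if (n4 < spec$n_maps + 1L) {
    wp_domain_error("need at least n_maps + 1 level-4 categories")
  }
  if (spec$n_maps >= 4L && n4 < 7L) {
    wp_domain_error("hub terminal archetype needs at least 7 level-4 categories")
  }
  n_enr <- if (is.null(spec$enriched)) 0L else as.integer(spec$enriched$n)
  if (!is.null(spec$enriched)) {
    e <- spec$enriched
    if (e$k > e$n || e$N < e$k || e$n > spec$n_genes) {
      wp_domain_error("enriched spec infeasible: need k <= n, k <= N, n <= n_genes")
    }
  }
  if (spec$n_genes < n_enr + (n4 - 1L) + length(spec$planted_genes)) {
    wp_domain_error("n_genes too small for the requested category structure")
  }
  structure(spec, class = "toy_model_spec")
}

#' Spec shaped like the reference master table
#'
#' An iCEL1314-sized fixture: 1314 genes, 907 metabolite rows, 2230
#' reactions, category counts 10/61/79/85, a 32% multi-pathway fraction,
#' the gene `alh-2` planted with exactly four pathway assignments, and an
#' inventory of 62 maps.
#'
#' @param seed single integer seed.
#' @return a `toy_model_spec`.
#' @export
master_shaped_spec <- function(seed = 1L) {
  toy_model_spec(seed = seed, n_genes = 1314L, n_mets = 907L,
                 n_reactions = 2230L, n_categories = c(10L, 61L, 79L, 85L),
                 multi_fraction = 0.32,
                 planted_transport = c("C_E", "C_E", "M_C"),
                 enriched = list(n = 10L, k = 10L, N = 20L),
                 planted_genes = c("alh-2" = 4L, "acdh-1" = 3L),
                 n_maps = 62L, chain_len = 4L)
}

# blank a trailing run of cells equal to the level above (redundancy is
# written in the blank-cell form to exercise inheritance on load)
blank_trailing <- function(path4) {
  out <- path4
  for (k in 4:2) {
    if (path4[k] == path4[k - 1]) out[k] <- "" else break
  }
  out
}

#' Generate a synthetic model, annotation table and maps with planted truth
#'
#' Writes into `dir`: `genes.tsv`, `metabolites.tsv`, `reactions.tsv`,
#' `annotations.tsv`, `maps/map-XX.yaml`, and `manifest.json` recording
#' every planted truth (per-gene pathway-path counts, per-metabolite
#' pathway counts and transport classes, the reaction-to-pathway table, the
#' enriched category, and the expected terminal classification of every
#' map). Identical specs produce byte-identical files.
#'
#' @param spec a [toy_model_spec()].
#' @param dir output directory (created).
#' @return the manifest, invisibly (also written as `manifest.json`).
#' @export
generate_toy_model <- function(spec, dir) {
  stopifnot(inherits(spec, "toy_model_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "maps"), showWarnings = FALSE)
  with_seed(spec$seed, generate_toy_model_impl(spec, dir))
}

generate_toy_model_impl <- function(spec, dir) {
  n4 <- spec$n_categories[4]
  namer <- make_namer()
  tree <- build_category_tree(spec$n_categories, namer)

  # ---- genes and pathway assignments -------------------------------------
  planted <- spec$planted_genes
  gene_ids <- make_gene_ids(spec$n_genes - length(planted), names(planted))
  gene_ids <- c(names(planted), gene_ids)[seq_len(spec$n_genes)]

  enr_leaf <- if (is.null(spec$enriched)) 0L else n4  # last leaf is the target
  other_leaves <- setdiff(seq_len(n4), enr_leaf)

  assignments <- vector("list", spec$n_genes)
  names(assignments) <- gene_ids

  idx <- 1L
  # planted multi-path genes first (they are at the front of gene_ids)
  for (g in names(planted)) {
    assignments[[g]] <- sample(other_leaves, planted[[g]])
    idx <- idx + 1L
  }
  # enriched category: exactly n dedicated genes, no extra paths
  enr_genes <- character(0)
  if (enr_leaf > 0L) {
    enr_genes <- gene_ids[idx:(idx + spec$enriched$n - 1L)]
    for (g in enr_genes) assignments[[g]] <- enr_leaf
    idx <- idx + spec$enriched$n
  }
  # one single-pathway representative per remaining leaf (kept single so
  # that reactions built on them have unambiguous pathway inference)
  reps <- stats::setNames(rep(NA_character_, n4), as.character(seq_len(n4)))
  for (lf in other_leaves) {
    g <- gene_ids[idx]; idx <- idx + 1L
    assignments[[g]] <- lf
    reps[as.character(lf)] <- g
  }
  # remaining genes: one random leaf each
  rest <- gene_ids[seq(idx, length.out = spec$n_genes - idx + 1L)]
  for (g in rest) assignments[[g]] <- sample(other_leaves, 1L)

  # plant the multi-pathway fraction exactly
  n_multi_target <- round(spec$multi_fraction * spec$n_genes)
  n_multi_planted <- sum(planted > 1L)
  eligible <- setdiff(rest, NA)
  n_extra <- max(0L, n_multi_target - n_multi_planted)
  if (n_extra > length(eligible)) {
    wp_domain_error("multi_fraction infeasible given planted genes and leaves")
  }
  for (g in sample(eligible, n_extra)) {
    free <- setdiff(other_leaves, assignments[[g]])
    assignments[[g]] <- c(assignments[[g]], sample(free, 1L))
  }

  leaf_genes <- lapply(seq_len(n4), function(lf) {
    sort(names(assignments)[vapply(assignments, function(a) lf %in% a, logical(1))])
  })

  # ---- annotation table --------------------------------------------------
  rec_rows <- list()
  for (g in gene_ids) {
    for (lf in sort(assignments[[g]])) {
      p <- unlist(tree[lf, LEVEL_COLS], use.names = FALSE)
      rec_rows[[length(rec_rows) + 1L]] <- c(g, blank_trailing(p))
    }
  }
  ann <- as.data.frame(do.call(rbind, rec_rows), stringsAsFactors = FALSE)
  names(ann) <- c("gene_id", LEVEL_COLS)

  # ---- metabolites -------------------------------------------------------
  coreactants <- c("atp", "adp")
  n_chain <- spec$n_maps * spec$chain_len
  # archetype roles by map position
  archetype <- function(i) {
    if (i == 1L) "PATHWAY_BOXES" else if (i == 2L) "TRANSPORT_ENDPOINT"
    else if (i == 4L) "LINK_ONLY" else "OTHER_BOX"
  }
  n_arch1 <- sum(vapply(seq_len(spec$n_maps), function(i) archetype(i) == "PATHWAY_BOXES", logical(1)))
  n_arch2 <- sum(vapply(seq_len(spec$n_maps), function(i) archetype(i) == "TRANSPORT_ENDPOINT", logical(1)))
  n_arch4 <- sum(vapply(seq_len(spec$n_maps), function(i) archetype(i) == "LINK_ONLY", logical(1)))
  rows_dedicated <- length(coreactants) + n_chain + n_arch1 + 5L * n_arch4 +
    n_arch2 + 2L * length(spec$planted_transport)
  n_background <- spec$n_mets - rows_dedicated
  if (n_background < 2L) {
    wp_domain_error("n_mets too small for the requested maps and transports")
  }
  n_abbrs <- n_chain + n_arch1 + 5L * n_arch4 +
    length(spec$planted_transport) + n_background
  abbrs <- make_met_abbrs(n_abbrs, reserved = coreactants)
  take <- local({ i <- 0L; function(n) { out <- abbrs[(i + 1L):(i + n)]; i <<- i + n; out } })
  chain_mets <- matrix(take(n_chain), nrow = spec$n_maps, byrow = TRUE)
  arch1_products <- if (n_arch1 > 0L) take(n_arch1) else character(0)
  arch4_products <- if (n_arch4 > 0L) take(5L * n_arch4) else character(0)
  transport_mets <- if (length(spec$planted_transport) > 0L)
    take(length(spec$planted_transport)) else character(0)
  background <- take(n_background)

  met_rows <- list()
  add_met <- function(abbr, comp, sref = "NONE") {
    met_rows[[length(met_rows) + 1L]] <<- c(abbr, comp,
      paste("synthetic metabolite", abbr),
      sprintf("C%dH%dO%d", sample(2:20, 1L), sample(4:30, 1L), sample(1:8, 1L)),
      sref)
  }
  for (a in coreactants) add_met(a, "c")
  for (i in seq_len(spec$n_maps)) for (a in chain_mets[i, ]) add_met(a, "c")
  for (a in arch1_products) add_met(a, "c")
  for (a in arch4_products) add_met(a, "c")
  # transport endpoints: chain terminal met also present extracellularly
  for (i in seq_len(spec$n_maps)) {
    if (archetype(i) == "TRANSPORT_ENDPOINT") {
      add_met(chain_mets[i, spec$chain_len], "e")
    }
  }
  for (j in seq_along(spec$planted_transport)) {
    a <- transport_mets[j]
    if (spec$planted_transport[j] == "C_E") { add_met(a, "c"); add_met(a, "e") }
    else { add_met(a, "c"); add_met(a, "m") }
  }
  for (j in seq_along(background)) {
    sref <- if (j <= 2L) sprintf("structures/%s.png", background[j]) else "NONE"
    add_met(background[j], "c", sref)
  }
  mets <- as.data.frame(do.call(rbind, met_rows), stringsAsFactors = FALSE)
  names(mets) <- c("met_id", "compartment", "name", "formula", "structure_ref")

  # ---- reactions ---------------------------------------------------------
  rxn_rows <- list()
  rxn_pathway <- character(0)   # rxn_id -> leaf pathway name (internal truth)
  rid_n <- 0L
  next_rid <- function() { rid_n <<- rid_n + 1L; sprintf("R%04d", rid_n) }
  leaf_name <- function(lf) tree$level4[lf]

  make_rule <- function(lf) {
    pool <- setdiff(leaf_genes[[lf]], character(0))
    m <- min(length(pool), sample(1:3, 1L))
    gs <- sample(pool, m)
    if (m == 1L) gs else if (m == 2L) paste(gs, collapse = sample(c("|", "&"), 1L))
    else paste0(gs[1], "&", gs[2], "|", gs[3])
  }

  add_rxn <- function(equation, rtype, rule, co, pathway = NA_character_) {
    rid <- next_rid()
    rxn_rows[[length(rxn_rows) + 1L]] <<- c(rid, equation, rtype, rule, co)
    if (!is.na(pathway)) rxn_pathway[rid] <<- pathway
    rid
  }

  map_leaves <- other_leaves[seq_len(spec$n_maps)]
  map_info <- vector("list", spec$n_maps)

  for (i in seq_len(spec$n_maps)) {
    lf <- map_leaves[i]
    kind <- archetype(i)
    chain <- chain_mets[i, ]
    chain_rids <- character(spec$chain_len - 1L)
    for (j in seq_len(spec$chain_len - 1L)) {
      arrow <- if (j %% 3L == 0L) "<=>" else "->"
      eq <- sprintf("%s[c] + atp[c] %s %s[c] + adp[c]", chain[j], arrow, chain[j + 1L])
      # leaf representative guarantees the rule resolves to this pathway
      rule <- if (j == 1L) reps[[as.character(lf)]] else make_rule(lf)
      chain_rids[j] <- add_rxn(eq, "enzymatic", rule, "atp[c],adp[c]",
                               leaf_name(lf))
    }
    term <- chain[spec$chain_len]
    extra_rids <- character(0)
    expected_pathways <- character(0)
    if (kind == "PATHWAY_BOXES") {
      # the terminal also feeds one reaction of the next map's pathway
      olf <- map_leaves[if (i < spec$n_maps) i + 1L else 1L]
      eq <- sprintf("%s[c] -> %s[c]", term, arch1_products[1])
      extra_rids <- add_rxn(eq, "enzymatic", reps[[as.character(olf)]], "",
                            leaf_name(olf))
      expected_pathways <- leaf_name(olf)
    } else if (kind == "TRANSPORT_ENDPOINT") {
      eq <- sprintf("%s[c] -> %s[e]", term, term)
      extra_rids <- add_rxn(eq, "transport", "", "")
    } else if (kind == "LINK_ONLY") {
      hub_leaves <- setdiff(other_leaves, lf)[1:5]
      for (z in 1:5) {
        eq <- sprintf("%s[c] -> %s[c]", term, arch4_products[z])
        extra_rids <- c(extra_rids,
                        add_rxn(eq, "enzymatic", reps[[as.character(hub_leaves[z])]],
                                "", leaf_name(hub_leaves[z])))
      }
      expected_pathways <- sort_c(leaf_name(hub_leaves))
    }
    map_info[[i]] <- list(i = i, leaf = lf, kind = kind, chain = chain,
                          chain_rids = chain_rids, extra_rids = extra_rids,
                          expected_pathways = expected_pathways)
  }

  # planted transportable metabolites (orphan transports, as is typical)
  for (j in seq_along(spec$planted_transport)) {
    a <- transport_mets[j]
    comp2 <- if (spec$planted_transport[j] == "C_E") "e" else "m"
    add_rxn(sprintf("%s[c] <=> %s[%s]", a, a, comp2), "transport", "", "")
  }

  # background reactions up to the requested count
  n_fill <- spec$n_reactions - rid_n
  if (n_fill < 0L) {
    wp_domain_error("n_reactions too small for the requested maps and transports")
  }
  for (z in seq_len(n_fill)) {
    pair <- sample(background, 2L)
    lf <- sample(other_leaves, 1L)
    arrow <- if (z %% 4L == 0L) "<=>" else "->"
    add_rxn(sprintf("%s[c] %s %s[c]", pair[1], arrow, pair[2]),
            "enzymatic", make_rule(lf), "", leaf_name(lf))
  }

  rxns <- as.data.frame(do.call(rbind, rxn_rows), stringsAsFactors = FALSE)
  names(rxns) <- c("rxn_id", "equation", "rtype", "gene_rule", "co_reactants")

  # ---- genes table -------------------------------------------------------
  aliases <- vapply(seq_along(gene_ids), function(i) {
    if (i %% 10L == 0L) toupper(gsub("-", "", gene_ids[i])) else ""
  }, "")
  genes <- data.frame(gene_id = gene_ids, aliases = aliases,
                      stringsAsFactors = FALSE)

  # ---- ground truth: per-metabolite pathway counts -----------------------
  met_paths <- stats::setNames(vector("list", n_abbrs + length(coreactants)),
                               c(coreactants, abbrs))
  for (r in seq_len(nrow(rxns))) {
    rid <- rxns$rxn_id[r]
    if (rxns$rtype[r] == "transport") next  # all transports are self-edges here
    if (!rid %in% names(rxn_pathway)) next
    toks <- regmatches(rxns$equation[r],
                       gregexpr("[a-z0-9]+\\[", rxns$equation[r]))[[1]]
    for (a in unique(sub("\\[$", "", toks))) {
      met_paths[[a]] <- unique(c(met_paths[[a]], rxn_pathway[[rid]]))
    }
  }
  met_pathway_counts <- vapply(met_paths, length, integer(1))

  transport_truth <- list()
  for (j in seq_along(spec$planted_transport)) {
    a <- transport_mets[j]
    transport_truth[[a]] <- unique(c(transport_truth[[a]],
                                     spec$planted_transport[j]))
  }
  for (i in seq_len(spec$n_maps)) {
    if (archetype(i) == "TRANSPORT_ENDPOINT") {
      transport_truth[[chain_mets[i, spec$chain_len]]] <- "C_E"
    }
  }

  # ---- write model + annotation tables -----------------------------------
  write_tsv <- function(df, file) {
    utils::write.table(df, file.path(dir, file), sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  }
  write_tsv(genes, "genes.tsv")
  write_tsv(mets, "metabolites.tsv")
  write_tsv(rxns, "reactions.tsv")
  write_tsv(ann, "annotations.tsv")

  # ---- map definitions ---------------------------------------------------
  terminals <- list()
  maps_manifest <- list()
  for (i in seq_len(spec$n_maps)) {
    mi <- map_info[[i]]
    map_id <- sprintf("map-%02d", i)
    file <- file.path("maps", sprintf("%s.yaml", map_id))
    cat_name <- leaf_name(mi$leaf)
    nodes <- lapply(seq_len(spec$chain_len), function(j) {
      nd <- list(met = sprintf("%s[c]", mi$chain[j]),
                 x = 80 + 150 * (j - 1), y = 160)
      if (j == 1L) { nd$terminal <- TRUE; nd$main_terminus <- TRUE }
      if (j == spec$chain_len) nd$terminal <- TRUE
      nd
    })
    edges <- lapply(seq_len(spec$chain_len - 1L), function(j) {
      x1 <- 80 + 150 * (j - 1); x2 <- 80 + 150 * j
      list(reaction = mi$chain_rids[j],
           waypoints = list(c(x1 + 20, 155), c(x2 - 20, 155)),
           label = c((x1 + x2) / 2, 140))
    })
    boxes <- list()
    term_ref <- sprintf("%s[c]", mi$chain[spec$chain_len])
    if (mi$kind == "PATHWAY_BOXES") {
      boxes <- list(list(kind = "pathway", target = mi$expected_pathways[1],
                         met = term_ref,
                         x = 80 + 150 * (spec$chain_len - 1), y = 220))
    } else if (mi$kind == "OTHER_BOX") {
      boxes <- list(list(kind = "other", met = term_ref,
                         x = 80 + 150 * (spec$chain_len - 1), y = 220))
    } else if (mi$kind == "TRANSPORT_ENDPOINT") {
      x1 <- 80 + 150 * (spec$chain_len - 1)
      edges <- c(edges, list(list(reaction = mi$extra_rids[1],
                                  waypoints = list(c(x1, 150), c(x1, 60)),
                                  label = c(x1 + 10, 100))))
    }
    doc <- list(
      map = list(id = map_id, title = sprintf("%s (synthetic map)", cat_name),
                 level = 4L, category = cat_name,
                 canvas = list(width = 80 + 150 * spec$chain_len,
                               height = 420)),
      nodes = nodes, edges = edges, boxes = boxes,
      regions = list(list(label = "cytosol", x = 20, y = 30,
                          width = 40 + 150 * spec$chain_len, height = 330)),
      reactions = as.list(c(mi$chain_rids,
                            if (mi$kind == "TRANSPORT_ENDPOINT") mi$extra_rids))
    )
    yaml::write_yaml(doc, file.path(dir, file))
    terminals[[length(terminals) + 1L]] <- list(
      map_id = map_id, file = file, met = term_ref, kind = mi$kind,
      pathways = mi$expected_pathways)
    map_genes <- sort_c(unique(unlist(lapply(
      c(mi$chain_rids, if (mi$kind == "TRANSPORT_ENDPOINT") mi$extra_rids),
      function(rid) {
        rule <- rxns$gene_rule[rxns$rxn_id == rid]
        if (nzchar(rule)) rule_genes(parse_gene_rule(rule)) else character(0)
      }))))
    maps_manifest[[length(maps_manifest) + 1L]] <- list(
      id = map_id, file = file, category = cat_name, level = 4L,
      genes = map_genes)
  }

  # ---- manifest ----------------------------------------------------------
  gene_path_counts <- vapply(assignments, length, integer(1))
  manifest <- list(
    spec = unclass(spec),
    counts = list(genes = spec$n_genes, metabolite_rows = nrow(mets),
                  reactions = nrow(rxns),
                  categories_per_level = spec$n_categories,
                  maps = spec$n_maps),
    multi = list(n_multi = as.integer(n_multi_target),
                 fraction = n_multi_target / spec$n_genes,
                 pct = round(100 * n_multi_target / spec$n_genes)),
    gene_path_counts = as.list(gene_path_counts),
    enriched = if (enr_leaf > 0L) list(
      level = 4L, name = leaf_name(enr_leaf), n = spec$enriched$n,
      k = spec$enriched$k, N = spec$enriched$N, M = spec$n_genes,
      genes = enr_genes) else NULL,
    met_pathway_counts = as.list(met_pathway_counts),
    transport = transport_truth,
    rxn_pathways = as.list(rxn_pathway),
    terminals = terminals,
    maps = maps_manifest,
    files = list(genes = "genes.tsv", metabolites = "metabolites.tsv",
                 reactions = "reactions.tsv", annotations = "annotations.tsv")
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Generate a PEA input gene list with a planted enrichment
#'
#' Writes a plain-text gene list (one token per line, `#` comments allowed)
#' containing `k` genes of the planted enriched category plus background
#' draws from the rest of the universe up to `N` metabolic hits, plus two
#' junk tokens that do not match the universe. Requires
#' [generate_toy_model()] to have been run into `dir` first.
#'
#' @param spec the `toy_model_spec` used to generate `dir`.
#' @param dir fixture directory containing `manifest.json` and
#'   `annotations.tsv`.
#' @param seed RNG seed for the draw (default derived from the spec seed, so
#'   repeated calls with different seeds give independent replicates).
#' @param file output file name within `dir`.
#' @return list with `file` (path) and `expected` (`M`, `N`, `n`, `k`,
#'   `level`, `category`), invisibly.
#' @export
generate_pea_input <- function(spec, dir, seed = spec$seed + 7777L,
                               file = "pea_input.txt") {
  stopifnot(inherits(spec, "toy_model_spec"))
  if (is.null(spec$enriched)) {
    wp_domain_error("spec has no planted enriched category")
  }
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  aset <- load_annotations(file.path(dir, "annotations.tsv"))
  enr <- manifest$enriched
  cat_genes <- genes_in_category(aset, enr$level, enr$name)
  k <- as.integer(spec$enriched$k)
  N <- as.integer(spec$enriched$N)
  with_seed(as.integer(seed), {
    in_cat <- if (k > 0L) sample(cat_genes, k) else character(0)
    pool <- setdiff(aset$universe, cat_genes)
    bg <- if (N - k > 0L) sample(pool, N - k) else character(0)
    tokens <- sample(c(in_cat, bg))
    path <- file.path(dir, file)
    writeLines(c("# synthetic PEA input list", tokens,
                 "notagene-1", "notagene-2"), path)
    invisible(list(file = path,
                   expected = list(M = length(aset$universe), N = N,
                                   n = length(cat_genes), k = k,
                                   level = enr$level, category = enr$name)))
  })
}
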