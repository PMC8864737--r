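# Metabolic model core: genes, compartmentalised metabolites, reactions with
# boolean gene-protein-reaction (GPR) rules.
#
# The model mirrors the shape of iCEL1314, the C. elegans genome-scale
# network (1314 genes, 907 metabolites, 2230 reactions): metabolites carry
# BiGG-style abbreviations plus a compartment code, reactions are enzymatic
# or transport, and each reaction may carry a flat OR-of-AND gene rule
# ("pck-1|pck-2|pck-3", "pdha-1&pdhb-1"). Orphan reactions (no known gene,
# common for transports) are legal.

# default compartment table; extra codes found in input files are accepted
# and added with the code as the display name, but only c/m/e take part in
# the transport-class legend logic (see connectivity.R).
WP_COMPARTMENTS <- c(c = "cytosol", m = "mitochondria", e = "extracellular")

#' Parse a boolean gene rule
#'
#' Gene rules are flat OR-of-AND expressions in the display convention used
#' on pathway maps: alternative enzymes ("OR" genes) are separated by a
#' vertical bar `|`, obligate complex subunits ("AND" genes) by an ampersand
#' `&`. `&` binds tighter than `|`; parentheses are not part of the grammar.
#'
#' @param text rule string, e.g. `"pck-1|pck-2|pck-3"` or `"pdha-1&pdhb-1"`.
#' @return an object of class `gene_rule`: a list of character vectors, one
#'   vector per OR-alternative (AND-chain).
#' @examples
#' r <- parse_gene_rule("pdha-1&pdhb-1 | pyk-1")
#' format(r)
#' rule_genes(r)
#' @export
parse_gene_rule <- function(text) {
  if (length(text) != 1L || is.na(text)) {
    wp_parse_error("gene rule must be a single string")
  }
  raw <- wp_trim(text)
  if (!nzchar(raw)) wp_parse_error("gene rule is empty")
  if (grepl("[()]", raw)) {
    wp_parse_error(sprintf("gene rule '%s': parentheses are not supported", raw))
  }
  chains <- strsplit(raw, "|", fixed = TRUE)[[1]]
  # strsplit drops a trailing empty field: "a|" -> "a"; catch it explicitly
  if (grepl("\\|\\s*$", raw)) chains <- c(chains, "")
  rule <- vector("list", length(chains))
  for (i in seq_along(chains)) {
    chain <- wp_trim(chains[i])
    if (!nzchar(chain)) {
      wp_parse_error(sprintf(
        "gene rule '%s': empty OR-alternative at position %d", raw, i))
    }
    genes <- wp_trim(strsplit(chain, "&", fixed = TRUE)[[1]])
    if (grepl("&\\s*$", chain)) genes <- c(genes, "")
    if (any(!nzchar(genes))) {
      wp_parse_error(sprintf(
        "gene rule '%s': empty gene token in AND-chain %d", raw, i))
    }
    rule[[i]] <- genes
  }
  structure(rule, class = "gene_rule")
}

#' @export
format.gene_rule <- function(x, ...) {
  paste(vapply(x, paste, "", collapse = "&"), collapse = "|")
}

#' @export
print.gene_rule <- function(x, ...) {
  cat("<gene_rule> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Flat set of genes appearing in a rule
#' @param rule a `gene_rule` (or NULL for an orphan reaction).
#' @return character vector of unique gene ids (empty for NULL).
#' @export
rule_genes <- function(rule) {
  if (is.null(rule)) return(character(0))
  unique(unlist(rule, use.names = FALSE))
}

# ---- metabolite references: "abbr[comp]" ----------------------------------

# parse one "abbr[comp]" token -> list(id=, compartment=)
parse_met_ref <- function(ref) {
  ref <- wp_trim(ref)
  m <- regmatches(ref, regexec("^([^][[:space:]]+)\\[([^][[:space:]]+)\\]$", ref))[[1]]
  if (length(m) != 3L) {
    wp_parse_error(sprintf("malformed metabolite reference '%s' (expected abbr[comp])", ref))
  }
  list(id = m[2], compartment = m[3])
}

format_met_ref <- function(id, compartment) sprintf("%s[%s]", id, compartment)

# parse one side of an equation: "2 pep[c] + gdp[c]" ->
# data.frame(met, compartment, ref, stoich)
parse_equation_side <- function(side, equation) {
  terms <- wp_trim(strsplit(side, "+", fixed = TRUE)[[1]])
  if (length(terms) == 0L || any(!nzchar(terms))) {
    wp_parse_error(sprintf("equation '%s': empty term", equation))
  }
  out <- lapply(terms, function(term) {
    m <- regmatches(term, regexec("^(([0-9.]+)[[:space:]]+)?([^][[:space:]]+\\[[^][[:space:]]+\\])$", term))[[1]]
    if (length(m) != 4L) {
      wp_parse_error(sprintf("equation '%s': malformed term '%s'", equation, term))
    }
    stoich <- if (nzchar(m[3])) as.numeric(m[3]) else 1
    ref <- parse_met_ref(m[4])
    data.frame(met = ref$id, compartment = ref$compartment,
               ref = m[4], stoich = stoich, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# parse "pep[c] + gdp[c] <=> oaa[c] + gtp[c]" ->
# list(substrates=, products=, reversible=)
parse_equation <- function(equation) {
  eq <- wp_trim(equation)
  reversible <- grepl("<=>", eq, fixed = TRUE)
  arrow <- if (reversible) "<=>" else "->"
  parts <- strsplit(eq, arrow, fixed = TRUE)[[1]]
  if (length(parts) != 2L) {
    wp_parse_error(sprintf("equation '%s': expected exactly one '%s'", eq, arrow))
  }
  list(substrates = parse_equation_side(parts[1], eq),
       products   = parse_equation_side(parts[2], eq),
       reversible = reversible)
}

# ---- model loading --------------------------------------------------------

#' Load a metabolic model from tabular text files
#'
#' Reads the three-table plain-text dialect: `genes.tsv` (columns `gene_id`,
#' `aliases`), `metabolites.tsv` (`met_id`, `compartment`, `name`, `formula`,
#' `structure_ref`), `reactions.tsv` (`rxn_id`, `equation`, `rtype`,
#' `gene_rule`, `co_reactants`). All files are UTF-8, tab-separated, with a
#' header row; lines starting with `#` are ignored. Every cross-reference is
#' resolved at load time; duplicate gene ids or duplicate
#' (metabolite, compartment) pairs are rejected.
#'
#' Equations use `<=>` for reversible and `->` for irreversible reactions;
#' metabolites are written `abbr[comp]` with an optional leading
#' stoichiometric coefficient. A transport reaction must move the same
#' metabolite abbreviation between two distinct compartments.
#'
#' @param gene_table,metabolite_table,reaction_table paths to the three TSVs.
#' @return an object of class `metabolic_model` with components `genes`,
#'   `metabolites` (data frames), `reactions` (named list of reaction
#'   records), and `compartments` (code -> name).
#' @export
load_model <- function(gene_table, metabolite_table, reaction_table) {
  genes <- read_wp_tsv(gene_table, c("gene_id", "aliases"), "gene table")
  genes$gene_id <- wp_trim(genes$gene_id)
  if (any(!nzchar(genes$gene_id))) wp_schema_error("gene table: empty gene_id")
  if (anyDuplicated(genes$gene_id)) {
    wp_schema_error(sprintf("gene table: duplicate gene id(s): %s",
      paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", ")))
  }

  mets <- read_wp_tsv(metabolite_table,
                      c("met_id", "compartment", "name", "formula", "structure_ref"),
                      "metabolite table")
  mets$met_id <- wp_trim(mets$met_id)
  mets$compartment <- wp_trim(mets$compartment)
  if (any(!nzchar(mets$met_id)) || any(!nzchar(mets$compartment))) {
    wp_schema_error("metabolite table: empty met_id or compartment")
  }
  key <- paste0(mets$met_id, "[", mets$compartment, "]")
  if (anyDuplicated(key)) {
    wp_schema_error(sprintf("metabolite table: duplicate (id, compartment): %s",
                            paste(unique(key[duplicated(key)]), collapse = ", ")))
  }
  mets$ref <- key

  compartments <- WP_COMPARTMENTS
  extra <- setdiff(unique(mets$compartment), names(compartments))
  if (length(extra) > 0L) {
    extra_named <- stats::setNames(extra, extra)
    compartments <- c(compartments, extra_named)
  }

  rxns <- read_wp_tsv(reaction_table,
                      c("rxn_id", "equation", "rtype", "gene_rule", "co_reactants"),
                      "reaction table")
  rxns$rxn_id <- wp_trim(rxns$rxn_id)
  if (anyDuplicated(rxns$rxn_id)) {
    wp_schema_error("reaction table: duplicate rxn_id")
  }
  if (!all(rxns$rtype %in% c("enzymatic", "transport"))) {
    wp_schema_error("reaction table: rtype must be 'enzymatic' or 'transport'")
  }

  gene_ids <- genes$gene_id
  met_refs <- mets$ref
  reactions <- vector("list", nrow(rxns))
  names(reactions) <- rxns$rxn_id
  for (i in seq_len(nrow(rxns))) {
    eq <- parse_equation(rxns$equation[i])
    all_refs <- c(eq$substrates$ref, eq$products$ref)
    bad <- setdiff(all_refs, met_refs)
    if (length(bad) > 0L) {
      wp_reference_error(sprintf(
        "reaction %s: unresolved metabolite reference(s): %s",
        rxns$rxn_id[i], paste(bad, collapse = ", ")), ids = bad)
    }
    rule <- NULL
    rule_txt <- wp_trim(rxns$gene_rule[i])
    if (nzchar(rule_txt)) {
      rule <- parse_gene_rule(rule_txt)
      bad_genes <- setdiff(rule_genes(rule), gene_ids)
      if (length(bad_genes) > 0L) {
        wp_reference_error(sprintf(
          "reaction %s: unresolved gene id(s) in rule: %s",
          rxns$rxn_id[i], paste(bad_genes, collapse = ", ")), ids = bad_genes)
      }
    }
    co <- character(0)
    co_txt <- wp_trim(rxns$co_reactants[i])
    if (nzchar(co_txt)) {
      co <- wp_trim(strsplit(co_txt, ",", fixed = TRUE)[[1]])
      bad_co <- setdiff(co, all_refs)
      if (length(bad_co) > 0L) {
        wp_reference_error(sprintf(
          "reaction %s: co-reactant(s) not in equation: %s",
          rxns$rxn_id[i], paste(bad_co, collapse = ", ")), ids = bad_co)
      }
    }
    if (rxns$rtype[i] == "transport") {
      shared <- intersect(eq$substrates$met, eq$products$met)
      ok <- FALSE
      for (s in shared) {
        cs <- eq$substrates$compartment[eq$substrates$met == s]
        cp <- eq$products$compartment[eq$products$met == s]
        if (length(setdiff(cp, cs)) > 0L || length(setdiff(cs, cp)) > 0L) ok <- TRUE
      }
      if (!ok) {
        wp_schema_error(sprintf(
          "reaction %s: transport reaction must move a metabolite between two compartments",
          rxns$rxn_id[i]))
      }
    }
    reactions[[i]] <- list(
      id = rxns$rxn_id[i],
      substrates = eq$substrates,
      products = eq$products,
      reversible = eq$reversible,
      rtype = rxns$rtype[i],
      rule = rule,
      co_reactants = co
    )
  }

  structure(
    list(genes = genes, metabolites = mets, reactions = reactions,
         compartments = compartments),
    class = "metabolic_model"
  )
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("<metabolic_model> %d genes, %d metabolites, %d reactions (%d compartments)\n",
              nrow(x$genes), nrow(x$metabolites), length(x$reactions),
              length(x$compartments)))
  n_orphan <- sum(vapply(x$reactions, function(r) is.null(r$rule), logical(1)))
  cat(sprintf("  %d transport reactions, %d orphan reactions (no gene rule)\n",
              sum(vapply(x$reactions, function(r) r$rtype == "transport", logical(1))),
              n_orphan))
  invisible(x)
}

#' Genes associated with a reaction
#'
#' The flat union of all genes appearing in the reaction's rule; the empty
#' set for orphan reactions (e.g. transports with no known transporter).
#'
#' @param model a `metabolic_model`.
#' @param rid reaction id.
#' @return character vector of gene ids (possibly empty).
#' @export
genes_of_reaction <- function(model, rid) {
  stopifnot(inherits(model, "metabolic_model"))
  rxn <- model$reactions[[rid]]
  if (is.null(rxn)) wp_lookup_error(sprintf("unknown reaction id: %s", rid))
  sort(rule_genes(rxn$rule))
}

#' Alias lookup table of a model
#'
#' @param model a `metabolic_model`.
#' @return named character vector mapping each alias to its gene id, for use
#'   with [compute_overlap()]'s alias expansion.
#' @export
model_aliases <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  out <- character(0)
  for (i in seq_len(nrow(model$genes))) {
    al <- wp_trim(strsplit(model$genes$aliases[i], ",", fixed = TRUE)[[1]])
    al <- al[nzchar(al)]
    if (length(al) > 0L) {
      out[al] <- model$genes$gene_id[i]
    }
  }
  out
}

# all "abbr[comp]" refs a reaction touches
reaction_met_refs <- function(rxn) {
  unique(c(rxn$substrates$ref, rxn$products$ref))
}
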