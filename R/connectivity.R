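# Metabolite connectivity and the terminal-metabolite rules behind map
# design.
#
# Pathway maps start or end with three kinds of metabolites: the pathway's
# defining substrate/product (histidine in histidine degradation), a
# connection to other pathways (valine degradation ends with propionyl-CoA,
# connecting it to propionate metabolism), or an endpoint transportable to
# or from the extracellular space (histamine, produced in histidine
# degradation and exported). Connections to other pathways are shown as
# clickable pathway boxes unless the metabolite connects to more pathways
# than a threshold, in which case only the metabolite link is kept (a busy
# hub like CoA would make the map cumbersome). Every metabolite also gets a
# grayscale square binning its pathway count and colored circles for its
# transport classes (cytosol<->extracellular, mitochondria<->cytosol).

# transport-class legend codes
WP_TRANSPORT_CLASSES <- c("C_E", "M_C")

# does `what` (bare abbreviation or "abbr[comp]" ref) occur in reaction rxn?
met_in_reaction <- function(rxn, what) {
  refs <- reaction_met_refs(rxn)
  if (grepl("[", what, fixed = TRUE)) what %in% refs
  else what %in% c(rxn$substrates$met, rxn$products$met)
}

# is rxn a transport self-edge for this abbreviation (same abbr both sides)?
is_transport_self_edge <- function(rxn, abbr) {
  rxn$rtype == "transport" &&
    abbr %in% rxn$substrates$met && abbr %in% rxn$products$met
}

bare_abbr <- function(what) sub("\\[.*$", "", what)

# pathway names a single reaction belongs to at `level`: the explicit
# reaction->pathway table wins when it lists the reaction (mirroring manual
# pathway splitting during curation); otherwise the union of the reaction's
# genes' level-`level` annotations.
reaction_pathway_names <- function(model, aset, rid, level, rxn_pathways = NULL) {
  if (!is.null(rxn_pathways) && rid %in% names(rxn_pathways)) {
    return(unique(unlist(rxn_pathways[[rid]], use.names = FALSE)))
  }
  genes <- rule_genes(model$reactions[[rid]]$rule)
  if (length(genes) == 0L) return(character(0))
  rec <- aset$records[aset$records$gene_id %in% genes, , drop = FALSE]
  unique(rec[[LEVEL_COLS[check_level(level)]]])
}

# distinct pathway names over all reactions touching the metabolite,
# transport self-edges excluded
metabolite_pathways <- function(model, aset, met, level = 4, rxn_pathways = NULL) {
  abbr <- bare_abbr(met)
  out <- character(0)
  for (rid in names(model$reactions)) {
    rxn <- model$reactions[[rid]]
    if (!met_in_reaction(rxn, met)) next
    if (is_transport_self_edge(rxn, abbr)) next
    out <- c(out, reaction_pathway_names(model, aset, rid, level, rxn_pathways))
  }
  sort_c(unique(out))
}

#' Number of pathways a metabolite connects to
#'
#' Counts the distinct map-level pathway names among the reactions that
#' consume or produce the metabolite. Transport self-edges (the reaction
#' only moves the metabolite between compartments) are ignored. Pathway
#' membership of a reaction comes from an explicit reaction-to-pathway
#' table when one is supplied (it wins on conflict), otherwise from the
#' reaction's genes' annotations at `level`.
#'
#' @param model a `metabolic_model`.
#' @param aset an `annotation_set`.
#' @param met a bare abbreviation (counts across compartments) or an
#'   `"abbr[comp]"` reference.
#' @param level annotation level at which maps are defined (default 4).
#' @param rxn_pathways optional named list: reaction id -> character vector
#'   of pathway names.
#' @return integer count (drives the grayscale square on maps).
#' @export
metabolite_pathway_count <- function(model, aset, met, level = 4,
                                     rxn_pathways = NULL) {
  stopifnot(inherits(model, "metabolic_model"))
  known <- grepl("[", met, fixed = TRUE) &&
    met %in% model$metabolites$ref ||
    bare_abbr(met) %in% model$metabolites$met_id
  if (!known) wp_lookup_error(sprintf("unknown metabolite: %s", met))
  length(metabolite_pathways(model, aset, met, level, rxn_pathways))
}

#' Transport classes of a metabolite
#'
#' Which of the two legend transport classes apply to an abbreviation:
#' `C_E` if some transport reaction moves it between cytosol (c) and
#' extracellular space (e), `M_C` if between mitochondria (m) and cytosol.
#' Transports between other compartment pairs are accepted in the model but
#' do not take part in the legend.
#'
#' @param model a `metabolic_model`.
#' @param met_id bare metabolite abbreviation.
#' @return character vector, subset of `c("C_E", "M_C")` (possibly empty).
#' @export
transport_classes <- function(model, met_id) {
  stopifnot(inherits(model, "metabolic_model"))
  if (!met_id %in% model$metabolites$met_id) {
    wp_lookup_error(sprintf("unknown metabolite abbreviation: %s", met_id))
  }
  classes <- character(0)
  for (rxn in model$reactions) {
    if (rxn$rtype != "transport") next
    cs <- rxn$substrates$compartment[rxn$substrates$met == met_id]
    cp <- rxn$products$compartment[rxn$products$met == met_id]
    if (length(cs) == 0L || length(cp) == 0L) next
    pairs <- unique(expand.grid(a = cs, b = cp, stringsAsFactors = FALSE))
    for (j in seq_len(nrow(pairs))) {
      pr <- sort(c(pairs$a[j], pairs$b[j]))
      if (identical(pr, c("c", "e"))) classes <- c(classes, "C_E")
      if (identical(pr, c("c", "m"))) classes <- c(classes, "M_C")
    }
  }
  intersect(WP_TRANSPORT_CLASSES, unique(classes))
}

#' Classify a terminal metabolite of a map
#'
#' Applies the terminal-metabolite decision cascade used when designing
#' pathway maps:
#' \enumerate{
#'   \item the map marks it as the pathway's defining substrate/product ->
#'     `MAIN_TERMINUS`;
#'   \item it connects to between 1 and `box_threshold` other pathways ->
#'     `PATHWAY_BOXES` (one clickable box per pathway);
#'   \item no other pathway but a legend-class transport exists ->
#'     `TRANSPORT_ENDPOINT` (a transport explains its source or fate);
#'   \item no other pathway and no transport -> `OTHER_BOX` (its remaining
#'     reactions are not included in any map yet);
#'   \item more than `box_threshold` other pathways -> `LINK_ONLY` (no
#'     boxes; the metabolite link alone carries the connections).
#' }
#'
#' @param model a `metabolic_model`.
#' @param aset an `annotation_set`.
#' @param mapdef a `map_definition` in which `met` is a declared terminal.
#' @param met the node's metabolite reference (as written in the map).
#' @param box_threshold maximum number of other pathways still drawn as
#'   boxes. Default 2 ("more than two other pathways" suppresses boxes);
#'   some published maps use a laxer cut of 4 - configurable for that
#'   reason.
#' @param rxn_pathways optional explicit reaction-to-pathway table.
#' @return an object of class `terminal_classification`: `met`, `map_id`,
#'   `kind`, and `pathways` (the other pathways, for `PATHWAY_BOXES` /
#'   `LINK_ONLY`).
#' @export
classify_terminal <- function(model, aset, mapdef, met, box_threshold = 2,
                              rxn_pathways = NULL) {
  stopifnot(inherits(model, "metabolic_model"),
            inherits(aset, "annotation_set"),
            inherits(mapdef, "map_definition"))
  nodes <- mapdef$nodes
  row <- which(nodes$met == met)
  if (length(row) == 0L || !any(nodes$terminal[row])) {
    stop_wp("wp_contract_error",
            sprintf("metabolite %s is not a declared terminal of map %s",
                    met, mapdef$map$id))
  }
  mk <- function(kind, pathways = character(0)) {
    structure(list(met = met, map_id = mapdef$map$id, kind = kind,
                   pathways = pathways),
              class = "terminal_classification")
  }
  if (any(nodes$main_terminus[row])) return(mk("MAIN_TERMINUS"))
  own <- mapdef$map$category
  P <- setdiff(
    metabolite_pathways(model, aset, met, mapdef$map$level, rxn_pathways),
    own)
  if (length(P) >= 1L && length(P) <= box_threshold) return(mk("PATHWAY_BOXES", P))
  if (length(P) == 0L) {
    if (length(transport_classes(model, bare_abbr(met))) > 0L) {
      return(mk("TRANSPORT_ENDPOINT"))
    }
    return(mk("OTHER_BOX"))
  }
  mk("LINK_ONLY", P)
}

#' @export
print.terminal_classification <- function(x, ...) {
  cat(sprintf("<terminal_classification> %s on map %s: %s", x$met, x$map_id, x$kind))
  if (length(x$pathways) > 0L) {
    cat(" [", paste(x$pathways, collapse = "; "), "]", sep = "")
  }
  cat("\n")
  invisible(x)
}

# grayscale bin index (1..4) for a pathway count: 1, 2, 3, >=4; 0 -> NA
pathway_count_bin <- function(count) {
  if (count <= 0L) return(NA_integer_)
  min(count, 4L)
}
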