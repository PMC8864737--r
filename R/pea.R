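# Pathway enrichment analysis (PEA) over the metabolic gene universe.
#
# The procedure follows the WormFlux PEA webtool. A user gene list is first
# intersected with the universe (the model's full gene complement, M = 1314
# on the reference network); the intersection is the set of "metabolic
# hits", of size N. For every category at every requested level the overlap
# k with the category's n genes is scored as k/n, and hypergeometric tail
# probabilities give the enrichment p-value P(K >= k) and the depletion
# p-value P(K <= k). Both tails INCLUDE k, so p_enrich + p_deplete =
# 1 + pmf(k). No multiple-testing correction is applied to the stored
# values - a deliberate choice to avoid understating enrichment strength;
# bonferroni_threshold() provides the advisory cut-off alpha/n_test.

check_hyper_args <- function(M, n, N) {
  for (v in list(M = M, n = n, N = N)) {
    if (length(v) != 1L || is.na(v) || v < 0 || v != floor(v)) {
      wp_domain_error("M, n and N must be single non-negative integers")
    }
  }
  if (n > M || N > M) wp_domain_error("require n <= M and N <= M")
}

#' Hypergeometric probability mass
#'
#' P(K = k) when drawing N genes without replacement from a universe of M
#' genes of which n belong to the category:
#' C(n,k) C(M-n, N-k) / C(M, N). Returns 0 for k outside the support
#' (max(0, n+N-M) .. min(n, N)).
#'
#' @param M universe size; @param n category size; @param N number of hits;
#' @param k intersection size (vectorised).
#' @return probability (vector along `k`).
#' @export
hypergeom_pmf <- function(M, n, N, k) {
  check_hyper_args(M, n, N)
  stats::dhyper(k, m = n, n = M - n, k = N)
}

#' Enrichment p-value: P(K >= k)
#'
#' The sum of hypergeometric probabilities for k and greater integers
#' (k-inclusive upper tail). Equals 1 whenever k is at or below the lower
#' support bound.
#' @inheritParams hypergeom_pmf
#' @export
enrichment_pvalue <- function(M, n, N, k) {
  check_hyper_args(M, n, N)
  pmin(1, stats::phyper(k - 1, m = n, n = M - n, k = N, lower.tail = FALSE))
}

#' Depletion p-value: P(K <= k)
#'
#' The sum of hypergeometric probabilities for k and smaller integers
#' (k-inclusive lower tail). Equals 1 at k = min(n, N).
#' @inheritParams hypergeom_pmf
#' @export
depletion_pvalue <- function(M, n, N, k) {
  check_hyper_args(M, n, N)
  pmin(1, stats::phyper(k, m = n, n = M - n, k = N, lower.tail = TRUE))
}

#' Bonferroni significance threshold
#'
#' The advisory per-test threshold alpha / n_test; with the reference
#' annotation table n_test is the number of categories at the level of
#' interest (10 at Level 1, 85 at Level 4).
#'
#' @param alpha family-wise significance level, in (0, 1).
#' @param n_test number of tests (categories at the level), >= 1.
#' @export
bonferroni_threshold <- function(alpha, n_test) {
  if (length(alpha) != 1L || is.na(alpha) || alpha <= 0 || alpha >= 1) {
    wp_domain_error("alpha must be in (0, 1)")
  }
  if (length(n_test) != 1L || is.na(n_test) || n_test < 1 || n_test != floor(n_test)) {
    wp_domain_error("n_test must be a positive integer")
  }
  alpha / n_test
}

#' Overlap a raw gene list with the universe
#'
#' Tokens are trimmed of surrounding whitespace and deduplicated; the
#' intersection with the universe defines the metabolic hits. Matching is
#' exact - no alias expansion, so the hit set is deterministic.
#'
#' @param raw_genes character vector of gene tokens as supplied.
#' @param universe character vector (or `annotation_set`) giving the
#'   background gene set.
#' @param aliases optional named character vector (alias -> gene id, e.g.
#'   from [model_aliases()]); when given, tokens that match an alias are
#'   translated before intersecting. Off by default.
#' @return an object of class `pea_input`: `raw_genes`, `hits`, `unmatched`,
#'   `N` (= number of hits) and `M` (= universe size).
#' @export
compute_overlap <- function(raw_genes, universe, aliases = NULL) {
  if (inherits(universe, "annotation_set")) universe <- universe$universe
  universe <- unique(universe)
  if (length(universe) == 0L) wp_domain_error("universe must be non-empty")
  tokens <- unique(wp_trim(as.character(raw_genes)))
  tokens <- tokens[nzchar(tokens)]
  if (!is.null(aliases)) {
    translatable <- tokens %in% names(aliases) & !tokens %in% universe
    tokens[translatable] <- unname(aliases[tokens[translatable]])
    tokens <- unique(tokens)
  }
  hits <- sort(intersect(tokens, universe))
  structure(
    list(raw_genes = tokens, hits = hits,
         unmatched = sort(setdiff(tokens, universe)),
         N = length(hits), M = length(universe)),
    class = "pea_input"
  )
}

#' @export
print.pea_input <- function(x, ...) {
  cat(sprintf("<pea_input> %d tokens -> %d metabolic hits (N) of universe %d (M); %d unmatched\n",
              length(x$raw_genes), x$N, x$M, length(x$unmatched)))
  invisible(x)
}

#' Run pathway enrichment analysis
#'
#' For each category at each requested level, computes the overlap k with
#' the metabolic hits, the enrichment score k/n, and k-inclusive
#' hypergeometric enrichment and depletion p-values. Raw (uncorrected)
#' p-values are stored. Categories that are empty after filtering are
#' skipped (none arise from a well-formed annotation table).
#'
#' @param raw_genes character vector of input gene tokens, or a `pea_input`.
#' @param aset an `annotation_set` supplying the categories and the universe.
#' @param levels subset of 1:4 to analyse (default all four).
#' @return an object of class `pea_table`: `input` (the `pea_input`) and
#'   `results`, a data frame with columns level, category, n, k, score,
#'   p_enrich, p_deplete, category_genes_in_hits, ordered by level, then
#'   p_enrich ascending, then category name.
#' @export
run_pea <- function(raw_genes, aset, levels = 1:4) {
  stopifnot(inherits(aset, "annotation_set"))
  levels <- unique(as.integer(levels))
  if (length(levels) == 0L || !all(levels %in% 1:4)) {
    wp_domain_error("levels must be a non-empty subset of 1:4")
  }
  input <- if (inherits(raw_genes, "pea_input")) raw_genes else
    compute_overlap(raw_genes, aset)
  M <- input$M; N <- input$N
  rows <- list()
  for (lev in sort(levels)) {
    idx <- aset$index[[LEVEL_COLS[lev]]]
    cats <- sort_c(names(idx))
    n_vec <- vapply(idx[cats], length, integer(1))
    keep <- n_vec > 0L
    cats <- cats[keep]; n_vec <- n_vec[keep]
    if (length(cats) == 0L) next
    k_vec <- integer(length(cats))
    hit_genes <- character(length(cats))
    for (i in seq_along(cats)) {
      inter <- intersect(idx[[cats[i]]], input$hits)
      k_vec[i] <- length(inter)
      hit_genes[i] <- paste(sort(inter), collapse = ",")
    }
    p_enr <- vapply(seq_along(cats), function(i)
      enrichment_pvalue(M, n_vec[[i]], N, k_vec[i]), numeric(1))
    p_dep <- vapply(seq_along(cats), function(i)
      depletion_pvalue(M, n_vec[[i]], N, k_vec[i]), numeric(1))
    rows[[length(rows) + 1L]] <- data.frame(
      level = lev, category = cats, n = as.integer(n_vec), k = k_vec,
      score = k_vec / n_vec, p_enrich = p_enr, p_deplete = p_dep,
      category_genes_in_hits = hit_genes,
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  res <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(level = integer(0), category = character(0), n = integer(0),
               k = integer(0), score = numeric(0), p_enrich = numeric(0),
               p_deplete = numeric(0), category_genes_in_hits = character(0),
               stringsAsFactors = FALSE)
  ord <- order(res$level, res$p_enrich, res$category, method = "radix")
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  structure(
    list(input = input, results = res,
         metadata = list(levels = sort(levels),
                         universe_size = M, hits = N)),
    class = "pea_table"
  )
}

#' @export
print.pea_table <- function(x, top = 5L, ...) {
  print(x$input)
  for (lev in x$metadata$levels) {
    sub <- x$results[x$results$level == lev, , drop = FALSE]
    cat(sprintf("Level %d (%d categories), top enrichments:\n", lev, nrow(sub)))
    show <- utils::head(sub[, c("category", "n", "k", "score", "p_enrich")], top)
    show$score <- signif(show$score, 3)
    show$p_enrich <- signif(show$p_enrich, 3)
    print(show, row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.pea_table <- function(object, alpha = 0.05, ...) {
  res <- object$results
  out <- lapply(split(res, res$level), function(sub) {
    thr <- bonferroni_threshold(alpha, nrow(sub))
    data.frame(level = sub$level[1], n_categories = nrow(sub),
               bonferroni_threshold = thr,
               n_enriched_pass = sum(sub$p_enrich < thr),
               n_depleted_pass = sum(sub$p_deplete < thr))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# -log10(p) mapped onto a white -> `hi` ramp saturating at 10
pea_cell_color <- function(p, hi) {
  s <- pmin(1, -log10(pmax(p, 1e-300)) / 10)
  lo_rgb <- c(255, 255, 255)
  hi_rgb <- grDevices::col2rgb(hi)[, 1]
  v <- round(lo_rgb + s * (hi_rgb - lo_rgb))
  grDevices::rgb(v[1], v[2], v[3], maxColorValue = 255)
}

#' Write PEA results to disk
#'
#' Writes `results.tsv` (columns level, category, n, k, score, p_enrich,
#' p_deplete, category_genes_in_hits; numbers to 6 significant digits with
#' p-values in scientific notation) and `results.html`, a color-coded
#' XHTML table mirroring the interactive view: enrichment cells on a
#' white-to-red ramp over -log10(p) saturating at 10, depletion cells
#' white-to-blue, with an advisory Bonferroni pass column per level (the
#' stored p-values themselves remain uncorrected).
#'
#' @param table a `pea_table`.
#' @param out_dir output directory (created if needed).
#' @param alpha significance level for the advisory Bonferroni column.
#' @return character vector of the two file paths, invisibly.
#' @export
write_pea_outputs <- function(table, out_dir, alpha = 0.05) {
  stopifnot(inherits(table, "pea_table"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) wp_io_error(sprintf("cannot create %s", out_dir))
  res <- table$results

  tsv_path <- file.path(out_dir, "results.tsv")
  fmt <- res
  fmt$score <- signif(fmt$score, 6)
  fmt$p_enrich <- sprintf("%.5e", fmt$p_enrich)
  fmt$p_deplete <- sprintf("%.5e", fmt$p_deplete)
  utils::write.table(fmt, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")

  # advisory Bonferroni pass flag, per level
  pass <- rep(FALSE, nrow(res))
  for (lev in unique(res$level)) {
    sel <- res$level == lev
    thr <- bonferroni_threshold(alpha, sum(sel))
    pass[sel] <- res$p_enrich[sel] < thr | res$p_deplete[sel] < thr
  }

  html_path <- file.path(out_dir, "results.html")
  doc <- xml2::xml_new_root("html")
  head <- xml2::xml_add_child(doc, "head")
  xml2::xml_add_child(head, "title", "PEA results")
  body <- xml2::xml_add_child(doc, "body")
  xml2::xml_add_child(body, "p", sprintf(
    "Metabolic hits N = %d of universe M = %d; p-values are uncorrected.",
    table$input$N, table$input$M))
  tab <- xml2::xml_add_child(body, "table", border = "1")
  hdr <- xml2::xml_add_child(tab, "tr")
  for (h in c("level", "category", "n", "k", "score", "p_enrich", "p_deplete",
              sprintf("bonferroni_pass(alpha=%g)", alpha))) {
    xml2::xml_add_child(hdr, "th", h)
  }
  for (i in seq_len(nrow(res))) {
    tr <- xml2::xml_add_child(tab, "tr")
    xml2::xml_add_child(tr, "td", as.character(res$level[i]))
    xml2::xml_add_child(tr, "td", res$category[i])
    xml2::xml_add_child(tr, "td", as.character(res$n[i]))
    xml2::xml_add_child(tr, "td", as.character(res$k[i]))
    xml2::xml_add_child(tr, "td", sprintf("%.4f", res$score[i]))
    xml2::xml_add_child(tr, "td", sprintf("%.3e", res$p_enrich[i]),
                        style = sprintf("background-color:%s",
                                        pea_cell_color(res$p_enrich[i], "red")))
    xml2::xml_add_child(tr, "td", sprintf("%.3e", res$p_deplete[i]),
                        style = sprintf("background-color:%s",
                                        pea_cell_color(res$p_deplete[i], "blue")))
    xml2::xml_add_child(tr, "td", if (pass[i]) "yes" else "no")
  }
  xml2::write_xml(doc, html_path)

  invisible(c(tsv = tsv_path, html = html_path))
}
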