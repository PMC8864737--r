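# Four-level gene-to-pathway annotation hierarchy.
#
# Level 1 is the broadest grouping (ten classes on the reference table:
# amino acids, carbohydrates, cofactors and vitamins, energy, lipids,
# nucleotides, one-carbon cycle, reactive oxygen species, other amino acids,
# other); Levels 2-4 successively refine it. Branches that cannot be
# subdivided further are carried down unchanged, so higher levels contain
# redundancy: an empty level-k cell (k >= 2) inherits the level-(k-1) value.
# A gene may own several records, one per pathway assignment.

LEVEL_COLS <- c("level1", "level2", "level3", "level4")

#' Load a master annotation table
#'
#' Reads the `annotations.tsv` dialect: columns `gene_id`, `level1`,
#' `level2`, `level3`, `level4`; tab-separated, UTF-8, header required, `#`
#' comments ignored. `level1` must be non-empty on every row; empty cells at
#' deeper levels inherit the value one level up (redundancy propagation).
#' Duplicate identical records are collapsed.
#'
#' @param path path to the annotation table.
#' @return an object of class `annotation_set` with components `records`
#'   (data frame gene_id + level1..level4), `index` (per level: named list
#'   category -> gene-id vector), and `universe` (all annotated gene ids).
#' @export
load_annotations <- function(path) {
  df <- read_wp_tsv(path, c("gene_id", LEVEL_COLS), "annotation table")
  df <- df[, c("gene_id", LEVEL_COLS)]
  for (col in names(df)) df[[col]] <- wp_trim(df[[col]])
  if (nrow(df) == 0L) wp_schema_error(sprintf("annotation table %s: no records", path))
  bad <- which(!nzchar(df$gene_id))
  if (length(bad) > 0L) {
    wp_schema_error(sprintf("annotation table: empty gene_id at row %d", bad[1]))
  }
  bad <- which(!nzchar(df$level1))
  if (length(bad) > 0L) {
    wp_schema_error(sprintf("annotation table: empty level1 cell at row %d", bad[1]))
  }
  # redundancy propagation: blank level-k inherits level-(k-1)
  for (k in 2:4) {
    blank <- !nzchar(df[[LEVEL_COLS[k]]])
    df[[LEVEL_COLS[k]]][blank] <- df[[LEVEL_COLS[k - 1]]][blank]
  }
  df <- unique(df)
  rownames(df) <- NULL
  build_annotation_set(df)
}

# build indexes from a clean records data frame
build_annotation_set <- function(records) {
  index <- lapply(LEVEL_COLS, function(col) {
    split_genes <- split(records$gene_id, records[[col]])
    lapply(split_genes, function(g) sort(unique(g)))
  })
  names(index) <- LEVEL_COLS
  structure(
    list(records = records, index = index,
         universe = sort(unique(records$gene_id))),
    class = "annotation_set"
  )
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %d genes, %d records\n",
              length(x$universe), nrow(x$records)))
  counts <- vapply(x$index, length, integer(1))
  cat(sprintf("  categories per level: %s\n",
              paste(sprintf("L%d=%d", 1:4, counts), collapse = ", ")))
  invisible(x)
}

check_level <- function(level) {
  if (length(level) != 1L || !level %in% 1:4) {
    wp_domain_error("level must be one of 1, 2, 3, 4")
  }
  as.integer(level)
}

#' Category names at a level
#'
#' @param aset an `annotation_set`.
#' @param level annotation level, 1-4.
#' @return character vector of distinct category names, lexicographically
#'   ordered (C collation, so ordering is locale-independent).
#' @export
categories_at_level <- function(aset, level) {
  stopifnot(inherits(aset, "annotation_set"))
  level <- check_level(level)
  nm <- names(aset$index[[LEVEL_COLS[level]]])
  sort_c(nm)
}

# locale-independent lexicographic sort
sort_c <- function(x) {
  old <- Sys.getlocale("LC_COLLATE")
  on.exit(suppressWarnings(Sys.setlocale("LC_COLLATE", old)), add = TRUE)
  suppressWarnings(Sys.setlocale("LC_COLLATE", "C"))
  sort(x)
}

#' Gene set of a category
#'
#' The size of the returned set is the PEA category size n.
#'
#' @param aset an `annotation_set`.
#' @param level annotation level, 1-4.
#' @param name category name (exact, case-sensitive match).
#' @return sorted character vector of gene ids.
#' @export
genes_in_category <- function(aset, level, name) {
  stopifnot(inherits(aset, "annotation_set"))
  level <- check_level(level)
  idx <- aset$index[[LEVEL_COLS[level]]]
  if (!name %in% names(idx)) {
    near <- agrep(name, names(idx), max.distance = 0.3, value = TRUE,
                  ignore.case = TRUE)
    hint <- if (length(near) > 0L) {
      sprintf("; did you mean: %s", paste(utils::head(near, 5L), collapse = ", "))
    } else ""
    wp_lookup_error(sprintf("unknown category '%s' at level %d%s", name, level, hint),
                    suggestions = near)
  }
  idx[[name]]
}

#' Pathway assignments of a gene
#'
#' All distinct (level1, level2, level3, level4) paths annotated to a gene,
#' in table order. An unannotated gene yields a zero-row data frame, not an
#' error.
#'
#' @param aset an `annotation_set`.
#' @param gene_id gene id.
#' @return data frame with columns level1..level4, one row per distinct path.
#' @export
pathways_of_gene <- function(aset, gene_id) {
  stopifnot(inherits(aset, "annotation_set"))
  rec <- aset$records[aset$records$gene_id == gene_id, LEVEL_COLS, drop = FALSE]
  rec <- unique(rec)
  rownames(rec) <- NULL
  rec
}

#' Summary statistics of an annotation hierarchy
#'
#' @param aset an `annotation_set`.
#' @return an object of class `annotation_stats`: `genes_total`,
#'   `categories_per_level` (named integer vector), `multi_pathway_fraction`
#'   (exact fraction of genes with more than one distinct full level-path),
#'   and `multi_pathway_pct` (that fraction as a percentage rounded to the
#'   nearest integer, the display convention).
#' @export
annotation_stats <- function(aset) {
  stopifnot(inherits(aset, "annotation_set"))
  counts <- vapply(aset$index, length, integer(1))
  names(counts) <- as.character(1:4)
  paths_per_gene <- table(aset$records$gene_id)  # records are already distinct paths
  frac <- if (length(paths_per_gene) == 0L) 0 else
    sum(paths_per_gene > 1L) / length(paths_per_gene)
  structure(
    list(genes_total = length(aset$universe),
         categories_per_level = counts,
         multi_pathway_fraction = frac,
         multi_pathway_pct = round(100 * frac)),
    class = "annotation_stats"
  )
}

#' @export
print.annotation_stats <- function(x, ...) {
  cat(sprintf("Annotated genes: %d\n", x$genes_total))
  cat(sprintf("Categories per level: %s\n",
              paste(sprintf("L%s=%d", names(x$categories_per_level),
                            x$categories_per_level), collapse = ", ")))
  cat(sprintf("Genes in multiple pathways: %d%%\n", x$multi_pathway_pct))
  invisible(x)
}

#' Export one annotation level as a GMT gene-set file
#'
#' Writes the standard Gene Matrix Transposed format: one set per line with
#' fields name, description (`WormPaths L<level>`), then tab-separated gene
#' ids (deduplicated, sorted). Suitable as custom gene sets for GSEA-style
#' tools.
#'
#' @param aset an `annotation_set`.
#' @param level annotation level, 1-4.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
export_gmt <- function(aset, level, path) {
  stopifnot(inherits(aset, "annotation_set"))
  level <- check_level(level)
  cats <- categories_at_level(aset, level)
  lines <- vapply(cats, function(nm) {
    genes <- genes_in_category(aset, level, nm)
    paste(c(nm, sprintf("WormPaths L%d", level), genes), collapse = "\t")
  }, "")
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) wp_io_error(sprintf("cannot write %s", path)))
  on.exit(close(con), add = TRUE)
  if (length(lines) > 0L) writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' @param path GMT file path.
#' @return named list: set name -> sorted character vector of gene ids.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) wp_io_error(sprintf("file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 2L) wp_parse_error("GMT line with fewer than 2 fields")
    out[[fields[1]]] <- sort(unique(fields[-(1:2)]))
  }
  out
}
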