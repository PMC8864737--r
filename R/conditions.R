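# Structured error conditions shared by all modules.
#
# Every user-facing failure is signalled as a classed condition so that the
# CLI layer can map it onto its exit-code contract (2 = input/schema error)
# and tests can assert on the failure class rather than on message text.
#
# Classes used throughout:
#   wp_schema_error    - malformed input table / missing column / bad header
#   wp_reference_error - a cross-reference does not resolve in the model
#   wp_lookup_error    - an id passed to a query function does not exist
#   wp_parse_error     - a gene rule / equation / map document fails to parse
#   wp_domain_error    - an argument outside its mathematical domain
#   wp_io_error        - filesystem failure

stop_wp <- function(class, msg, ...) {
  extra <- list(...)
  cond <- structure(
    class = c(class, "wp_error", "error", "condition"),
    c(list(message = msg, call = sys.call(-1)), extra)
  )
  stop(cond)
}

wp_schema_error    <- function(msg, ...) stop_wp("wp_schema_error", msg, ...)
wp_reference_error <- function(msg, ...) stop_wp("wp_reference_error", msg, ...)
wp_lookup_error    <- function(msg, ...) stop_wp("wp_lookup_error", msg, ...)
wp_parse_error     <- function(msg, ...) stop_wp("wp_parse_error", msg, ...)
wp_domain_error    <- function(msg, ...) stop_wp("wp_domain_error", msg, ...)
wp_io_error        <- function(msg, ...) stop_wp("wp_io_error", msg, ...)

# trim surrounding whitespace, vectorised
wp_trim <- function(x) trimws(x, which = "both")

# read a tab-separated table with a required header, "#" comment lines
# ignored, UTF-8; checks that `required` columns are all present.
read_wp_tsv <- function(path, required, what = "table") {
  if (!file.exists(path)) wp_io_error(sprintf("file not found: %s", path))
  df <- tryCatch(
    utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                      quote = "", stringsAsFactors = FALSE,
                      colClasses = "character", check.names = FALSE,
                      fileEncoding = "UTF-8", blank.lines.skip = TRUE),
    error = function(e) wp_schema_error(
      sprintf("cannot read %s %s: %s", what, path, conditionMessage(e)))
  )
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    wp_schema_error(sprintf("%s %s: missing column(s): %s",
                            what, path, paste(missing, collapse = ", ")),
                    columns = missing)
  }
  df
}
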