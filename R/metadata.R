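## Genome metadata: QC metrics, habitat, lifestyle and host-category labels.
##
## Metadata is carried as a data.frame with one row per genome. Required
## columns: genome_id, completeness, contamination, habitat, lifestyle;
## host_category is required to be non-empty exactly for host-associated
## genomes. Extra columns are preserved untouched.

LIFESTYLES <- c("free-living", "host-associated")

#' Read a per-genome metadata table
#'
#' Reads a tab-separated table (optionally gzipped; `#` comment lines are
#' ignored) and validates it: completeness and contamination must lie in
#' `[0, 100]`, lifestyle must be `free-living` or `host-associated`, and a
#' host category must be given if and only if the genome is host-associated.
#'
#' @param path path to a TSV file with header columns `genome_id`,
#'   `completeness`, `contamination`, `habitat`, `lifestyle` and optionally
#'   `host_category`; further columns are kept as opaque annotations.
#' @return a validated data.frame, one row per genome.
#' @export
read_genome_metadata <- function(path) {
  con <- open_input(path)
  on.exit(close(con))
  df <- utils::read.delim(con, comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE)
  validate_genome_metadata(df, where = path)
}

#' Validate a genome metadata data.frame
#'
#' @param df data.frame as described in [read_genome_metadata()].
#' @param where label for error messages.
#' @return the validated data.frame (with `host_category` column present,
#'   `NA` for free-living genomes).
#' @export
validate_genome_metadata <- function(df, where = "metadata") {
  required <- c("genome_id", "completeness", "contamination", "habitat", "lifestyle")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stopf("%s: missing required column(s): %s", where, paste(missing, collapse = ", "))
  if (!"host_category" %in% names(df)) df$host_category <- NA_character_
  df$genome_id <- as.character(df$genome_id)
  if (anyDuplicated(df$genome_id))
    stopf("%s: duplicate genome_id", where)
  for (col in c("completeness", "contamination")) {
    v <- df[[col]]
    if (!is.numeric(v) || anyNA(v) || any(v < 0 | v > 100))
      stopf("%s: column '%s' must be numeric within [0, 100]", where, col)
  }
  bad_life <- setdiff(unique(df$lifestyle), LIFESTYLES)
  if (length(bad_life) > 0L)
    stopf("%s: unknown lifestyle value(s): %s", where, paste(bad_life, collapse = ", "))
  hc <- as.character(df$host_category)
  hc[!is.na(hc) & !nzchar(trimws(hc))] <- NA_character_
  df$host_category <- hc
  host <- df$lifestyle == "host-associated"
  if (any(host & is.na(hc)))
    stopf("%s: host-associated genome(s) without host_category: %s", where,
          paste(utils::head(df$genome_id[host & is.na(hc)], 5L), collapse = ", "))
  if (any(!host & !is.na(hc)))
    stopf("%s: free-living genome(s) with host_category set: %s", where,
          paste(utils::head(df$genome_id[!host & !is.na(hc)], 5L), collapse = ", "))
  df
}

#' Filter genomes on assembly-quality estimates
#'
#' Retains genomes strictly above the completeness threshold and strictly
#' below the contamination threshold (defaults: > 90% complete, < 5%
#' contamination). Boundary values are excluded on both sides; input order is
#' preserved.
#'
#' @param metadata validated metadata data.frame.
#' @param min_completeness completeness threshold in percent (default 90).
#' @param max_contamination contamination threshold in percent (default 5).
#' @return the retained rows of `metadata`.
#' @export
qc_filter_genomes <- function(metadata, min_completeness = 90, max_contamination = 5) {
  keep <- metadata$completeness > min_completeness &
    metadata$contamination < max_contamination
  metadata[keep, , drop = FALSE]
}

#' Write a results table as TSV
#'
#' Tab-separated output with a header row, deterministic column order (as in
#' the input), and floating-point columns rendered with 6 significant digits.
#' An empty table yields a header-only file.
#'
#' @param results a data.frame (possibly with zero rows).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(results, path) {
  stopifnot(is.data.frame(results))
  out <- results
  for (col in names(out)) {
    if (is.double(out[[col]])) out[[col]] <- signif(out[[col]], 6L)
    if (is.list(out[[col]]))
      out[[col]] <- vapply(out[[col]], function(x) paste(x, collapse = ";"), "")
  }
  ok <- tryCatch({
    utils::write.table(out, file = path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, na = "")
    TRUE
  }, error = function(e) stopf("cannot write '%s': %s", path, conditionMessage(e)))
  invisible(path)
}

#' Read a results table written by [write_results_table()]
#'
#' @param path path to a TSV file.
#' @return a data.frame.
#' @export
read_results_table <- function(path) {
  con <- open_input(path)
  on.exit(close(con))
  utils::read.delim(con, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}
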