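#' Default hit-table column layout
#'
#' Column layout of a BLAST/DIAMOND tabular file produced with
#' `-outfmt "6 std staxids"`: the 12 standard columns followed by the subject
#' taxid column. Tokens follow the BLAST+ format specifier names; an optional
#' `ssciname` column carries the subject species name.
#'
#' @return Character vector of column tokens, in file order.
#' @export
hit_columns_default <- function() {
  c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
    "qstart", "qend", "sstart", "send", "evalue", "bitscore", "staxids")
}

# map BLAST-style tokens (and already-internal names) to internal column names
.hit_col_map <- c(
  qseqid = "query_id",   query_id = "query_id",
  sseqid = "subject_id", subject_id = "subject_id",
  pident = "percent_identity", percent_identity = "percent_identity",
  length = "align_length", align_length = "align_length",
  evalue = "evalue", bitscore = "bitscore",
  staxids = "subject_taxid", subject_taxid = "subject_taxid",
  ssciname = "subject_species", subject_species = "subject_species"
)

#' Parse a tabular similarity-search results file
#'
#' Reads a BLAST/DIAMOND tabular (outfmt 6 style) file into a `hit_table`.
#' Multi-taxid subject cells (`"562;1280"`, a known DIAMOND dialect) resolve
#' to the first taxid. Lines whose mandatory numeric fields do not parse are
#' rejected with their line number. Input row order is preserved; a query's
#' rows may repeat subjects (multiple HSPs).
#'
#' @param path Path to the tab-separated file (no header line).
#' @param column_spec Ordered column tokens describing the file layout; must
#'   include at least query id, subject id, evalue, bitscore and subject
#'   taxid. See [hit_columns_default()]. Unknown tokens are read and ignored.
#' @return A `hit_table`: a `data.frame` with columns `query_id`,
#'   `subject_id`, `percent_identity`, `align_length`, `evalue`, `bitscore`,
#'   `subject_taxid`, `subject_species` (NA when the file has no species
#'   column).
#' @export
parse_hit_table <- function(path, column_spec = hit_columns_default()) {
  if (!file.exists(path)) stop("hit table file not found: ", path)
  internal <- unname(.hit_col_map[column_spec])
  mandatory <- c("query_id", "subject_id", "evalue", "bitscore", "subject_taxid")
  missing_cols <- setdiff(mandatory, internal)
  if (length(missing_cols)) {
    stop("column_spec is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (!length(lines)) stop("hit table is empty: ", path)

  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_expected <- length(column_spec)
  bad_width <- which(vapply(fields, length, 0L) < n_expected)
  if (length(bad_width)) {
    stop("hit table line ", bad_width[1], " has fewer than ", n_expected,
         " fields")
  }
  mat <- do.call(rbind, lapply(fields, `[`, seq_len(n_expected)))
  colnames(mat) <- ifelse(is.na(internal), column_spec, internal)

  get_num <- function(col) {
    x <- suppressWarnings(as.numeric(mat[, col]))
    bad <- which(is.na(x))
    if (length(bad)) {
      stop("hit table line ", bad[1], ": cannot parse ", col,
           " value '", mat[bad[1], col], "'")
    }
    x
  }
  first_taxid <- function(x) sub(";.*$", "", x)
  taxid_chr <- first_taxid(mat[, "subject_taxid"])
  taxid <- suppressWarnings(as.integer(taxid_chr))
  bad <- which(is.na(taxid))
  if (length(bad)) {
    stop("hit table line ", bad[1], ": cannot parse subject_taxid value '",
         mat[bad[1], "subject_taxid"], "'")
  }

  tab <- data.frame(
    query_id = mat[, "query_id"],
    subject_id = mat[, "subject_id"],
    percent_identity = if ("percent_identity" %in% colnames(mat))
      get_num("percent_identity") else NA_real_,
    align_length = if ("align_length" %in% colnames(mat))
      as.integer(get_num("align_length")) else NA_integer_,
    evalue = get_num("evalue"),
    bitscore = get_num("bitscore"),
    subject_taxid = taxid,
    subject_species = if ("subject_species" %in% colnames(mat))
      mat[, "subject_species"] else NA_character_,
    stringsAsFactors = FALSE
  )
  if (any(tab$evalue < 0)) stop("negative e-value in hit table")
  if (any(tab$bitscore <= 0)) stop("non-positive bitscore in hit table")
  as_hit_table(tab)
}

#' Construct a hit_table from a data.frame
#'
#' @param df Data frame with at least `query_id`, `subject_id`, `evalue`,
#'   `bitscore`, `subject_taxid`.
#' @return The data frame with class `hit_table` prepended, row order kept.
#' @export
as_hit_table <- function(df) {
  mandatory <- c("query_id", "subject_id", "evalue", "bitscore", "subject_taxid")
  stopifnot(all(mandatory %in% names(df)))
  if (!"subject_species" %in% names(df)) df$subject_species <- NA_character_
  rownames(df) <- NULL
  class(df) <- unique(c("hit_table", class(df)))
  df
}

#' Split a hit table by query
#'
#' @param table A `hit_table`.
#' @return Named list of per-query data frames, each preserving input order;
#'   names are the query ids in order of first appearance.
#' @export
by_query <- function(table) {
  split(as.data.frame(table),
        factor(table$query_id, levels = unique(table$query_id)))
}

#' Hits of a single query
#'
#' @param table A `hit_table`.
#' @param query_id Query identifier.
#' @return Data frame of the query's rows, input order preserved.
#' @export
hits_for_query <- function(table, query_id) {
  as.data.frame(table)[table$query_id == query_id, , drop = FALSE]
}

#' @export
print.hit_table <- function(x, ...) {
  cat("hit_table: ", nrow(x), " records, ",
      length(unique(x$query_id)), " queries\n", sep = "")
  print(utils::head(as.data.frame(x), 6))
  invisible(x)
}
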