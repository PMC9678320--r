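#' Read a FASTA file into a named character vector
#'
#' Thin wrapper around Biostrings adding the contract checks the pipeline
#' needs: duplicate ids and empty sequences are errors, an empty file yields
#' an empty map with a warning.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, names = full header lines (ids).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (file.size(path) == 0 || !length(readLines(path, n = 1L, warn = FALSE))) {
    warning("FASTA file is empty: ", path)
    return(stats::setNames(character(0), character(0)))
  }
  ss <- Biostrings::readBStringSet(path)
  ids <- names(ss)
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate FASTA id: ", dup[1])
  seqs <- as.character(ss)
  if (any(!nzchar(seqs))) {
    stop("empty sequence for FASTA id: ", ids[which(!nzchar(seqs))[1]])
  }
  stats::setNames(seqs, ids)
}

#' Write a named character vector of sequences to FASTA
#'
#' @param seqs Named character vector (id -> sequence).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids))) stop("all sequences must be named")
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate FASTA id: ", dup[1])
  if (any(!nzchar(seqs))) {
    stop("empty sequence for FASTA id: ", ids[which(!nzchar(seqs))[1]])
  }
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Parse gene loci from a GFF3 annotation
#'
#' Retains features of one type (default `"gene"`), requires an `ID`
#' attribute on each, keeps GFF3's 1-based inclusive coordinates, and sorts
#' by (seqid, start, end): a deterministic total order that downstream
#' neighborhood scoring relies on.
#'
#' @param path Path to a GFF3 file.
#' @param feature_type Feature type to retain (column 3).
#' @return Data frame with columns `gene_id`, `seqid`, `start`, `end`,
#'   `strand`, sorted by (seqid, start, end).
#' @export
parse_gff3_genes <- function(path, feature_type = "gene") {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  g <- rtracklayer::readGFF(path)
  g <- as.data.frame(g)
  g <- g[g$type == feature_type, , drop = FALSE]
  if (nrow(g) == 0) {
    return(data.frame(gene_id = character(0), seqid = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  if (!"ID" %in% names(g) || any(is.na(g$ID)) || any(!nzchar(g$ID))) {
    stop("GFF3 '", feature_type, "' feature without an ID attribute")
  }
  loci <- data.frame(gene_id = as.character(g$ID),
                     seqid = as.character(g$seqid),
                     start = as.integer(g$start),
                     end = as.integer(g$end),
                     strand = as.character(g$strand),
                     stringsAsFactors = FALSE)
  if (any(loci$start > loci$end)) stop("GFF3 locus with start > end")
  loci[order(loci$seqid, loci$start, loci$end, loci$gene_id), , drop = FALSE]
}
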