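#' Build a taxonomy database from a nodes + names dump
#'
#' Accepts the two-file flavour of an NCBI-style taxonomy dump: a nodes table
#' (taxid, parent taxid, rank) and a names table (taxid, name). Lineages are
#' flattened root-to-leaf at construction time, so lookups are O(1) and the
#' prefix-consistency invariant (a child's lineage extends its parent's) holds
#' by construction.
#'
#' @param nodes Data frame with columns `taxid`, `parent`, `rank`, or path to
#'   a headerless TSV with those three columns.
#' @param names Data frame with columns `taxid`, `name`, or path to a
#'   headerless two-column TSV.
#' @return A `taxonomy_db`: list with `lineage` (named list, taxid ->
#'   data.frame(rank, name, taxid) from root to the taxid itself) and `names`
#'   (named integer vector, name -> taxid).
#' @export
taxonomy_from_dump <- function(nodes, names) {
  if (is.character(nodes)) {
    nodes <- utils::read.delim(nodes, header = FALSE,
                               col.names = c("taxid", "parent", "rank"),
                               colClasses = c("integer", "integer", "character"))
  }
  if (is.character(names)) {
    names <- utils::read.delim(names, header = FALSE,
                               col.names = c("taxid", "name"),
                               colClasses = c("integer", "character"))
  }
  stopifnot(all(c("taxid", "parent", "rank") %in% base::names(nodes)),
            all(c("taxid", "name") %in% base::names(names)))
  parent <- stats::setNames(nodes$parent, nodes$taxid)
  rank <- stats::setNames(nodes$rank, nodes$taxid)
  nm <- stats::setNames(names$name, names$taxid)

  lineage <- new.env(parent = emptyenv())
  walk <- function(taxid) {
    key <- as.character(taxid)
    hit <- lineage[[key]]
    if (!is.null(hit)) return(hit)
    chain <- integer(0)
    t <- taxid
    repeat {
      chain <- c(t, chain)
      p <- parent[[as.character(t)]]
      if (is.null(p) || is.na(p) || p == t) break
      t <- p
      if (length(chain) > 100L) stop("taxonomy cycle at taxid ", taxid)
    }
    lin <- data.frame(
      rank = unname(rank[as.character(chain)]),
      name = unname(nm[as.character(chain)]),
      taxid = chain,
      stringsAsFactors = FALSE
    )
    lineage[[key]] <- lin
    lin
  }
  for (t in nodes$taxid) walk(t)
  db <- list(
    lineage = as.list(lineage),
    names = stats::setNames(as.integer(base::names(nm)), unname(nm))
  )
  class(db) <- "taxonomy_db"
  db
}

#' Build a taxonomy database from a pre-flattened lineage TSV
#'
#' Each line: `taxid<TAB>name1;name2;...;nameN` where the names run from the
#' root to the taxid's own name. Ranks are not carried by this format and are
#' recorded as `"no rank"`; ancestor taxids other than the line's own are NA.
#'
#' @param path Path to the TSV.
#' @return A `taxonomy_db` (see [taxonomy_from_dump()]).
#' @export
taxonomy_from_lineage_tsv <- function(path) {
  if (!file.exists(path)) stop("lineage file not found: ", path)
  df <- utils::read.delim(path, header = FALSE,
                          col.names = c("taxid", "lineage"),
                          colClasses = c("integer", "character"))
  lineage <- lapply(seq_len(nrow(df)), function(i) {
    nms <- strsplit(df$lineage[i], ";", fixed = TRUE)[[1]]
    n <- length(nms)
    data.frame(rank = rep("no rank", n), name = nms,
               taxid = c(rep(NA_integer_, n - 1L), df$taxid[i]),
               stringsAsFactors = FALSE)
  })
  base::names(lineage) <- as.character(df$taxid)
  leaf_names <- vapply(lineage, function(l) l$name[nrow(l)], "")
  db <- list(lineage = lineage,
             names = stats::setNames(df$taxid, unname(leaf_names)))
  class(db) <- "taxonomy_db"
  db
}

#' Lineage names of a taxid
#'
#' @param tax A `taxonomy_db`.
#' @param taxid Integer taxid.
#' @return Character vector of lineage names root-to-leaf, or `NULL` when the
#'   taxid is not present in the database.
#' @export
lineage_names <- function(tax, taxid) {
  lin <- tax$lineage[[as.character(taxid)]]
  if (is.null(lin)) NULL else lin$name
}

#' Define the Ingroup for an analysis
#'
#' The Ingroup is the user-defined lineage considered closely related to the
#' query species; every other resolvable taxon is a potential Donor. Taxa
#' under any `excluded_names` lineage are ignored entirely (for example the
#' query's own phylum, when scanning for transfers already shared with close
#' relatives).
#'
#' @param ingroup_names Non-empty character vector of lineage names defining
#'   the Ingroup.
#' @param query_taxid Taxid of the query species itself.
#' @param excluded_names Character vector (possibly empty) of lineage names
#'   to exclude from all computations.
#' @return An `ingroup_spec` list.
#' @export
ingroup_spec <- function(ingroup_names, query_taxid, excluded_names = character(0)) {
  if (!length(ingroup_names)) stop("ingroup_names must be non-empty")
  spec <- list(ingroup_names = as.character(ingroup_names),
               excluded_names = as.character(excluded_names),
               query_taxid = as.integer(query_taxid))
  class(spec) <- "ingroup_spec"
  spec
}

#' Taxonomic affiliation of a taxid
#'
#' Resolves a subject taxid to one of `EXCLUDED`, `QUERY`, `INGROUP`,
#' `UNKNOWN` or `DONOR`, in that order of precedence: exclusion wins over
#' everything (so a query-phylum relative never masquerades as Ingroup or
#' Donor), the query species' own taxid is `QUERY`, membership of any ingroup
#' lineage gives `INGROUP`, an unresolvable taxid gives `UNKNOWN`, and
#' everything else is `DONOR`. Total: never errors.
#'
#' @param taxid Integer taxid(s); vectorised.
#' @param spec An [ingroup_spec()].
#' @param tax A `taxonomy_db`.
#' @return Character vector of affiliations.
#' @export
affiliate <- function(taxid, spec, tax) {
  vapply(as.integer(taxid), function(t) {
    lin <- if (is.na(t)) NULL else lineage_names(tax, t)
    if (!is.null(lin) && any(lin %in% spec$excluded_names)) return("EXCLUDED")
    if (!is.na(t) && t == spec$query_taxid) return("QUERY")
    if (!is.null(lin) && any(lin %in% spec$ingroup_names)) return("INGROUP")
    if (is.null(lin)) return("UNKNOWN")
    "DONOR"
  }, "")
}

#' @export
print.taxonomy_db <- function(x, ...) {
  cat("taxonomy_db: ", length(x$lineage), " taxids\n", sep = "")
  invisible(x)
}
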