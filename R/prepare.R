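#' Fraction of shared database hits between two queries
#'
#' `|A ∩ B| / min(|A|, |B|)` by default (so a small query fully nested in a
#' large one scores 1), or Jaccard (`|A ∩ B| / |A ∪ B|`) when
#' `denominator = "union"`. 0 when either set is empty.
#'
#' @param hits_a,hits_b Character vectors of subject ids.
#' @param denominator `"min"` (default) or `"union"`.
#' @return Fraction in [0, 1].
#' @export
shared_hit_fraction <- function(hits_a, hits_b, denominator = c("min", "union")) {
  denominator <- match.arg(denominator)
  a <- unique(hits_a); b <- unique(hits_b)
  if (!length(a) || !length(b)) return(0)
  inter <- length(intersect(a, b))
  d <- if (denominator == "min") min(length(a), length(b))
       else length(union(a, b))
  inter / d
}

#' Group candidate queries by shared hits (single linkage)
#'
#' Builds a graph over the candidate queries with an edge wherever the
#' shared-hit fraction reaches `threshold`, and returns its connected
#' components: single-linkage clusters, so two queries in one group are
#' connected by a chain of pairwise overlaps even if they share little
#' directly. Groups are numbered by their lexicographically smallest member,
#' making the output invariant to candidate input order.
#'
#' @param candidates Character vector of query ids (must appear in `table`,
#'   or be grouped as hitless singletons with a warning).
#' @param table A `hit_table`.
#' @param threshold Minimum shared-hit fraction for an edge (default 0.7).
#' @param denominator Passed to [shared_hit_fraction()].
#' @return List of `query_group`s: each a list with `group_id` (integer),
#'   `query_ids` (sorted character), `hit_subject_ids` (union of members'
#'   hits). The groups partition `candidates`.
#' @export
group_queries <- function(candidates, table, threshold = 0.7,
                          denominator = "min") {
  candidates <- sort(unique(as.character(candidates)))
  if (!length(candidates)) return(list())
  hit_sets <- lapply(candidates, function(q)
    unique(table$subject_id[table$query_id == q]))
  names(hit_sets) <- candidates
  empty <- candidates[vapply(hit_sets, length, 0L) == 0]
  if (length(empty)) {
    warning("candidate(s) with zero hits grouped as singletons: ",
            paste(empty, collapse = ", "))
  }
  n <- length(candidates)
  edges <- integer(0)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq((i + 1), n)) {
        f <- shared_hit_fraction(hit_sets[[i]], hit_sets[[j]], denominator)
        if (f >= threshold) edges <- c(edges, i, j)
      }
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)$membership
  members <- split(candidates, comp)
  members <- members[order(vapply(members, min, ""))]
  out <- lapply(seq_along(members), function(k) {
    qs <- sort(members[[k]])
    grp <- list(group_id = k, query_ids = qs,
                hit_subject_ids = sort(unique(unlist(hit_sets[qs]))))
    class(grp) <- "query_group"
    grp
  })
  out
}

#' Load user-generated query groups
#'
#' Reads a TSV with one group per line: `group_id<TAB>q1,q2<TAB>s1,s2,...`
#' (e.g. exported from an orthology inference run). Groups are taken
#' verbatim; a query appearing in two groups is an error. A group with an
#' empty hits field is kept and flagged `no_hits`.
#'
#' @param path Path to the TSV.
#' @return List of `query_group`s.
#' @export
load_user_groups <- function(path) {
  if (!file.exists(path)) stop("group file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("group file is empty: ", path)
  split_csv <- function(x) {
    out <- strsplit(x, ",", fixed = TRUE)[[1]]
    out[nzchar(trimws(out))]
  }
  groups <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 2) stop("group file line ", i, ": expected >= 2 fields")
    hits <- if (length(f) >= 3) split_csv(f[3]) else character(0)
    grp <- list(group_id = i, query_ids = sort(split_csv(f[2])),
                hit_subject_ids = sort(unique(hits)),
                label = f[1])
    if (!length(hits)) grp$flag <- "no_hits"
    class(grp) <- "query_group"
    grp
  })
  all_q <- unlist(lapply(groups, `[[`, "query_ids"))
  dup <- unique(all_q[duplicated(all_q)])
  if (length(dup)) {
    stop("query present in more than one group: ", paste(dup, collapse = ", "))
  }
  groups
}

#' Build the FASTA input of one group's phylogeny
#'
#' Collects every group query plus, per query, its top `max_hits_per_query`
#' hits by bitscore; shared hits are written once. Database-hit headers
#' encode the subject taxid as `subject_id|taxid` so that tree leaves can be
#' re-affiliated downstream without the hit table.
#'
#' @param group A `query_group`.
#' @param query_seqs Named character vector of query-species sequences.
#' @param db_seqs Named character vector of database sequences (by subject id).
#' @param table A `hit_table` (supplies per-query rankings and taxids).
#' @param path Output FASTA path.
#' @param max_hits_per_query Per-query cap on retained hits (default 100).
#' @return `path` invisibly, with attributes `n_sequences` and `too_small`
#'   (TRUE when fewer than 4 sequences were written, too few for a
#'   phylogeny).
#' @export
build_group_fasta <- function(group, query_seqs, db_seqs, table, path,
                              max_hits_per_query = 100) {
  missing_q <- setdiff(group$query_ids, names(query_seqs))
  if (length(missing_q)) {
    stop("query sequence(s) missing from FASTA: ",
         paste(missing_q, collapse = ", "))
  }
  taxid_of <- stats::setNames(table$subject_taxid, table$subject_id)
  kept <- character(0)
  for (q in group$query_ids) {
    hits <- hits_for_query(table, q)
    hits <- hits[hits$subject_id %in% group$hit_subject_ids, , drop = FALSE]
    o <- order(-hits$bitscore, hits$evalue, seq_len(nrow(hits)))
    subj <- unique(hits$subject_id[o])
    kept <- union(kept, utils::head(subj, max_hits_per_query))
  }
  missing_s <- setdiff(kept, names(db_seqs))
  if (length(missing_s)) {
    stop("database sequence(s) missing: ", paste(missing_s, collapse = ", "))
  }
  out <- c(
    stats::setNames(query_seqs[group$query_ids], group$query_ids),
    stats::setNames(db_seqs[kept],
                    paste0(kept, "|", taxid_of[kept]))
  )
  write_fasta(out, path)
  n <- length(out)
  if (n < 4) {
    warning("group ", group$group_id, ": only ", n,
            " sequences, too small for phylogeny")
  }
  structure(invisible(path), n_sequences = n, too_small = n < 4)
}

#' @keywords internal
#' fill {placeholders} in a command template and split into argv
.fill_template <- function(template, values) {
  for (k in names(values)) {
    template <- gsub(paste0("{", k, "}"), values[[k]], template, fixed = TRUE)
  }
  argv <- strsplit(trimws(template), "[[:space:]]+")[[1]]
  argv
}

#' @keywords internal
.run_tool <- function(argv, tool_name, stdout_file = NULL) {
  exe <- Sys.which(argv[1])
  if (!nzchar(exe)) {
    stop("external tool not found on PATH: ", tool_name, " ('", argv[1], "')")
  }
  err_file <- tempfile("stderr-")
  status <- system2(exe, argv[-1],
                    stdout = if (is.null(stdout_file)) FALSE else stdout_file,
                    stderr = err_file)
  if (!identical(status, 0L)) {
    msg <- paste(readLines(err_file, warn = FALSE), collapse = "\n")
    stop(tool_name, " failed (exit ", status, "):\n", msg)
  }
  invisible(TRUE)
}

#' Align one group FASTA (MAFFT, optional trimAl trimming)
#'
#' Runs the configured aligner command on the group FASTA and, optionally,
#' the trimming command on the alignment. Both tools are invoked as
#' subprocesses from `{placeholder}` command templates; their algorithms are
#' never re-implemented. The sequence id set must survive both steps (the
#' trimming mode must not drop sequences).
#'
#' @param fasta Input FASTA path.
#' @param out Output alignment path (default `<fasta>.aln`).
#' @param trim Apply the trimming step.
#' @param mafft_cmd Aligner template; `{input}` is substituted, alignment is
#'   read from stdout.
#' @param trimal_cmd Trimmer template; `{input}` and `{output}` substituted.
#' @return Path to the alignment, invisibly.
#' @export
align_group <- function(fasta, out = paste0(fasta, ".aln"), trim = FALSE,
                        mafft_cmd = "mafft --auto --quiet --anysymbol {input}",
                        trimal_cmd = "trimal -in {input} -out {output} -gappyout") {
  ids_in <- names(read_fasta(fasta))
  argv <- .fill_template(mafft_cmd, list(input = fasta))
  .run_tool(argv, "mafft", stdout_file = out)
  if (trim) {
    tmp <- paste0(out, ".untrimmed")
    file.rename(out, tmp)
    argv <- .fill_template(trimal_cmd, list(input = tmp, output = out))
    .run_tool(argv, "trimal")
  }
  ids_out <- names(read_fasta(out))
  if (!setequal(ids_in, ids_out)) {
    stop("alignment dropped sequences: ",
         paste(setdiff(ids_in, ids_out), collapse = ", "))
  }
  invisible(out)
}
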