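#' Assign a putative origin to a confirmed HGT candidate
#'
#' Given the Donor leaves of the candidate's sister clade and a nested rank
#' hierarchy (coarse to fine, e.g. `c("Bacteria", "Proteobacteria")`),
#' returns the deepest rank whose label is contained in at least `threshold`
#' of the donor leaves' lineages — the same majority logic used for branch
#' tagging. `"ambiguous"` when not even the coarsest rank reaches the
#' threshold.
#'
#' @param donor_taxids Integer taxids of the donor leaves (one per leaf;
#'   repeats allowed and counted).
#' @param tax A `taxonomy_db`.
#' @param ranks Character vector of nested rank labels, coarse to fine.
#' @param threshold Fraction of leaves required (default 0.8).
#' @return A rank label or `"ambiguous"`.
#' @export
assign_origin <- function(donor_taxids, tax, ranks, threshold = 0.8) {
  if (!length(donor_taxids)) return("ambiguous")
  lineages <- lapply(donor_taxids, function(t) lineage_names(tax, t))
  for (r in rev(ranks)) {
    frac <- mean(vapply(lineages, function(l) !is.null(l) && r %in% l, TRUE))
    if (frac >= threshold) return(r)
  }
  "ambiguous"
}

#' Build the constrained (no-HGT) topology for evaluation
#'
#' The alternative hypothesis to HGT is vertical inheritance, under which
#' the query must group with its relatives: the constraint forces a single
#' monophyletic group of the query sequence plus all Ingroup sequences,
#' leaving the Donor sequences unresolved outside it:
#' `((query, i1, ..., im), d1, ..., dk);` (multifurcating, no branch
#' lengths).
#'
#' @param leaf_ids All leaf labels of the group alignment.
#' @param query_id The query's leaf label.
#' @param affiliations Named affiliation vector over `leaf_ids`.
#' @return Newick string, or `NULL` (with a warning) when there is no
#'   Ingroup leaf to constrain.
#' @export
build_constraint_tree <- function(leaf_ids, query_id, affiliations) {
  stopifnot(query_id %in% leaf_ids)
  others <- setdiff(leaf_ids, query_id)
  ingroup <- others[affiliations[others] == "INGROUP"]
  outside <- setdiff(others, ingroup)
  if (!length(ingroup)) {
    warning("nothing to constrain: no Ingroup leaves for ", query_id)
    return(NULL)
  }
  clade <- paste(c(query_id, ingroup), collapse = ",")
  if (!length(outside)) return(sprintf("(%s);", clade))
  sprintf("((%s),%s);", clade, paste(outside, collapse = ","))
}

#' Parse a tree-topology test report
#'
#' Reads the plain-text USER TREES table that IQ-TREE appends to its report
#' file: a header naming the statistics (`logL`, `deltaL`, `bp-RELL`,
#' `p-KH`, ..., `p-AU`) followed by one row per topology where each test
#' value is followed by a `+`/`-` significance mark. Whitespace-tolerant.
#'
#' @param path Path to the report file.
#' @param topology_ids Labels for the rows, in submission order (default
#'   `c("original", "constrained")`).
#' @return Data frame with a `topology` column plus one numeric column per
#'   statistic (names with `-` mapped to `_`, e.g. `p_AU`).
#' @export
parse_topology_report <- function(path, topology_ids = c("original", "constrained")) {
  if (!file.exists(path)) stop("report file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("\\blogL\\b", lines)
  hdr <- hdr[grepl("p-AU", lines[hdr])]
  if (!length(hdr)) {
    if (any(grepl("\\blogL\\b", lines))) {
      stop("topology report is missing the p-AU column")
    }
    stop("topology report is missing the logL/p-AU table")
  }
  hdr <- hdr[1]
  stats_names <- strsplit(trimws(sub("^\\s*Tree\\s*", "", lines[hdr])),
                          "\\s+")[[1]]
  rows <- list()
  for (ln in lines[(hdr + 1):length(lines)]) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (!length(tok) || !grepl("^[0-9]+$", tok[1])) {
      if (length(rows)) break else next
    }
    vals <- suppressWarnings(as.numeric(tok[tok != "+" & tok != "-"][-1]))
    if (length(vals) != length(stats_names) || any(is.na(vals))) {
      stop("cannot parse topology report row: ", ln)
    }
    rows[[length(rows) + 1]] <- vals
  }
  if (!length(rows)) stop("topology report has no tree rows")
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- gsub("-", "_", stats_names, fixed = TRUE)
  out <- cbind(topology = topology_ids[seq_len(nrow(out))], out,
               stringsAsFactors = FALSE)
  out
}

#' Run constrained inference and topology tests via external tools
#'
#' Orchestrates the evaluation step: (i) infer a constrained tree from the
#' group alignment under the monophyly constraint, (ii) submit the original
#' and constrained topologies to a topology-test run, (iii) parse the
#' resulting report. Both steps are external commands given as
#' `{placeholder}` templates (an IQ-TREE-style toolchain); their internals
#' are never re-implemented.
#'
#' @param alignment Path to the group alignment.
#' @param original_tree Path to the unconstrained gene tree (newick).
#' @param constraint_tree Path to the constraint newick from
#'   [build_constraint_tree()].
#' @param constrained_cmd Template for constrained inference; placeholders
#'   `{alignment}`, `{constraint}`, `{output}` (the constrained tree file the
#'   command must produce).
#' @param test_cmd Template for the topology-test run; placeholders
#'   `{alignment}`, `{trees}` (a file with both newicks, original first),
#'   `{report}` (the report file the command must produce).
#' @param workdir Directory for intermediate files.
#' @return Data frame from [parse_topology_report()].
#' @export
run_topology_tests <- function(alignment, original_tree, constraint_tree,
    constrained_cmd = paste("iqtree2 -s {alignment} -g {constraint}",
                            "-pre {output} -m LG -quiet"),
    test_cmd = paste("iqtree2 -s {alignment} -z {trees} -n 0 -zb 10000 -au",
                     "-pre {report} -m LG -quiet"),
    workdir = tempfile("evaluate-")) {
  dir.create(workdir, showWarnings = FALSE, recursive = TRUE)
  constrained_out <- file.path(workdir, "constrained.treefile")
  argv <- .fill_template(constrained_cmd,
                         list(alignment = alignment,
                              constraint = constraint_tree,
                              output = constrained_out))
  .run_tool(argv, "tree builder (constrained search)")
  trees_file <- file.path(workdir, "both.trees")
  writeLines(c(readLines(original_tree, warn = FALSE),
               readLines(constrained_out, warn = FALSE)), trees_file)
  report <- file.path(workdir, "topotest.report")
  argv <- .fill_template(test_cmd, list(alignment = alignment,
                                        trees = trees_file, report = report))
  .run_tool(argv, "topology test")
  parse_topology_report(report)
}

#' Decide whether the HGT topology is preferred
#'
#' The constrained (vertical-inheritance) topology is compared to the
#' observed one via the approximately-unbiased (AU) test: when the AU
#' p-value of the constrained topology falls below `alpha` the constraint is
#' rejected and the HGT topology is `STRONG`ly preferred; otherwise the two
#' are statistically indistinguishable (`EQUAL`) and the candidate is
#' downgraded in the final report.
#'
#' @param result Data frame from [parse_topology_report()], containing a
#'   `topology == "constrained"` row with a `p_AU` column.
#' @param alpha Significance level (default 0.05).
#' @return `"STRONG"` or `"EQUAL"`.
#' @export
evaluate_decision <- function(result, alpha = 0.05) {
  p <- result$p_AU[result$topology == "constrained"]
  if (!length(p) || is.na(p)) stop("no AU p-value for the constrained topology")
  if (p < alpha) "STRONG" else "EQUAL"
}
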