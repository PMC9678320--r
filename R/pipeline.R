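#' Read and validate a run configuration
#'
#' Loads a YAML run config, fills defaults, and validates fractions and
#' referenced paths. Keys: `paths` (query_fasta, db_fasta, hit_table,
#' taxonomy_nodes/taxonomy_names or taxonomy_lineage, optional gff,
#' optional tree_dir, out_dir), `hit_columns`, `ingroup`, `exclude`,
#' `query_taxid`, `thresholds` (candidate_predicate, shared_hit,
#' tag_majority, branch_support, evaluate_alpha, local_score_window),
#' `tools` (mafft, trimal, fasttree, iqtree command templates), and
#' optional `ranks` for origin classification.
#'
#' @param path Path to a YAML file.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  defaults <- list(
    hit_columns = hit_columns_default(),
    exclude = character(0),
    thresholds = list(candidate_predicate = "AI > 0 | AHS > 0",
                      shared_hit = 0.7, tag_majority = 0.8,
                      branch_support = 0, evaluate_alpha = 0.05,
                      local_score_window = 10, max_hits_per_query = 100),
    tools = list(
      mafft = "mafft --auto --quiet --anysymbol {input}",
      trimal = "trimal -in {input} -out {output} -gappyout",
      fasttree = "fasttree -gamma -lg {input}",
      iqtree = "iqtree2 -s {input} -mset WAG,LG,JTT -AICc -mrate E,I,G,R"
    ),
    steps = list(classify = FALSE, evaluate = FALSE, hgt_local_score = FALSE)
  )
  cfg <- utils::modifyList(defaults, cfg)
  th <- cfg$thresholds
  fr <- c(shared_hit = th$shared_hit, tag_majority = th$tag_majority,
          evaluate_alpha = th$evaluate_alpha)
  if (any(fr < 0 | fr > 1)) stop("config fractions must lie in [0, 1]")
  for (key in c("query_fasta", "db_fasta", "hit_table")) {
    p <- cfg$paths[[key]]
    if (!is.null(p) && !file.exists(p)) {
      stop("config path '", key, "' does not exist: ", p)
    }
  }
  class(cfg) <- "run_config"
  cfg
}

#' @keywords internal
.load_taxonomy_from_config <- function(cfg) {
  p <- cfg$paths
  if (!is.null(p$taxonomy_lineage)) {
    taxonomy_from_lineage_tsv(p$taxonomy_lineage)
  } else {
    taxonomy_from_dump(p$taxonomy_nodes, p$taxonomy_names)
  }
}

#' Run the full detection pipeline
#'
#' Orchestrates metrics -> candidate selection -> grouping -> group FASTA ->
#' gene trees -> per-query classification, then the optional origin
#' classification, topology evaluation and genomic-neighborhood scoring
#' steps, writing every intermediate into `out_dir`. Stages whose output
#' files already exist are skipped, so an interrupted run resumes from its
#' intermediates. The final report joins metrics, verdict, origin,
#' evaluation status and local score per selected candidate.
#'
#' Gene trees come from, in order of precedence: `tree_fun` (a
#' `function(group_fasta, group) -> phylo`, used by the synthetic test
#' harness), a directory of user-supplied newick files named
#' `group_<k>.nwk` (`paths$tree_dir`), or alignment + the configured
#' external tree builder.
#'
#' @param config A `run_config` (or path to one).
#' @param tree_fun Optional tree-builder override.
#' @param force Recompute stages even when outputs exist.
#' @return Invisibly, the final report data frame (also written to
#'   `out_dir/report.tsv`).
#' @export
run_pipeline <- function(config, tree_fun = NULL, force = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  p <- config$paths
  th <- config$thresholds
  out <- p$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) message("[hgtphylo] ", ...)

  tax <- .load_taxonomy_from_config(config)
  spec <- ingroup_spec(config$ingroup, config$query_taxid,
                       unlist(config$exclude))
  table <- parse_hit_table(p$hit_table, config$hit_columns)

  # stage 1: metrics
  metrics_file <- file.path(out, "metrics.tsv")
  if (force || !file.exists(metrics_file)) {
    log_msg("computing screening metrics")
    metrics <- compute_metrics(table, spec, tax)
    utils::write.table(metrics, metrics_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    log_msg("metrics.tsv exists, skipping")
    metrics <- utils::read.delim(metrics_file, stringsAsFactors = FALSE)
  }

  # stage 2: candidate selection + grouping
  groups_file <- file.path(out, "groups.tsv")
  candidates <- select_candidates(metrics, th$candidate_predicate)
  if (force || !file.exists(groups_file)) {
    log_msg(length(candidates), " candidate(s) selected by ",
            th$candidate_predicate)
    groups <- if (!is.null(p$groups_file)) {
      load_user_groups(p$groups_file)
    } else {
      group_queries(candidates, table, th$shared_hit)
    }
    lines <- vapply(groups, function(g) {
      paste(g$group_id, paste(g$query_ids, collapse = ","),
            paste(g$hit_subject_ids, collapse = ","), sep = "\t")
    }, "")
    writeLines(lines, groups_file)
  } else {
    log_msg("groups.tsv exists, skipping")
    groups <- load_user_groups(groups_file)
  }

  # stage 3: per-group FASTA + tree
  query_seqs <- read_fasta(p$query_fasta)
  db_seqs <- read_fasta(p$db_fasta)
  tree_dir <- file.path(out, "trees")
  dir.create(tree_dir, showWarnings = FALSE)
  results <- list()
  for (g in groups) {
    fasta <- file.path(out, sprintf("group_%d.fasta", g$group_id))
    if (force || !file.exists(fasta)) {
      build_group_fasta(g, query_seqs, db_seqs, table, fasta,
                        th$max_hits_per_query)
    }
    n_seq <- length(read_fasta(fasta))
    if (n_seq < 4) {
      log_msg("group ", g$group_id, ": too few homologs, COMPLEX by default")
      for (q in g$query_ids) {
        results[[q]] <- data.frame(query_id = q, verdict = "COMPLEX",
                                   sb_tag = NA, asb_tag = NA,
                                   flag = "too_few_homologs",
                                   stringsAsFactors = FALSE)
      }
      next
    }
    tree_file <- file.path(tree_dir, sprintf("group_%d.nwk", g$group_id))
    if (force || !file.exists(tree_file)) {
      if (!is.null(tree_fun)) {
        tree <- tree_fun(fasta, g)
        ape::write.tree(tree, tree_file)
      } else if (!is.null(p$tree_dir)) {
        src <- file.path(p$tree_dir, sprintf("group_%d.nwk", g$group_id))
        if (!file.exists(src)) stop("user tree missing for group ",
                                    g$group_id, ": ", src)
        file.copy(src, tree_file)
      } else {
        aln <- align_group(fasta, trim = FALSE,
                           mafft_cmd = config$tools$mafft,
                           trimal_cmd = config$tools$trimal)
        argv <- .fill_template(config$tools$fasttree, list(input = aln))
        .run_tool(argv, "tree builder", stdout_file = tree_file)
      }
    }
    tree <- ape::read.tree(tree_file)
    for (q in g$query_ids) {
      res <- detect_query(tree, q, spec, tax,
                          min_support = th$branch_support,
                          majority_threshold = th$tag_majority)
      write_nexus(res$tree, res$affiliations,
                  file.path(tree_dir, paste0(q, ".nexus")))
      results[[q]] <- data.frame(
        query_id = q, verdict = res$verdict, sb_tag = res$sb_tag,
        asb_tag = res$asb_tag,
        flag = if (length(res$flags)) paste(res$flags, collapse = ";") else "",
        stringsAsFactors = FALSE)
    }
  }
  classification <- if (length(results)) do.call(rbind, results) else
    data.frame(query_id = character(0), verdict = character(0),
               sb_tag = character(0), asb_tag = character(0),
               flag = character(0), stringsAsFactors = FALSE)
  utils::write.table(classification, file.path(out, "classification.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  report <- merge(metrics[metrics$query_id %in% candidates,
                          c("query_id", "AI", "h", "outg_pct", "AHS", "flag")],
                  classification, by = "query_id", all.x = TRUE,
                  suffixes = c("_metrics", ""))

  # optional: local score
  if (isTRUE(config$steps$hgt_local_score) && !is.null(p$gff)) {
    log_msg("computing genomic neighborhood scores")
    loci <- parse_gff3_genes(p$gff)
    statuses <- stats::setNames(classification$verdict,
                                classification$query_id)
    cand_hgt <- classification$query_id[classification$verdict == "HGT"]
    cand_hgt <- intersect(cand_hgt, loci$gene_id)
    scored <- score_all_candidates(cand_hgt, loci, statuses,
                                   window = th$local_score_window)
    utils::write.table(scored$summary, file.path(out, "local_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report <- merge(report,
                    scored$summary[, c("gene_id", "score", "alert")],
                    by.x = "query_id", by.y = "gene_id", all.x = TRUE)
  }

  utils::write.table(report, file.path(out, "report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  log_msg("report written: ", file.path(out, "report.tsv"))
  invisible(report)
}
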