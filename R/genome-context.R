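#' Default per-status contribution weights for the local score
#'
#' A neighbor supports the HGT-insertion hypothesis when it looks native
#' (vertically inherited) and supports the contamination hypothesis when it
#' is itself an HGT candidate: `NO` (tree says no HGT) and `NOT_TESTED`
#' (never passed metric screening, i.e. Ingroup-dominated homology) count
#' +1; `HGT` counts -1; `COMPLEX` counts -0.5; `NO_HITS` (no homology
#' information) is neutral at 0. Every value is a configuration key.
#'
#' @return Named numeric vector status -> weight in [-1, 1].
#' @export
default_status_weights <- function() {
  c(NO = 1, NOT_TESTED = 1, COMPLEX = -0.5, HGT = -1, NO_HITS = 0)
}

#' Genomic neighborhood score of one HGT candidate
#'
#' Looks at up to `window` annotated genes on each side of the candidate on
#' the same scaffold (rank-based: intergenic distances and strand are
#' ignored) and averages their status weights. The score lies in [-1, +1]:
#' +1 when every neighbor looks native (a genuine HGT insertion in the
#' genome), -1 when every neighbor is itself an HGT candidate (the
#' signature of a contaminant block in the assembly).
#'
#' @param gene_id Candidate gene id (must be present in `loci`).
#' @param loci Gene loci from [parse_gff3_genes()] (sorted).
#' @param statuses Named character vector gene_id -> status in
#'   `names(default_status_weights())`; genes absent from the map count as
#'   `NOT_TESTED`.
#' @param window Genes per side (default 10).
#' @param weights Status weights (see [default_status_weights()]).
#' @return List (`local_score_result`): `gene_id`, `score` (NA when the
#'   gene has no neighbor on its scaffold), `neighbors_used`,
#'   `contributions` (data frame gene_id/status/weight), `flags`.
#' @export
hgt_local_score <- function(gene_id, loci, statuses, window = 10,
                            weights = default_status_weights()) {
  stopifnot(window >= 1)
  i <- which(loci$gene_id == gene_id)
  if (!length(i)) stop("gene not found in annotation: ", gene_id)
  i <- i[1]
  same <- which(loci$seqid == loci$seqid[i])
  pos <- match(i, same)
  left <- same[seq_len(pos - 1)]
  left <- utils::tail(left, window)
  right <- same[same > i]
  right <- utils::head(right, window)
  nb <- c(left, right)
  if (!length(nb)) {
    return(structure(list(gene_id = gene_id, score = NA_real_,
                          neighbors_used = 0L,
                          contributions = NULL,
                          flags = "no_neighbors"),
                     class = "local_score_result"))
  }
  st <- statuses[loci$gene_id[nb]]
  st[is.na(st)] <- "NOT_TESTED"
  bad <- setdiff(unique(st), names(weights))
  if (length(bad)) stop("status without a weight: ", paste(bad, collapse = ", "))
  w <- unname(weights[st])
  structure(list(gene_id = gene_id, score = mean(w),
                 neighbors_used = length(nb),
                 contributions = data.frame(gene_id = loci$gene_id[nb],
                                            status = unname(st), weight = w,
                                            stringsAsFactors = FALSE),
                 flags = character(0)),
            class = "local_score_result")
}

#' Score all HGT candidates and flag possible contamination
#'
#' Runs [hgt_local_score()] over a candidate list and summarises: candidates
#' scoring below `alert_threshold` (default 0) are listed as possible
#' contamination. The alert is a caveat, not a verdict — HGT of a whole
#' block of genes, or duplication after acquisition, can also produce
#' negative scores.
#'
#' @inheritParams hgt_local_score
#' @param candidates Character vector of candidate gene ids.
#' @param alert_threshold Scores strictly below this raise an alert.
#' @return List with `results` (per-candidate `local_score_result`s),
#'   `summary` (data frame gene_id/score/neighbors_used/alert) and `caveat`
#'   (the block-transfer caveat string).
#' @export
score_all_candidates <- function(candidates, loci, statuses, window = 10,
                                 weights = default_status_weights(),
                                 alert_threshold = 0) {
  results <- lapply(candidates, hgt_local_score, loci = loci,
                    statuses = statuses, window = window, weights = weights)
  summary <- data.frame(
    gene_id = as.character(candidates),
    score = vapply(results, function(r) r$score, 0),
    neighbors_used = vapply(results, function(r) r$neighbors_used, 0L),
    stringsAsFactors = FALSE
  )
  summary$alert <- !is.na(summary$score) & summary$score < alert_threshold
  list(results = results, summary = summary,
       caveat = paste("negative scores flag possible contamination;",
                      "HGT of a whole block of genes or duplications after",
                      "acquisition are also possible"))
}
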