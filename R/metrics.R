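#' @keywords internal
#' best hit = lowest e-value, then highest bitscore, then input order
.best_hit <- function(hits) {
  if (!nrow(hits)) return(NULL)
  o <- order(hits$evalue, -hits$bitscore, seq_len(nrow(hits)))
  hits[o[1], , drop = FALSE]
}

#' Alien Index of one query
#'
#' AI contrasts the strongest Ingroup and Donor hits on the e-value scale:
#' `AI = ln(bestE_ingroup + epsilon) - ln(bestE_donor + epsilon)`, where
#' "best" is the minimum e-value (ties: highest bitscore, then input order).
#' A side with no hits enters with e-value 1, so a query with only Donor
#' homology gets a large positive AI. Positive AI means the query is more
#' similar to a distant taxon and is a potential HGT.
#'
#' @param hits Data frame of the query's hits (`evalue`, `bitscore`).
#' @param affiliations Character vector, one affiliation per hit row;
#'   `EXCLUDED`/`QUERY`/`UNKNOWN` hits are ignored.
#' @param epsilon Pseudo-e-value guarding `log(0)`; default `1e-200`.
#' @return AI, or `NA_real_` when the query has no Donor and no Ingroup hits
#'   (flagged undefined; such rows never pass candidate selection).
#' @export
alien_index <- function(hits, affiliations, epsilon = 1e-200) {
  don <- hits[affiliations == "DONOR", , drop = FALSE]
  ing <- hits[affiliations == "INGROUP", , drop = FALSE]
  if (!nrow(don) && !nrow(ing)) return(NA_real_)
  e_in <- if (nrow(ing)) .best_hit(ing)$evalue else 1
  e_don <- if (nrow(don)) .best_hit(don)$evalue else 1
  log(e_in + epsilon) - log(e_don + epsilon)
}

#' HGT index (h) of one query
#'
#' Bitscore counterpart of the Alien Index:
#' `h = best_donor_bitscore - best_ingroup_bitscore`, a side with no hits
#' contributing 0. Unlike AI it cannot saturate when both e-values underflow
#' to zero.
#'
#' @inheritParams alien_index
#' @return h (0 when neither side has hits).
#' @export
hgt_index <- function(hits, affiliations) {
  don <- hits[affiliations == "DONOR", , drop = FALSE]
  ing <- hits[affiliations == "INGROUP", , drop = FALSE]
  b_don <- if (nrow(don)) .best_hit(don)$bitscore else 0
  b_ing <- if (nrow(ing)) .best_hit(ing)$bitscore else 0
  b_don - b_ing
}

#' Percentage of distinct Donor species among the top hits
#'
#' Ranks the query's hits by descending bitscore after dropping
#' `EXCLUDED`/`QUERY` hits, takes the top `top_n`, and reports
#' `100 * (distinct Donor species) / denominator`, the denominator being
#' `top_n` or the actual hit count when fewer exist. Species are
#' distinguished by `subject_species` name when available, else by taxid, so
#' ten HSPs from one bacterium count once.
#'
#' @inheritParams alien_index
#' @param top_n Number of top hits to inspect (default 10).
#' @return Percentage in [0, 100]; 0 when the query has no usable hits.
#' @export
outg_pct <- function(hits, affiliations, top_n = 10) {
  stopifnot(top_n >= 1)
  keep <- !(affiliations %in% c("EXCLUDED", "QUERY"))
  hits <- hits[keep, , drop = FALSE]
  aff <- affiliations[keep]
  if (!nrow(hits)) return(0)
  o <- order(-hits$bitscore, hits$evalue, seq_len(nrow(hits)))
  o <- o[seq_len(min(top_n, length(o)))]
  top <- hits[o, , drop = FALSE]
  top_aff <- aff[o]
  sp <- ifelse(!is.na(top$subject_species) & nzchar(top$subject_species),
               top$subject_species, paste0("taxid:", top$subject_taxid))
  denom <- min(top_n, nrow(top))
  100 * length(unique(sp[top_aff == "DONOR"])) / denom
}

#' Exponentially down-weighted (normalized) bitscore
#'
#' Down-weights a hit's bitscore by its distance from the query's highest
#' bitscore `HBitscore`:
#' `BitscoreN = Bitscore * exp(-10 * (HBitscore - Bitscore) / Bitscore)`,
#' so the top hit keeps its full score and weaker hits decay rapidly. With
#' `alt_denominator = TRUE` the exponent divides by `HBitscore` instead (a
#' gentler decay), provided for sensitivity analysis.
#'
#' @param bitscore Positive bitscore(s); vectorised.
#' @param hbitscore The query's highest bitscore; must be >= every
#'   `bitscore`.
#' @param alt_denominator Use `HBitscore` as the exponent denominator.
#' @return Normalized bitscore(s), in (0, bitscore], equal to `bitscore`
#'   exactly when `bitscore == hbitscore`.
#' @export
normalized_bitscore <- function(bitscore, hbitscore, alt_denominator = FALSE) {
  if (any(bitscore <= 0)) stop("bitscore must be positive")
  if (any(bitscore > hbitscore)) stop("bitscore exceeds hbitscore")
  denom <- if (alt_denominator) hbitscore else bitscore
  bitscore * exp(-10 * (hbitscore - bitscore) / denom)
}

#' Aggregate Hit Support (AHS) of one query
#'
#' Contamination-aware screening metric: sum of normalized bitscores over all
#' Donor hits minus the sum over all Ingroup hits, with `HBitscore` taken
#' over the union of both sides. Because every homolog contributes (instead
#' of only the single best hit on each side), one taxonomically mislabelled
#' top hit cannot flip the call. Positive AHS suggests a potential HGT
#' candidate.
#'
#' @inheritParams alien_index
#' @param alt_denominator Passed to [normalized_bitscore()].
#' @return AHS; 0 when the query has no Donor and no Ingroup hits.
#' @export
ahs <- function(hits, affiliations, alt_denominator = FALSE) {
  don <- hits$bitscore[affiliations == "DONOR"]
  ing <- hits$bitscore[affiliations == "INGROUP"]
  if (!length(don) && !length(ing)) return(0)
  hbit <- max(c(don, ing))
  s <- function(b) if (length(b))
    sum(normalized_bitscore(b, hbit, alt_denominator)) else 0
  s(don) - s(ing)
}

#' Per-query screening metrics table
#'
#' Computes AI, h, outg_pct, AHS and best-hit bookkeeping for every query in
#' a hit table. Hits affiliated `EXCLUDED` or `QUERY` never contribute;
#' `UNKNOWN` hits are ignored by AI/h/AHS but remain in the outg_pct top-hit
#' denominator.
#'
#' @param table A `hit_table`.
#' @param spec An [ingroup_spec()].
#' @param tax A `taxonomy_db`.
#' @param epsilon Pseudo-e-value for AI.
#' @param top_n Top-hit window for outg_pct.
#' @param alt_denominator Passed to [normalized_bitscore()].
#' @return Data frame, one row per query: `query_id`, `n_hits`,
#'   `n_hits_used`, `AI`, `h`, `outg_pct`, `AHS`, `HBitscore`,
#'   `best_ingroup_id`, `best_ingroup_evalue`, `best_ingroup_bitscore`,
#'   `best_donor_id`, `best_donor_evalue`, `best_donor_bitscore`, `flag`
#'   (`"ok"`, `"no_ingroup"`, `"no_donor"`, or `"undefined"` when the query
#'   has no Donor and no Ingroup hits at all).
#' @export
compute_metrics <- function(table, spec, tax, epsilon = 1e-200, top_n = 10,
                            alt_denominator = FALSE) {
  per_query <- by_query(table)
  rows <- lapply(names(per_query), function(q) {
    hits <- per_query[[q]]
    aff <- affiliate(hits$subject_taxid, spec, tax)
    don <- hits[aff == "DONOR", , drop = FALSE]
    ing <- hits[aff == "INGROUP", , drop = FALSE]
    bd <- .best_hit(don)
    bi <- .best_hit(ing)
    usable <- nrow(don) + nrow(ing)
    flag <- if (usable == 0) "undefined"
      else if (!nrow(ing)) "no_ingroup"
      else if (!nrow(don)) "no_donor"
      else "ok"
    data.frame(
      query_id = q,
      n_hits = nrow(hits),
      n_hits_used = usable,
      AI = alien_index(hits, aff, epsilon),
      h = hgt_index(hits, aff),
      outg_pct = outg_pct(hits, aff, top_n),
      AHS = ahs(hits, aff, alt_denominator),
      HBitscore = if (usable) max(c(don$bitscore, ing$bitscore)) else NA_real_,
      best_ingroup_id = if (is.null(bi)) NA_character_ else bi$subject_id,
      best_ingroup_evalue = if (is.null(bi)) NA_real_ else bi$evalue,
      best_ingroup_bitscore = if (is.null(bi)) NA_real_ else bi$bitscore,
      best_donor_id = if (is.null(bd)) NA_character_ else bd$subject_id,
      best_donor_evalue = if (is.null(bd)) NA_real_ else bd$evalue,
      best_donor_bitscore = if (is.null(bd)) NA_real_ else bd$bitscore,
      flag = flag,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Select candidate queries by a metric predicate
#'
#' Evaluates a boolean expression over the metric columns (`AI`, `h`,
#' `outg_pct`, `AHS`) of a metrics table and returns the query ids that
#' satisfy it. Rows with undefined (NA) values in the expression are never
#' selected. The default reproduces the permissive initial filter
#' `AI > 0 | AHS > 0`.
#'
#' @param rows Metrics data frame from [compute_metrics()].
#' @param predicate Unquoted boolean expression over metric columns, or a
#'   one-sided formula (e.g. `~ AI > 30`), or a string.
#' @return Character vector of selected query ids (metrics-table order).
#' @export
select_candidates <- function(rows, predicate = AI > 0 | AHS > 0) {
  expr <- substitute(predicate)
  if (!missing(predicate)) {
    # a string or one-sided formula (possibly held in a variable) also works
    maybe <- tryCatch(eval(expr, parent.frame()), error = function(e) NULL)
    if (is.character(maybe)) {
      expr <- str2lang(maybe)
    } else if (inherits(maybe, "formula")) {
      expr <- maybe[[2]]
    }
  }
  if (is.call(expr) && identical(expr[[1]], as.name("~"))) expr <- expr[[2]]
  keep <- eval(expr, rows, parent.frame())
  keep[is.na(keep)] <- FALSE
  rows$query_id[keep]
}

#' F1 scan over Alien Index thresholds
#'
#' For each threshold N, counts the queries with `AI > N` and the
#' phylogenetically confirmed HGTs among them, and computes
#' `F1(N) = 2 * HGT_{AI>N} / (HGT_{AI>0} + Genes_{AI>N})` together with
#' sensitivity and precision. Used to pick a data-driven AI cutoff trading
#' precision against sensitivity once a first round of tree-based
#' confirmation is available.
#'
#' @param rows Metrics data frame from [compute_metrics()].
#' @param confirmed Character vector of query ids confirmed as HGT by tree
#'   classification; must all have `AI > 0`.
#' @param n_grid Numeric thresholds to scan (default `0:40`).
#' @return Data frame with columns `N`, `genes_above`, `hgt_above`,
#'   `hgt_total`, `sensitivity`, `precision`, `F1`; attribute `best_N` holds
#'   the argmax-F1 threshold (smallest N on ties; NA when `hgt_total` is 0).
#' @export
f1_threshold_scan <- function(rows, confirmed, n_grid = 0:40) {
  ai <- rows$AI[match(confirmed, rows$query_id)]
  if (any(is.na(ai)) || any(ai <= 0)) {
    stop("all confirmed HGTs must be queries with AI > 0")
  }
  hgt_total <- length(confirmed)
  is_conf <- rows$query_id %in% confirmed
  scan <- lapply(sort(unique(n_grid)), function(N) {
    above <- !is.na(rows$AI) & rows$AI > N
    genes_above <- sum(above)
    hgt_above <- sum(above & is_conf)
    data.frame(
      N = N, genes_above = genes_above, hgt_above = hgt_above,
      hgt_total = hgt_total,
      sensitivity = if (hgt_total) hgt_above / hgt_total else 0,
      precision = if (genes_above) hgt_above / genes_above else NA_real_,
      F1 = if (hgt_total + genes_above)
        2 * hgt_above / (hgt_total + genes_above) else 0
    )
  })
  out <- do.call(rbind, scan)
  rownames(out) <- NULL
  attr(out, "best_N") <- if (hgt_total == 0) NA_real_
    else out$N[which.max(out$F1)]
  out
}
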