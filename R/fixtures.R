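#' Generate a synthetic two-clade taxonomy
#'
#' Builds an NCBI-style dump with two disjoint lineage families under a
#' shared root: an ingroup clade (root -> Eukaryota -> Metazoa -> species)
#' holding the query species and `n_ingroup_taxa` relatives, and a donor
#' clade (root -> Bacteria -> species) with `n_donor_taxa` species. The
#' matching analysis spec sets Ingroup = Metazoa. Deterministic per seed.
#'
#' @param n_ingroup_taxa,n_donor_taxa Leaf species per clade.
#' @param seed Integer seed.
#' @return List: `tax` (`taxonomy_db`), `spec` ([ingroup_spec()]),
#'   `ingroup_taxids`, `donor_taxids`, `query_taxid`, `nodes`, `names`
#'   (the dump tables).
#' @export
make_taxonomy <- function(n_ingroup_taxa, n_donor_taxa, seed = 1) {
  set.seed(seed)
  ingroup_taxids <- if (n_ingroup_taxa) 1000L + seq_len(n_ingroup_taxa) else integer(0)
  donor_taxids <- if (n_donor_taxa) 2000L + seq_len(n_donor_taxa) else integer(0)
  query_taxid <- 999L
  nodes <- rbind(
    data.frame(taxid = 1L, parent = 1L, rank = "no rank"),
    data.frame(taxid = 2759L, parent = 1L, rank = "superkingdom"),
    data.frame(taxid = 33208L, parent = 2759L, rank = "kingdom"),
    data.frame(taxid = 2L, parent = 1L, rank = "superkingdom"),
    data.frame(taxid = query_taxid, parent = 33208L, rank = "species"),
    if (length(ingroup_taxids))
      data.frame(taxid = ingroup_taxids, parent = 33208L, rank = "species"),
    if (length(donor_taxids))
      data.frame(taxid = donor_taxids, parent = 2L, rank = "species")
  )
  names_df <- rbind(
    data.frame(taxid = 1L, name = "cellular organisms"),
    data.frame(taxid = 2759L, name = "Eukaryota"),
    data.frame(taxid = 33208L, name = "Metazoa"),
    data.frame(taxid = 2L, name = "Bacteria"),
    data.frame(taxid = query_taxid, name = "Query species"),
    if (length(ingroup_taxids))
      data.frame(taxid = ingroup_taxids,
                 name = sprintf("Metazoa_sp%d", seq_along(ingroup_taxids))),
    if (length(donor_taxids))
      data.frame(taxid = donor_taxids,
                 name = sprintf("Bacteria_sp%d", seq_along(donor_taxids)))
  )
  tax <- taxonomy_from_dump(nodes, names_df)
  list(tax = tax,
       spec = ingroup_spec("Metazoa", query_taxid),
       ingroup_taxids = ingroup_taxids, donor_taxids = donor_taxids,
       query_taxid = query_taxid, nodes = nodes, names = names_df)
}

#' Describe a planted-truth screening scenario
#'
#' @param seed Integer seed driving every random draw.
#' @param n_queries Number of query proteins.
#' @param fraction_hgt Fraction of queries planted as HGT (rounded to a
#'   count).
#' @param hits_per_side Donor and Ingroup hits per query.
#' @return A `planted_scenario` list; `truth` is filled by
#'   [make_hit_table()].
#' @export
planted_scenario <- function(seed = 1, n_queries = 20, fraction_hgt = 0.5,
                             hits_per_side = 8) {
  sc <- list(seed = as.integer(seed), n_queries = as.integer(n_queries),
             fraction_hgt = fraction_hgt,
             hits_per_side = as.integer(hits_per_side))
  class(sc) <- "planted_scenario"
  sc
}

#' @keywords internal
#' random protein-like sequence
.random_protein <- function(n = 120) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

#' Generate a hit table with planted HGT signal
#'
#' Planted-HGT queries receive Donor hits that are both closer on the
#' e-value scale and higher-scoring than their Ingroup hits (log10 e-values
#' uniform in [-180, -100] vs [-50, -5], bitscores linear in -log10 e with
#' seeded jitter); native queries get the mirror image. The separation is
#' wide enough that AI, h and AHS all recover the planted class, and the
#' e-value floor keeps AI far from the epsilon = 1e-200 saturation region.
#' Each query draws its own disjoint subject set, so shared-hit grouping
#' yields singletons.
#'
#' @param scenario A [planted_scenario()].
#' @param taxonomy Output of [make_taxonomy()]; a default 10+10-species one
#'   (same seed) is built when omitted.
#' @return List: `table` (`hit_table`), `truth` (named vector query ->
#'   `"HGT"`/`"NATIVE"`), `taxonomy`, `query_seqs`, `db_seqs` (named
#'   character vectors of synthetic protein sequences).
#' @export
make_hit_table <- function(scenario, taxonomy = NULL) {
  set.seed(scenario$seed)
  if (is.null(taxonomy)) {
    taxonomy <- make_taxonomy(10, 10, seed = scenario$seed)
  }
  n <- scenario$n_queries
  k <- scenario$hits_per_side
  n_hgt <- round(scenario$fraction_hgt * n)
  is_hgt <- rep(c(TRUE, FALSE), c(n_hgt, n - n_hgt))
  queries <- sprintf("q%03d", seq_len(n))
  truth <- stats::setNames(ifelse(is_hgt, "HGT", "NATIVE"), queries)

  strong_log10e <- function(m) stats::runif(m, -180, -100)
  weak_log10e <- function(m) stats::runif(m, -50, -5)
  bits <- function(log10e) round(50 + 2 * (-log10e) + stats::runif(length(log10e), -2, 2), 1)

  rows <- list()
  db_seqs <- character(0)
  for (qi in seq_len(n)) {
    don_e <- if (is_hgt[qi]) strong_log10e(k) else weak_log10e(k)
    ing_e <- if (is_hgt[qi]) weak_log10e(k) else strong_log10e(k)
    don_tax <- sample(taxonomy$donor_taxids, k, replace = TRUE)
    ing_tax <- sample(taxonomy$ingroup_taxids, k, replace = TRUE)
    subj <- sprintf("%s_s%02d", queries[qi], seq_len(2 * k))
    log10e <- c(don_e, ing_e)
    taxid <- c(don_tax, ing_tax)
    df <- data.frame(
      query_id = queries[qi], subject_id = subj,
      percent_identity = round(stats::runif(2 * k, 30, 95), 1),
      align_length = sample(80:300, 2 * k, replace = TRUE),
      evalue = 10^log10e, bitscore = bits(log10e),
      subject_taxid = taxid,
      subject_species = vapply(taxid, function(t) {
        l <- lineage_names(taxonomy$tax, t); l[length(l)]
      }, ""),
      stringsAsFactors = FALSE
    )
    df <- df[order(df$evalue), , drop = FALSE]  # best hits first, like BLAST
    rows[[qi]] <- df
    db_seqs <- c(db_seqs,
                 stats::setNames(vapply(subj, function(s) .random_protein(), ""),
                                 subj))
  }
  table <- as_hit_table(do.call(rbind, rows))
  query_seqs <- stats::setNames(
    vapply(queries, function(q) .random_protein(), ""), queries)
  list(table = table, truth = truth, taxonomy = taxonomy,
       query_seqs = query_seqs, db_seqs = db_seqs)
}

#' Generate a gene tree with a planted decision-matrix cell
#'
#' Emits a newick tree whose midpoint rooting and sister-branch search
#' recover the requested (ancestral sister branch, sister branch) tag pair.
#' Topology: `(((query, SB), ASB), out)` with a distant outgroup leaf on a
#' long branch so the midpoint falls on the outgroup edge; for the
#' `NOT_PRESENT` row the query sits on the long branch itself
#' (`(query, SB)`), leaving no ancestral sister. Leaf affiliations realising
#' each tag are drawn from the taxonomy at the 0.8 majority threshold;
#' `noise` injects a minority-affiliation fraction into pure `DONOR` /
#' `INGROUP` branches (kept below the `BOTH` boundary).
#'
#' @param table1_cell Character pair `c(asb_tag, sb_tag)`; asb in
#'   `DONOR`/`INGROUP`/`BOTH`/`NOT_PRESENT`, sb in `DONOR`/`INGROUP`/`BOTH`.
#' @param n_sb_leaves,n_asb_leaves Leaves per branch (>= 5 recommended so
#'   the BOTH mixtures are realisable).
#' @param noise Minority fraction in [0, 0.2) for pure tags.
#' @param seed Integer seed (branch lengths, supports, taxon draws).
#' @param taxonomy Output of [make_taxonomy()] (default built from seed).
#' @return List: `newick`, `expected_verdict`, `query_id`, `cell`,
#'   `taxonomy`.
#' @export
make_planted_tree <- function(table1_cell, n_sb_leaves = 5, n_asb_leaves = 5,
                              noise = 0, seed = 1, taxonomy = NULL) {
  asb_tag <- match.arg(table1_cell[1],
                       c("DONOR", "INGROUP", "BOTH", "NOT_PRESENT"))
  sb_tag <- match.arg(table1_cell[2], c("DONOR", "INGROUP", "BOTH"))
  set.seed(seed)
  if (is.null(taxonomy)) taxonomy <- make_taxonomy(10, 10, seed = seed)

  leaf <- function(tag_side, j) {
    taxid <- if (tag_side == "DONOR") {
      sample(taxonomy$donor_taxids, 1)
    } else {
      sample(taxonomy$ingroup_taxids, 1)
    }
    sprintf("%s%d|%d", tolower(substr(tag_side, 1, 1)), j, taxid)
  }
  branch_leaves <- function(tag, n, offset = 0) {
    sides <- switch(tag,
      DONOR = {
        n_min <- min(floor(noise * n), floor((1 - 0.8) * n))
        c(rep("INGROUP", n_min), rep("DONOR", n - n_min))
      },
      INGROUP = {
        n_min <- min(floor(noise * n), floor((1 - 0.8) * n))
        c(rep("DONOR", n_min), rep("INGROUP", n - n_min))
      },
      BOTH = {
        n_don <- max(1, min(n - 1, round(0.6 * n)))
        c(rep("DONOR", n_don), rep("INGROUP", n - n_don))
      })
    vapply(seq_len(n), function(j) leaf(sides[j], offset + j), "")
  }
  blen <- function() sprintf("%.3f", stats::runif(1, 0.05, 0.4))
  sup <- function() sprintf("%.2f", stats::runif(1, 0.85, 0.99))
  clade <- function(leaves) {
    # ladderised clade with random lengths and supports
    s <- sprintf("%s:%s", leaves[1], blen())
    for (l in leaves[-1]) {
      s <- sprintf("(%s,%s:%s)%s:%s", s, l, blen(), sup(), blen())
    }
    s
  }
  query_id <- "QUERY_g1"
  sb <- clade(branch_leaves(sb_tag, n_sb_leaves))
  if (asb_tag == "NOT_PRESENT") {
    newick <- sprintf("(%s:10.0,(%s)%s:%s);", query_id, sb, sup(), blen())
  } else {
    asb <- clade(branch_leaves(asb_tag, n_asb_leaves, offset = 100))
    out_leaf <- sprintf("out1|%d", sample(taxonomy$donor_taxids, 1))
    newick <- sprintf("(((%s:%s,(%s)%s:%s)%s:%s,(%s)%s:%s)%s:%s,%s:10.0);",
                      query_id, blen(), sb, sup(), blen(), sup(), blen(),
                      asb, sup(), blen(), sup(), blen(), out_leaf)
  }
  expected <- as.character(classify_topology(asb_tag, sb_tag))
  list(newick = newick, expected_verdict = expected, query_id = query_id,
       cell = c(asb = asb_tag, sb = sb_tag), taxonomy = taxonomy)
}

#' Generate an annotated toy genome with planted contamination
#'
#' Writes GFF3-style gene loci over `n_scaffolds` native scaffolds (genes of
#' status `NO`), plants `isolated_insertions` single HGT-status genes among
#' them (genuine-looking HGT insertions), and adds `contaminant_blocks`
#' extra scaffolds consisting entirely of HGT-status genes — the classic
#' signature of a contaminant contig in an assembly. Deterministic per seed
#' (byte-identical GFF3 text).
#'
#' @param n_scaffolds Native scaffolds.
#' @param genes_per_scaffold Genes on each native scaffold.
#' @param contaminant_blocks Number of contaminant scaffolds.
#' @param isolated_insertions Number of isolated HGT genes planted on native
#'   scaffolds.
#' @param seed Integer seed.
#' @param block_size Genes per contaminant scaffold.
#' @return List: `gff_lines` (character, GFF3), `loci` (parsed/sorted data
#'   frame), `statuses` (named vector), `truth` (list with `block_genes`,
#'   `isolated_genes`).
#' @export
make_annotated_genome <- function(n_scaffolds = 2, genes_per_scaffold = 30,
                                  contaminant_blocks = 1,
                                  isolated_insertions = 2, seed = 1,
                                  block_size = 6) {
  set.seed(seed)
  gff <- c("##gff-version 3")
  statuses <- character(0)
  gene_rows <- list()
  gid <- 0
  add_gene <- function(seqid, start, end, status) {
    gid <<- gid + 1
    id <- sprintf("g%04d", gid)
    strand <- sample(c("+", "-"), 1)
    gff <<- c(gff, sprintf("%s\tsynth\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                           seqid, start, end, strand, id))
    statuses[id] <<- status
    id
  }
  isolated <- character(0)
  # isolated insertions spread over native scaffolds, away from ends
  slots <- expand.grid(sc = seq_len(n_scaffolds),
                       g = seq(5, genes_per_scaffold - 4))
  picks <- slots[sample(nrow(slots), isolated_insertions), , drop = FALSE]
  for (sc in seq_len(n_scaffolds)) {
    pos <- 1
    for (g in seq_len(genes_per_scaffold)) {
      len <- sample(500:2000, 1)
      status <- if (any(picks$sc == sc & picks$g == g)) "HGT" else "NO"
      id <- add_gene(sprintf("scaffold_%d", sc), pos, pos + len, status)
      if (status == "HGT") isolated <- c(isolated, id)
      pos <- pos + len + sample(200:800, 1)
    }
  }
  block_genes <- character(0)
  for (b in seq_len(contaminant_blocks)) {
    pos <- 1
    for (g in seq_len(block_size)) {
      len <- sample(500:2000, 1)
      id <- add_gene(sprintf("contam_%d", b), pos, pos + len, "HGT")
      block_genes <- c(block_genes, id)
      pos <- pos + len + sample(200:800, 1)
    }
  }
  tmp <- tempfile(fileext = ".gff3")
  writeLines(gff, tmp)
  loci <- parse_gff3_genes(tmp)
  unlink(tmp)
  list(gff_lines = gff, loci = loci, statuses = statuses,
       truth = list(block_genes = block_genes, isolated_genes = isolated))
}

#' Write a complete ready-to-run synthetic workspace
#'
#' Materialises a planted scenario as the files the pipeline reads: query
#' FASTA, database FASTA, tabular hit table, taxonomy dump TSVs, GFF3 and a
#' YAML run config. Round-trips losslessly through the package's own
#' readers.
#'
#' @param dir Output directory (created).
#' @param scenario A [planted_scenario()].
#' @param genome Optionally, output of [make_annotated_genome()].
#' @return Invisibly, a list of the generated objects plus `paths` and the
#'   config path.
#' @export
make_workspace <- function(dir, scenario = planted_scenario(),
                           genome = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ht <- make_hit_table(scenario)
  paths <- list(
    query_fasta = file.path(dir, "queries.fasta"),
    db_fasta = file.path(dir, "database.fasta"),
    hit_table = file.path(dir, "hits.tsv"),
    nodes = file.path(dir, "taxonomy.nodes.tsv"),
    names = file.path(dir, "taxonomy.names.tsv"),
    gff = if (!is.null(genome)) file.path(dir, "genes.gff3") else NULL,
    config = file.path(dir, "config.yaml")
  )
  write_fasta(ht$query_seqs, paths$query_fasta)
  write_fasta(ht$db_seqs, paths$db_fasta)
  tab <- as.data.frame(ht$table)
  tab$evalue <- format(tab$evalue, digits = 6, scientific = TRUE)
  utils::write.table(
    tab[, c("query_id", "subject_id", "percent_identity", "align_length",
            "evalue", "bitscore", "subject_taxid", "subject_species")],
    paths$hit_table, sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  tx <- ht$taxonomy
  utils::write.table(tx$nodes, paths$nodes, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(tx$names, paths$names, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(genome)) writeLines(genome$gff_lines, paths$gff)
  cfg <- list(
    paths = list(query_fasta = paths$query_fasta, db_fasta = paths$db_fasta,
                 hit_table = paths$hit_table, taxonomy_nodes = paths$nodes,
                 taxonomy_names = paths$names, gff = paths$gff,
                 out_dir = file.path(dir, "run")),
    hit_columns = c("qseqid", "sseqid", "pident", "length", "evalue",
                    "bitscore", "staxids", "ssciname"),
    ingroup = "Metazoa", exclude = list(), query_taxid = tx$query_taxid,
    thresholds = list(candidate_predicate = "AI > 0 | AHS > 0",
                      shared_hit = 0.7, tag_majority = 0.8,
                      branch_support = 0, evaluate_alpha = 0.05,
                      local_score_window = 10)
  )
  yaml::write_yaml(cfg, paths$config)
  invisible(c(ht, list(genome = genome, paths = paths, scenario = scenario)))
}

#' Mock tree builder reproducing the planted truth
#'
#' Returns a function with the signature the pipeline expects of a tree
#' builder (`function(group_fasta, group)` -> `phylo`) that, instead of
#' aligning and inferring, emits a tree nesting each group's query inside
#' its Donor hits (planted HGT) or its Ingroup hits (planted native),
#' according to the scenario truth. Used to exercise the pipeline end to end
#' without external tools.
#'
#' @param truth Named vector query -> `"HGT"`/`"NATIVE"` (from
#'   [make_hit_table()]).
#' @return `function(group_fasta, group)` returning an `ape::phylo`.
#' @export
planted_tree_builder <- function(truth) {
  function(group_fasta, group) {
    ids <- names(read_fasta(group_fasta))
    q <- intersect(group$query_ids, ids)[1]
    hits <- setdiff(ids, group$query_ids)
    # leaves carry subject|taxid headers; split by affiliation clade family
    taxid <- as.integer(sub("^.*\\|", "", hits))
    donor <- hits[taxid >= 2000]
    ingroup <- hits[taxid < 2000]
    planted_hgt <- identical(unname(truth[q]), "HGT")
    near <- if (planted_hgt) donor else ingroup
    far <- setdiff(hits, near)
    stopifnot(length(near) >= 4, length(far) >= 1)
    clade <- function(leaves) {
      Reduce(function(a, b) sprintf("(%s,%s:0.2)0.95:0.2", a, b),
             sprintf("%s:0.2", leaves[-1]),
             init = sprintf("%s:0.2", leaves[1]))
    }
    # query nests inside the near side: sister = 2 near hits, ancestral
    # sister = the remaining near hits; the far side hangs on a long branch
    sb <- clade(near[1:2])
    asb <- clade(near[-(1:2)])
    newick <- sprintf("(((%s:0.1,(%s)0.99:0.1)0.99:0.2,(%s)0.99:0.2)0.99:0.3,(%s)0.99:8.0);",
                      q, sb, asb, clade(far))
    ape::read.tree(text = newick)
  }
}
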