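# Shared synthetic fixtures and independent oracles.

# one taxonomy bundle reused across tests (10 ingroup + 10 donor species)
tax10 <- make_taxonomy(10, 10, seed = 1)

# write a tiny hit-table file; rows = list of tab-joined character vectors
write_hit_file <- function(rows) {
  path <- tempfile(fileext = ".tsv")
  writeLines(vapply(rows, paste, "", collapse = "\t"), path)
  path
}

# outfmt "6 std staxids"-shaped row with given key fields
std_row <- function(q, s, evalue, bitscore, taxid) {
  c(q, s, "90.0", "100", "5", "0", "1", "100", "1", "100",
    format(evalue, scientific = TRUE), format(bitscore), as.character(taxid))
}

# independent leaf-to-leaf path lengths: shortest paths on the edge graph
brute_leaf_dists <- function(tree) {
  g <- igraph::graph_from_edgelist(apply(tree$edge, 2, as.character),
                                   directed = FALSE)
  igraph::E(g)$weight <- tree$edge.length
  d <- igraph::distances(g)
  tips <- as.character(seq_along(tree$tip.label))
  d[tips, tips, drop = FALSE]
}

# independent single-linkage oracle: union-find over pairwise fractions
brute_group_oracle <- function(candidates, hit_sets, threshold) {
  parent <- stats::setNames(candidates, candidates)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  n <- length(candidates)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      a <- unique(hit_sets[[candidates[i]]])
      b <- unique(hit_sets[[candidates[j]]])
      f <- if (!length(a) || !length(b)) 0 else
        length(intersect(a, b)) / min(length(a), length(b))
      if (f >= threshold) parent[[find(candidates[i])]] <- find(candidates[j])
    }
  }
  roots <- vapply(candidates, find, "")
  unname(lapply(split(candidates, roots), sort))
}

# mock executable on PATH recording its argv and copying input to output
local_mock_tool <- function(name, body, env = parent.frame()) {
  dir <- withr::local_tempdir(.local_envir = env)
  exe <- file.path(dir, name)
  writeLines(c("#!/bin/sh", body), exe)
  Sys.chmod(exe, "0755")
  withr::local_path(dir, .local_envir = env)
  exe
}

# root-side depth balance of a rooted tree: max root-to-leaf distance on each
# side of the root
root_side_depths <- function(tree) {
  ntip <- length(tree$tip.label)
  root <- unique(tree$edge[!(tree$edge[, 1] %in% tree$edge[, 2]), 1])[1]
  d <- ape::dist.nodes(tree)
  kids <- tree$edge[tree$edge[, 1] == root, 2]
  vapply(kids, function(k) {
    tips <- if (k <= ntip) k else
      intersect(which(d[k, seq_len(ntip)] < d[root, seq_len(ntip)]),
                seq_len(ntip))
    max(d[root, tips]) }, 0)
}

all_table1_cells <- expand.grid(
  asb = c("DONOR", "INGROUP", "BOTH", "NOT_PRESENT"),
  sb = c("DONOR", "INGROUP", "BOTH"),
  stringsAsFactors = FALSE)

# printed decision matrix, cell for cell
table1_expected <- function(asb, sb) {
  key <- paste(asb, sb)
  switch(key,
    "DONOR DONOR" = "HGT", "DONOR INGROUP" = "NO", "DONOR BOTH" = "COMPLEX",
    "INGROUP DONOR" = "COMPLEX", "INGROUP INGROUP" = "NO",
    "INGROUP BOTH" = "NO",
    "BOTH DONOR" = "COMPLEX", "BOTH INGROUP" = "NO", "BOTH BOTH" = "COMPLEX",
    "NOT_PRESENT DONOR" = "HGT", "NOT_PRESENT INGROUP" = "NO",
    "NOT_PRESENT BOTH" = "COMPLEX")
}
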