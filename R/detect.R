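#' Affiliation of gene-tree leaves
#'
#' Tree leaves produced by the pipeline are either query-species sequences
#' (their plain sequence id) or database hits labelled `subject_id|taxid`.
#' Labels carrying a taxid are affiliated through [affiliate()]; bare labels
#' are treated as query-species sequences (`QUERY`).
#'
#' @param labels Character vector of leaf labels.
#' @param spec An [ingroup_spec()].
#' @param tax A `taxonomy_db`.
#' @return Named character vector label -> affiliation.
#' @export
leaf_affiliations <- function(labels, spec, tax) {
  aff <- vapply(labels, function(lab) {
    parts <- strsplit(lab, "|", fixed = TRUE)[[1]]
    if (length(parts) >= 2) {
      taxid <- suppressWarnings(as.integer(parts[length(parts)]))
      if (is.na(taxid)) return("UNKNOWN")
      affiliate(taxid, spec, tax)
    } else {
      "QUERY"
    }
  }, "")
  stats::setNames(aff, labels)
}

#' Tag a branch by its leaf affiliations
#'
#' A branch (a set of leaves) is tagged `DONOR` or `INGROUP` when that side
#' holds at least `majority_threshold` (default 80%) of its informative
#' leaves, `BOTH` when the minority side exceeds the threshold's complement,
#' and `EMPTY` when no informative leaf remains. `QUERY`, `EXCLUDED` and
#' `UNKNOWN` leaves are not informative and are dropped before counting.
#'
#' @param leaf_affiliations Character vector of affiliations (a multiset).
#' @param majority_threshold Fraction in (0.5, 1] required for a pure tag.
#' @return One of `"DONOR"`, `"INGROUP"`, `"BOTH"`, `"EMPTY"`.
#' @export
tag_branch <- function(leaf_affiliations, majority_threshold = 0.8) {
  d <- sum(leaf_affiliations == "DONOR")
  i <- sum(leaf_affiliations == "INGROUP")
  n <- d + i
  if (n == 0) return("EMPTY")
  if (d / n >= majority_threshold) return("DONOR")
  if (i / n >= majority_threshold) return("INGROUP")
  "BOTH"
}

#' @keywords internal
#' children / parent / tips-under helpers on the edge matrix
.children <- function(tree, node) tree$edge[tree$edge[, 1] == node, 2]
.parent <- function(tree, node) {
  p <- tree$edge[tree$edge[, 2] == node, 1]
  if (length(p)) p else NA_integer_
}
.tips_under <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  out <- character(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[1]; stack <- stack[-1]
    ch <- .children(tree, nd)
    out <- c(out, tree$tip.label[ch[ch <= ntip]])
    stack <- c(stack, ch[ch > ntip])
  }
  out
}

#' Sister branch and ancestral sister branch of a query leaf
#'
#' The sister branch (SB) is the sibling subtree of the query leaf; the
#' ancestral sister branch (ASB) is the sibling of the query leaf's parent.
#' In a polytomy, a node's sibling set is the union of all co-children.
#' When the sister branch consists solely of other query-species sequences
#' (paralogs), the query clade is enlarged to its parent and the search
#' ascends until a non-query leaf appears in the sister branch or the root
#' is reached. ASB is `NOT_PRESENT` when the query clade's parent is the
#' root.
#'
#' @param tree Rooted `ape::phylo`.
#' @param query_leaf Leaf label of the query sequence.
#' @param affiliations Named affiliation vector over all leaves (see
#'   [leaf_affiliations()]).
#' @return List with `sb_leaves` (character), `asb_leaves` (character or
#'   `NULL`), `asb_present` (logical), `query_clade_leaves`.
#' @export
find_sister_branches <- function(tree, query_leaf, affiliations) {
  ntip <- length(tree$tip.label)
  root <- unique(tree$edge[!(tree$edge[, 1] %in% tree$edge[, 2]), 1])[1]
  tip <- which(tree$tip.label == query_leaf)
  if (!length(tip)) stop("query leaf not found in tree: ", query_leaf)
  node <- tip[1]
  repeat {
    p <- .parent(tree, node)
    if (is.na(p)) stop("query leaf is the entire tree")
    sibs <- setdiff(.children(tree, p), node)
    sb_leaves <- unique(unlist(lapply(sibs, .tips_under, tree = tree)))
    all_query <- length(sb_leaves) > 0 &&
      all(affiliations[sb_leaves] == "QUERY")
    if (!all_query || p == root) break
    node <- p
  }
  if (p == root) {
    asb_leaves <- NULL
    asb_present <- FALSE
  } else {
    gp <- .parent(tree, p)
    uncles <- setdiff(.children(tree, gp), p)
    asb_leaves <- unique(unlist(lapply(uncles, .tips_under, tree = tree)))
    asb_present <- TRUE
  }
  list(sb_leaves = sb_leaves, asb_leaves = asb_leaves,
       asb_present = asb_present,
       query_clade_leaves = .tips_under(tree, node))
}

#' Decision matrix: verdict from the two branch tags
#'
#' Maps the (ancestral sister branch, sister branch) tag pair to the final
#' call: `HGT` (the query nests among Donor sequences), `NO` (it nests among
#' Ingroup sequences), or `COMPLEX` (mixed signal needing manual review).
#' A sister branch left `EMPTY` by exclusions yields `COMPLEX` with a flag;
#' an `EMPTY` ancestral sister branch carries no signal and is treated as
#' `NOT_PRESENT`.
#'
#' @param asb_tag `"DONOR"`, `"INGROUP"`, `"BOTH"`, `"EMPTY"` or
#'   `"NOT_PRESENT"`.
#' @param sb_tag `"DONOR"`, `"INGROUP"`, `"BOTH"` or `"EMPTY"`.
#' @return `"HGT"`, `"NO"` or `"COMPLEX"` (attribute `flag` set for the
#'   EMPTY sister-branch case).
#' @export
classify_topology <- function(asb_tag, sb_tag) {
  if (sb_tag == "EMPTY") {
    return(structure("COMPLEX", flag = "empty_sister_branch"))
  }
  if (asb_tag == "EMPTY") asb_tag <- "NOT_PRESENT"
  m <- matrix(c(
    # sb:  DONOR      INGROUP  BOTH
    "HGT",     "NO", "COMPLEX",   # asb DONOR
    "COMPLEX", "NO", "NO",        # asb INGROUP
    "COMPLEX", "NO", "COMPLEX",   # asb BOTH
    "HGT",     "NO", "COMPLEX"    # asb NOT_PRESENT
  ), nrow = 4, byrow = TRUE,
  dimnames = list(c("DONOR", "INGROUP", "BOTH", "NOT_PRESENT"),
                  c("DONOR", "INGROUP", "BOTH")))
  if (!asb_tag %in% rownames(m) || !sb_tag %in% colnames(m)) {
    stop("invalid tag pair: (", asb_tag, ", ", sb_tag, ")")
  }
  m[asb_tag, sb_tag]
}

#' Classify one query sequence on its gene tree
#'
#' Full per-query engine: midpoint-root the tree (unless `root = "none"`,
#' for user-supplied pre-rooted trees), collapse poorly supported branches,
#' locate the sister and ancestral sister branches of the query leaf, tag
#' both by their Donor/Ingroup content, and apply the decision matrix.
#'
#' @param tree `ape::phylo` or path to a newick file.
#' @param query_id Leaf label of the query sequence.
#' @param spec An [ingroup_spec()].
#' @param tax A `taxonomy_db`.
#' @param min_support Support threshold for [collapse_low_support()]
#'   (default 0: no collapsing).
#' @param majority_threshold Passed to [tag_branch()].
#' @param root `"midpoint"` (default) or `"none"`.
#' @return A `classification_result`: list with `query_id`, `verdict`
#'   (`"HGT"`/`"COMPLEX"`/`"NO"`), `sb_tag`, `asb_tag` (`"NOT_PRESENT"` when
#'   absent), `sb_leaves`, `asb_leaves`, `query_clade_leaves`, `flags`,
#'   `tree` (the processed tree), `affiliations`.
#' @export
detect_query <- function(tree, query_id, spec, tax, min_support = 0,
                         majority_threshold = 0.8,
                         root = c("midpoint", "none")) {
  root <- match.arg(root)
  if (is.character(tree)) tree <- ape::read.tree(tree)
  if (root == "midpoint") tree <- midpoint_root(tree)
  tree <- collapse_low_support(tree, min_support)
  aff <- leaf_affiliations(tree$tip.label, spec, tax)
  aff[query_id] <- "QUERY"
  sisters <- find_sister_branches(tree, query_id, aff)
  informative <- function(leaves) {
    a <- aff[leaves]
    a[!(a %in% c("QUERY", "EXCLUDED", "UNKNOWN"))]
  }
  sb_tag <- tag_branch(informative(sisters$sb_leaves), majority_threshold)
  asb_tag <- if (sisters$asb_present) {
    tag_branch(informative(sisters$asb_leaves), majority_threshold)
  } else "NOT_PRESENT"
  verdict <- classify_topology(asb_tag, sb_tag)
  flags <- attr(verdict, "flag")
  res <- list(query_id = query_id, verdict = as.character(verdict),
              sb_tag = sb_tag, asb_tag = asb_tag,
              sb_leaves = sisters$sb_leaves,
              asb_leaves = sisters$asb_leaves,
              query_clade_leaves = sisters$query_clade_leaves,
              flags = if (is.null(flags)) character(0) else flags,
              tree = tree, affiliations = aff)
  class(res) <- "classification_result"
  res
}

#' @export
print.classification_result <- function(x, ...) {
  glyph <- c(HGT = "\u2713", COMPLEX = "?", NO = "X")[x$verdict]
  cat(sprintf("%s  %s  (sb=%s, asb=%s)\n", x$query_id, glyph,
              x$sb_tag, x$asb_tag))
  invisible(x)
}

#' Default affiliation colour palette for NEXUS output
#'
#' @return Named character vector affiliation -> hex colour.
#' @export
default_palette <- function() {
  c(QUERY = "#ff0000", INGROUP = "#ff8c00", DONOR = "#228b22",
    EXCLUDED = "#8b4513", UNKNOWN = "#808080")
}

#' Write a FigTree-readable coloured NEXUS file
#'
#' Emits a taxa block in which each leaf label carries a colour annotation
#' keyed by its taxonomic affiliation, and a trees block with the processed
#' tree, for quick visual inspection in FigTree.
#'
#' @param tree Rooted `ape::phylo`.
#' @param affiliations Named affiliation vector over leaf labels.
#' @param path Output path.
#' @param palette Named colours per affiliation (see [default_palette()]).
#' @return `path` invisibly.
#' @export
write_nexus <- function(tree, affiliations, path, palette = default_palette()) {
  labs <- tree$tip.label
  cols <- palette[affiliations[labs]]
  cols[is.na(cols)] <- "#000000"
  lines <- c(
    "#NEXUS",
    "begin taxa;",
    sprintf("\tdimensions ntax=%d;", length(labs)),
    "\ttaxlabels",
    sprintf("\t'%s'[&!color=%s][&affiliation=%s]",
            labs, cols, affiliations[labs]),
    ";",
    "end;",
    "",
    "begin trees;",
    sprintf("\ttree tree_1 = [&R] %s", ape::write.tree(tree)),
    "end;"
  )
  writeLines(lines, path)
  invisible(path)
}
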