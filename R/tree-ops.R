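#' @keywords internal
#' leaf-to-leaf patristic distances of a phylo object
.leaf_dists <- function(tree) {
  d <- ape::dist.nodes(tree)
  n <- length(tree$tip.label)
  d[seq_len(n), seq_len(n), drop = FALSE]
}

#' Midpoint-root a gene tree
#'
#' Places the root at the midpoint of the longest leaf-to-leaf path (the tree
#' diameter). The input rooting is discarded (the tree is treated as
#' unrooted). Ties between equally long paths are broken deterministically by
#' the lexicographically smallest leaf-name pair. When the midpoint falls
#' exactly on an internal node the tree is rooted at that node.
#'
#' @param tree An `ape::phylo` with branch lengths.
#' @return Rooted `phylo`; the two diameter leaves end up on opposite sides
#'   of the root at equal path distance (up to numeric tolerance).
#' @export
midpoint_root <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  n <- length(tree$tip.label)
  if (n < 2) stop("tree must have at least 2 leaves")
  if (n == 2) {
    len <- sum(tree$edge.length)
    lab <- sort(tree$tip.label)
    out <- ape::read.tree(text = sprintf("(%s:%f,%s:%f);",
                                         lab[1], len / 2, lab[2], len / 2))
    return(out)
  }
  if (ape::is.rooted(tree)) tree <- ape::unroot(tree)
  d <- .leaf_dists(tree)
  diam <- max(d)
  # candidate diameter pairs; deterministic tie-break on sorted label pair
  idx <- which(d >= diam - 1e-12 * max(diam, 1), arr.ind = TRUE)
  idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
  pair_key <- apply(idx, 1, function(ij) {
    paste(sort(tree$tip.label[ij]), collapse = "\r")
  })
  best <- idx[order(pair_key)[1], ]
  a <- best[[1]]; b <- best[[2]]

  path <- ape::nodepath(tree, a, b)
  # walk from leaf a, find the edge containing the midpoint
  half <- d[a, b] / 2
  acc <- 0
  for (k in seq_len(length(path) - 1)) {
    e <- which(tree$edge[, 1] == path[k] & tree$edge[, 2] == path[k + 1] |
               tree$edge[, 1] == path[k + 1] & tree$edge[, 2] == path[k])
    len <- tree$edge.length[e]
    if (acc + len >= half - 1e-12) {
      from_k <- half - acc          # distance from path[k] into this edge
      parent <- tree$edge[e, 1]     # edge stored parent->child
      child <- tree$edge[e, 2]
      # phytools::reroot position is measured from the parent end of the edge
      pos <- if (child == path[k]) len - from_k else from_k
      tol <- 1e-12 * max(diam, 1)
      rooted <- if (pos <= tol) {
        ape::root(tree, node = parent, resolve.root = FALSE)
      } else if (pos >= len - tol) {
        ape::root(tree, node = child, resolve.root = FALSE)
      } else {
        phytools::reroot(tree, node.number = child, position = pos)
      }
      # canonicalise node numbering (rerooting tools need not preserve the
      # root = ntip+1 convention downstream code relies on)
      if (!is.null(rooted$node.label)) {
        nl <- rooted$node.label
        nl <- c(nl, rep("", rooted$Nnode))[seq_len(rooted$Nnode)]
        nl[is.na(nl) | nl == "Root"] <- ""
        rooted$node.label <- nl
      }
      return(ape::read.tree(text = ape::write.tree(rooted)))
    }
    acc <- acc + len
  }
  stop("midpoint not found on diameter path (numeric failure)")
}

#' Collapse poorly supported branches into polytomies
#'
#' Contracts every internal (non-root) edge whose child node's support value
#' is below `min_support`; the children of a collapsed node are attached to
#' its parent and the collapsed edge's length is discarded. Supports are read
#' from `tree$node.label` (numeric; non-numeric or empty labels are kept).
#' With `min_support = 0` (the default) the tree is returned unchanged: no
#' support threshold is imposed unless the user asks for one.
#'
#' @param tree An `ape::phylo` (rooted or not) with node labels as supports.
#' @param min_support Collapse threshold on the same scale as the labels.
#' @return `phylo` with the same leaf set.
#' @export
collapse_low_support <- function(tree, min_support = 0) {
  if (min_support <= 0 || is.null(tree$node.label)) return(tree)
  repeat {
    ntip <- length(tree$tip.label)
    root <- ntip + 1L
    sup <- suppressWarnings(as.numeric(tree$node.label))
    bad <- which(!is.na(sup) & sup < min_support) + ntip
    bad <- setdiff(bad, root)
    if (!length(bad)) return(tree)
    n <- bad[1]
    e <- which(tree$edge[, 2] == n)
    p <- tree$edge[e, 1]
    tree$edge[tree$edge[, 1] == n, 1] <- p
    tree$edge <- tree$edge[-e, , drop = FALSE]
    if (!is.null(tree$edge.length)) tree$edge.length <- tree$edge.length[-e]
    tree$node.label <- tree$node.label[-(n - ntip)]
    tree$edge[tree$edge > n] <- tree$edge[tree$edge > n] - 1L
    tree$Nnode <- tree$Nnode - 1L
  }
}
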