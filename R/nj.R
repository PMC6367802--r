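# Neighbour-joining tree construction and bootstrap support.
#
# nj_tree() is a from-scratch Saitou-Nei implementation (Q-criterion joins,
# rate-corrected branch lengths).  On any additive distance matrix it
# reconstructs the generating tree exactly, which is the property the test
# suite leans on; ape::nj() serves only as an independent cross-check there.

#' Neighbour-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration: at each step join the pair (i, j)
#' minimizing `Q(i,j) = (n-2) d(i,j) - r_i - r_j`, with branch lengths from
#' the rate-corrected formulas.  A negative branch length is clamped to zero
#' and its deficit moved to the sibling branch, preserving the joined pair's
#' distance.  Ties in Q are broken by the lexicographic order of the two
#' node labels.  The result is the unrooted tree, represented with a single
#' trifurcating root node.
#'
#' @param d symmetric numeric matrix with zero diagonal, finite entries and
#'   at least 3 labelled rows.
#' @return an [ape::phylo] tree with branch lengths.
#' @examples
#' d <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' nj_tree(d)  # leaf branches 0.5, 1.5, 2.5
#' @export
nj_tree <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (nrow(d) < 3L) stopf("nj_tree() needs at least 3 taxa")
  if (is.null(rownames(d))) stopf("distance matrix must be labelled")
  if (any(!is.finite(d))) stopf("distance matrix has non-finite entries")
  if (max(abs(d - t(d))) > 1e-9) stopf("distance matrix is not symmetric")

  D <- unname(d)
  labels <- rownames(d)     # current node labels (tie-breaking)
  frag <- labels            # newick fragment per active node
  node_count <- 0L

  while (nrow(D) > 3L) {
    n <- nrow(D)
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    cand <- which(Q == min(Q), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    ord <- order(labels[cand[, 1]], labels[cand[, 2]])
    i <- cand[ord[1L], 1L]; j <- cand[ord[1L], 2L]

    bi <- 0.5 * D[i, j] + (r[i] - r[j]) / (2 * (n - 2))
    bj <- D[i, j] - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }

    new_frag <- sprintf("(%s:%.15g,%s:%.15g)", frag[i], bi, frag[j], bj)
    dnew <- pmax(0, 0.5 * (D[i, ] + D[j, ] - D[i, j]))[-c(i, j)]

    keep <- setdiff(seq_len(n), c(i, j))
    D <- D[keep, keep, drop = FALSE]
    D <- rbind(cbind(D, dnew), c(dnew, 0))
    frag <- c(frag[keep], new_frag)
    node_count <- node_count + 1L
    labels <- c(labels[keep], sprintf("%06d", node_count))
  }

  # final trifurcation: three-point formulas
  ba <- pmax(0, (D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  bb <- pmax(0, (D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  bc <- pmax(0, (D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  nwk <- sprintf("(%s:%.15g,%s:%.15g,%s:%.15g);",
                 frag[1], ba, frag[2], bb, frag[3], bc)
  ape::read.tree(text = nwk)
}

#' Non-trivial bipartitions of an unrooted tree
#'
#' Each internal edge splits the leaves in two; a split is keyed by the
#' sorted, comma-joined leaf set on the side *not* containing the
#' lexicographically smallest leaf, which makes keys invariant to rooting
#' and leaf order.
#'
#' @param tree an [ape::phylo] tree.
#' @return character vector of split keys, named by the internal node number
#'   subtending each split (root excluded).
#' @export
tree_bipartitions <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  ref <- min(tips)
  parts <- ape::prop.part(tree)
  nodes <- seq_along(parts) + length(tips)
  keys <- vapply(seq_along(parts), function(k) {
    side <- tips[parts[[k]]]
    if (ref %in% side) side <- setdiff(tips, side)
    paste(sort(side), collapse = ",")
  }, character(1))
  keep <- keys != "" & lengths(parts) > 1L & lengths(parts) < length(tips)
  stats::setNames(keys[keep], nodes[keep])
}

#' Bootstrap support for a neighbour-joining tree
#'
#' Resamples alignment columns with replacement `B` times, rebuilds the NJ
#' tree from each resampled alignment and scores every internal branch of
#' the original tree by the percentage of replicate trees containing the
#' same bipartition.  Supports are written into `tree$node.label` (root
#' empty) and also returned in the `support` attribute.
#'
#' @param alignment named character vector of equal-length gapped sequences.
#' @param B number of bootstrap replicates (default 1000).
#' @param seed optional integer seed controlling column resampling.
#' @param model distance model, see [protein_distances()].
#' @return the original NJ [ape::phylo] tree, with node labels giving
#'   percent support.
#' @export
bootstrap_support <- function(alignment, B = 1000L, seed = NULL,
                              model = c("p_distance", "poisson")) {
  model <- match.arg(model)
  stopifnot(B >= 1L)
  if (!is.null(seed)) set.seed(seed)
  M <- alignment_matrix(alignment)
  tree <- nj_tree(protein_distances(alignment, model))
  orig <- tree_bipartitions(tree)
  counts <- stats::setNames(numeric(length(orig)), names(orig))
  for (b in seq_len(B)) {
    cols <- sample.int(ncol(M), ncol(M), replace = TRUE)
    aln_b <- stats::setNames(
      apply(M[, cols, drop = FALSE], 1L, paste, collapse = ""),
      names(alignment))
    rep_tree <- nj_tree(protein_distances(aln_b, model))
    counts <- counts + (orig %in% tree_bipartitions(rep_tree))
  }
  support <- 100 * counts / B
  lab <- rep("", tree$Nnode)
  idx <- as.integer(names(orig)) - length(tree$tip.label)
  lab[idx] <- sprintf("%g", round(support, 1))
  tree$node.label <- lab
  attr(tree, "support") <- data.frame(
    node = as.integer(names(orig)), split = unname(orig),
    support = unname(support), stringsAsFactors = FALSE)
  tree
}
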