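#' UPGMA tree from a TCR distance matrix
#'
#' Average-linkage agglomeration (unweighted pair group method with arithmetic
#' mean). Clusters are merged at height equal to half their average pairwise
#' distance, so the height of the common ancestor of two leaves equals half
#' their cophenetic distance and the leaf-to-leaf path length equals the
#' average distance itself. Ties in the minimum inter-cluster distance are
#' broken toward the lexicographically smallest pair of cluster labels (each
#' cluster labelled by its smallest member id), making the tree reproducible.
#'
#' @param d Symmetric nonnegative distance matrix with zero diagonal and
#'   identifier dimnames (e.g. a [distance_matrix()] result), or a `dist`.
#' @return Object of class `tcr_dendro` (also `hclust`-compatible via
#'   [as.hclust.tcr_dendro()]): list with `merge`, `height`, `labels`,
#'   `order`, `members` (leaf index sets per internal node).
#' @export
upgma <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  d <- unclass(d)
  attr(d, "d_max") <- NULL
  attr(d, "no_kmer_ids") <- NULL
  n <- nrow(d)
  if (is.null(nrow(d)) || n < 2) stop("UPGMA needs at least 2 leaves")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-12)) )
    stop("distance matrix must be symmetric")
  if (any(d < 0)) stop("distance matrix must be nonnegative")
  if (any(diag(d) != 0)) stop("distance matrix must have a zero diagonal")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("L", seq_len(n))

  # active clusters: list of leaf index vectors; label = smallest member id
  active <- as.list(seq_len(n))
  clab <- labels                      # current label per active cluster
  node <- -seq_len(n)                 # hclust coding: negatives = leaves
  D <- d
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  members <- vector("list", n - 1)

  for (step in seq_len(n - 1)) {
    m <- length(active)
    Dv <- D
    diag(Dv) <- Inf
    dmin <- min(Dv)
    cand <- which(Dv == dmin, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    # lexicographic tie-break on (min label, max label) of each candidate pair
    key1 <- pmin(clab[cand[, 1]], clab[cand[, 2]])
    key2 <- pmax(clab[cand[, 1]], clab[cand[, 2]])
    pick <- order(key1, key2)[1]
    i <- cand[pick, 1]; j <- cand[pick, 2]
    if (i > j) { tmp <- i; i <- j; j <- tmp }

    merge[step, ] <- c(node[i], node[j])
    height[step] <- dmin / 2
    members[[step]] <- sort(c(active[[i]], active[[j]]))

    ni <- length(active[[i]]); nj <- length(active[[j]])
    newrow <- (ni * D[i, ] + nj * D[j, ]) / (ni + nj)
    keep <- setdiff(seq_len(m), c(i, j))
    D <- D[keep, keep, drop = FALSE]
    nr <- newrow[keep]
    D <- rbind(cbind(D, nr), c(nr, 0))
    active <- c(active[keep], list(members[[step]]))
    clab <- c(clab[keep], min(clab[c(i, j)]))
    node <- c(node[keep], step)
  }

  tree <- structure(
    list(merge = merge, height = height, labels = labels,
         members = members, method = "upgma", call = match.call(),
         dist.method = "tcr_min_kmer"),
    class = "tcr_dendro")
  tree$order <- leaf_order(merge, n)
  tree
}

# left-to-right leaf ordering by recursive traversal of the merge matrix
leaf_order <- function(merge, n) {
  desc <- function(k) {
    if (k < 0) return(-k)
    c(desc(merge[k, 1]), desc(merge[k, 2]))
  }
  desc(n - 1L)
}

#' @export
as.hclust.tcr_dendro <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height, order = x$order,
                 labels = x$labels, method = "average",
                 call = x$call, dist.method = x$dist.method),
            class = "hclust")
}

#' @export
print.tcr_dendro <- function(x, ...) {
  cat(sprintf("UPGMA tree with %d leaves (heights %.4g .. %.4g)\n",
              length(x$labels), min(x$height), max(x$height)))
  invisible(x)
}

#' Cophenetic distances of a UPGMA tree
#'
#' Twice the merge height of the most recent common ancestor, i.e. distances
#' on the scale of the input matrix.
#'
#' @param tree `tcr_dendro`.
#' @return `dist` object.
#' @export
cophenetic_distances <- function(tree) {
  stopifnot(inherits(tree, "tcr_dendro"))
  2 * stats::cophenetic(as.hclust(tree))
}

#' Export a UPGMA tree as newick
#'
#' @param tree `tcr_dendro`.
#' @param path Output file; when `NULL`, the newick string is returned.
#' @return The newick string, invisibly when written to a file.
#' @export
write_tree_newick <- function(tree, path = NULL) {
  phy <- ape::as.phylo(as.hclust(tree))
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}
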