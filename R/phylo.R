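#' Pairwise evolutionary distances from an alignment
#'
#' Computes the p-distance (fraction of mismatches over columns where both
#' rows are non-gap) for every pair of rows, optionally with the Kimura
#' protein correction `d = -ln(1 - p - p^2/5)`. Pairs sharing no comparable
#' column get distance 1. The correction is applied for `p < 0.75`; beyond
#' that it is capped at 10.
#'
#' @param family An [aligned_family()] (>= 2 rows).
#' @param correction `"none"` (p-distance, default) or `"kimura"`.
#' @return An object of class `"dist_matrix"`: a symmetric numeric matrix
#'   with zero diagonal and row/column names equal to the row ids.
#' @export
pairwise_distances <- function(family, correction = c("none", "kimura")) {
  correction <- match.arg(correction)
  stopifnot(inherits(family, "aligned_family"))
  n <- length(family$rows)
  if (n < 2L) stop("need at least 2 rows to compute distances")
  M <- do.call(rbind, strsplit(unname(family$rows), ""))
  gap <- matrix(M %in% GAP_CHARS, nrow = n)
  ids <- names(family$rows)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    ok_i <- !gap[i, ]
    for (j in (i + 1L):n) {
      comp <- ok_i & !gap[j, ]
      nc <- sum(comp)
      p <- if (nc == 0L) 1 else sum(M[i, comp] != M[j, comp]) / nc
      if (correction == "kimura")
        p <- if (p < 0.75) -log(1 - p - p^2 / 5) else 10
      D[i, j] <- D[j, i] <- p
    }
  }
  class(D) <- c("dist_matrix", "matrix")
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration: at each step the pair minimizing
#' `Q(i,j) = (r-2) D(i,j) - R(i) - R(j)` (with `R` the row sums over the `r`
#' active taxa) is joined. Ties are broken by the lexicographically smallest
#' sorted id pair, making the result reproducible. Negative branch lengths
#' are clamped to zero with the deficit transferred to the sister branch, so
#' each cherry's depth sum is preserved. The final three taxa are joined in a
#' trifurcation (the tree is unrooted); two taxa yield a single split edge.
#'
#' @param D A `"dist_matrix"` or plain symmetric matrix with ids as dimnames.
#' @return An unrooted `ape::phylo` tree over the ids.
#' @seealso [root_with_outgroup()]
#' @export
neighbor_joining <- function(D) {
  D <- unclass(D)
  if (!is.matrix(D) || nrow(D) != ncol(D)) stop("distance matrix must be square")
  if (any(!is.finite(D))) stop("distance matrix has non-finite entries")
  if (max(abs(D - t(D))) > 1e-12) stop("distance matrix must be symmetric")
  ids <- rownames(D)
  if (is.null(ids)) stop("distance matrix must carry row ids")
  n <- nrow(D)
  if (n < 2L) stop("need at least 2 taxa")
  if (n == 2L) {
    tr <- list(edge = matrix(c(3L, 1L, 3L, 2L), 2, 2, byrow = TRUE),
               edge.length = rep(D[1, 2] / 2, 2),
               tip.label = ids, Nnode = 1L)
    class(tr) <- "phylo"
    return(tr)
  }

  # node bookkeeping: tips are 1..n; internal nodes numbered from n+1
  node_of <- seq_len(n)              # active cluster -> phylo node id
  next_node <- n + 1L
  edges <- matrix(integer(0), 0, 2)
  elen <- numeric(0)
  active <- rep(TRUE, n)
  labs <- ids                        # active cluster labels (for tie-breaks)

  add_edge <- function(parent, child, len) {
    edges <<- rbind(edges, c(parent, child))
    elen <<- c(elen, max(len, 0))
  }

  while (sum(active) > 3L) {
    idx <- which(active)
    r <- length(idx)
    Dsub <- D[idx, idx, drop = FALSE]
    R <- rowSums(Dsub)
    Q <- (r - 2) * Dsub - outer(R, R, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    # lexicographically smallest sorted id pair
    keys <- apply(cand, 1, function(k) {
      p <- sort(c(labs[idx[k[1]]], labs[idx[k[2]]]))
      paste(p, collapse = "\r")
    })
    pick <- cand[order(keys)[1], ]
    i <- idx[pick[1]]; j <- idx[pick[2]]
    dij <- D[i, j]
    li <- dij / 2 + (R[pick[1]] - R[pick[2]]) / (2 * (r - 2))
    lj <- dij - li
    # clamp negatives, transferring the deficit to the sister branch
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    new <- next_node; next_node <- next_node + 1L
    add_edge(new, node_of[i], li)
    add_edge(new, node_of[j], lj)
    # distances from the new cluster
    k <- idx[idx != i & idx != j]
    D[i, k] <- D[k, i] <- (D[i, k] + D[j, k] - dij) / 2
    active[j] <- FALSE
    node_of[i] <- new
    labs[i] <- paste0("(", paste(sort(c(labs[i], labs[j])), collapse = ","), ")")
  }

  idx <- which(active)
  if (length(idx) == 3L) {
    a <- idx[1]; b <- idx[2]; c3 <- idx[3]
    la <- (D[a, b] + D[a, c3] - D[b, c3]) / 2
    lb <- (D[a, b] + D[b, c3] - D[a, c3]) / 2
    lc <- (D[a, c3] + D[b, c3] - D[a, b]) / 2
    hub <- next_node; next_node <- next_node + 1L
    add_edge(hub, node_of[a], la)
    add_edge(hub, node_of[b], lb)
    add_edge(hub, node_of[c3], lc)
  }

  n_internal <- next_node - n - 1L
  # renumber internal nodes so the last created (the hub) is the phylo root
  # ape convention: root = n+1; internal ids created in join order, so map
  # internal node k (n+1..) to n + (n_internal - (k - n) + 1)
  remap <- function(v) {
    ifelse(v <= n, v, n + (n_internal - (v - n) + 1L))
  }
  edges <- cbind(remap(edges[, 1]), remap(edges[, 2]))
  tr <- list(edge = edges, edge.length = elen, tip.label = ids,
             Nnode = n_internal)
  class(tr) <- "phylo"
  ape::reorder.phylo(tr, "cladewise")
}

#' Root a tree with the shuffled-query outgroup
#'
#' Places the root at the midpoint of the outgroup's pendant edge. By default
#' the outgroup leaf is then removed and its leftover degree-2 node
#' contracted, leaving a rooted tree over the homolog leaves only. Pairwise
#' path lengths among retained leaves are unchanged.
#'
#' @param tree An `ape::phylo` tree containing the outgroup as a tip.
#' @param outgroup_id Tip label of the outgroup.
#' @param drop_outgroup If `TRUE` (default) remove the outgroup after rooting.
#' @return A rooted `ape::phylo` tree.
#' @export
root_with_outgroup <- function(tree, outgroup_id, drop_outgroup = TRUE) {
  stopifnot(inherits(tree, "phylo"))
  tip <- match(outgroup_id, tree$tip.label)
  if (is.na(tip)) stop("outgroup '", outgroup_id, "' is not a leaf of the tree")
  if (is.null(tree$edge.length))
    tree$edge.length <- rep(0, nrow(tree$edge))
  pend <- which(tree$edge[, 2] == tip)
  half <- tree$edge.length[pend] / 2
  rooted <- phytools::reroot(tree, tip, position = half)
  if (drop_outgroup)
    rooted <- ape::drop.tip(rooted, outgroup_id, collapse.singles = TRUE)
  rooted
}

#' Read and write Newick trees
#'
#' Thin wrappers around `ape` with the package's conventions: missing branch
#' lengths default to zero, and `read(write(T))` preserves topology, tip ids
#' and branch lengths.
#'
#' @param text Newick string (or `file` a path).
#' @param file Optional path to read from instead of `text`.
#' @return For `read_newick`, an `ape::phylo`; for `write_newick`, a Newick
#'   string (invisibly also written to `file` when given).
#' @export
read_newick <- function(text = NULL, file = NULL) {
  tr <- if (!is.null(file)) ape::read.tree(file)
        else ape::read.tree(text = text)
  if (is.null(tr)) stop("failed to parse Newick input")
  if (is.null(tr$edge.length))
    tr$edge.length <- rep(0, nrow(tr$edge))
  tr
}

#' @rdname read_newick
#' @param tree An `ape::phylo` object.
#' @export
write_newick <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "phylo"))
  txt <- ape::write.tree(tree)
  if (!is.null(file)) writeLines(txt, file)
  invisible(txt)
}
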