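#' Label path from a leaf to the root
#'
#' Climbs from the leaf to the root collecting node labels, with an all-zeros
#' label prepended before the leaf. Consecutive entries are nested by
#' inclusion under the loss-only model (leaf-to-root, cysteines only gained
#' going back in time).
#'
#' @param labels A `"cys_labels"` object from [assign_inner_labels()].
#' @param leaf Tip label (or tip index) of the starting leaf.
#' @return Integer matrix: rows are the path labels
#'   `(all-zeros, leaf, parent, ..., root)`.
#' @export
root_path_labels <- function(labels, leaf) {
  tree <- attr(labels, "tree")
  ntip <- length(tree$tip.label)
  node <- if (is.character(leaf)) match(leaf, tree$tip.label) else as.integer(leaf)
  if (is.na(node) || node < 1L || node > ntip)
    stop("leaf '", leaf, "' is not a tip of the tree")
  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  path <- node
  while (parent[node] != 0L) {
    node <- parent[node]
    path <- c(path, node)
  }
  rbind(rep(0L, ncol(labels)), unclass(labels)[path, , drop = FALSE])
}

#' Weight increments from one step between adjacent labels
#'
#' Compares a node label `l_i` with its parent's `l_i1` (leaf-to-root
#' direction, `l_i` a subset of `l_i1`). Let `M` be the positions that are 0
#' in `l_i` and 1 in `l_i1` and `mu = |M|` the number of cysteines lost in
#' this step. Identical labels (`mu = 0`) give no information. `mu = 2` is a
#' clean tandem loss: that single candidate bond gains weight 1. For even
#' `mu > 2` the evolutionary sampling cannot separate the coupled events, so
#' all `mu(mu-1)/2` bonds among `M` share the evidence, each gaining
#' `2/(mu(mu-1))` (total still 1). Odd `mu` (parity breaking) contributes
#' nothing in this model.
#'
#' @param l_i,l_i1 Integer 0/1 vectors of equal length.
#' @return Data frame with columns `i`, `j` (1-based cysteine indices,
#'   `i < j`) and `w` (increment); zero rows when no inference is possible.
#' @export
compare_step <- function(l_i, l_i1) {
  if (length(l_i) != length(l_i1))
    stop("labels must have equal length")
  M <- which(l_i == 0L & l_i1 == 1L)
  mu <- length(M)
  if (mu < 2L || mu %% 2L == 1L)
    return(data.frame(i = integer(0), j = integer(0), w = numeric(0)))
  pairs <- t(combn(M, 2L))
  w <- if (mu == 2L) 1 else 2 / (mu * (mu - 1))
  data.frame(i = pairs[, 1], j = pairs[, 2], w = w)
}

#' Accumulate tandem-loss evidence into the connectivity graph
#'
#' Sums [compare_step()] increments over every leaf's root path. The
#' production path is a single pass over the tree edges: a step on edge
#' `(child, parent)` appears in the root path of each leaf below `child`, so
#' its increments are multiplied by that leaf count; the artificial
#' `(all-zeros, leaf)` step contributes once per leaf. The literal per-leaf
#' traversal (`method = "per_leaf"`) is retained as a cross-check and gives
#' identical results.
#'
#' @param labels A `"cys_labels"` object from [assign_inner_labels()].
#' @param method `"edges"` (single pass, default) or `"per_leaf"` (literal
#'   traversal of every leaf's path).
#' @return Object of class `"connectivity_graph"`: symmetric non-negative
#'   weight matrix over the cysteine indices, zero diagonal. Attribute
#'   `"informative_steps"` counts the (leaf-weighted) steps with even
#'   `mu >= 2`; total graph weight equals it exactly.
#' @export
accumulate_weights <- function(labels, method = c("edges", "per_leaf")) {
  method <- match.arg(method)
  stopifnot(inherits(labels, "cys_labels"))
  tree <- attr(labels, "tree")
  ntip <- length(tree$tip.label)
  if (ntip < 1L) stop("tree has no leaves")
  nb <- ncol(labels)
  W <- matrix(0, nb, nb)
  steps <- 0
  add <- function(inc, mult) {
    if (nrow(inc) == 0L) return()
    for (r in seq_len(nrow(inc))) {
      W[inc$i[r], inc$j[r]] <<- W[inc$i[r], inc$j[r]] + mult * inc$w[r]
      W[inc$j[r], inc$i[r]] <<- W[inc$i[r], inc$j[r]]
    }
    steps <<- steps + mult
  }
  lab <- unclass(labels)
  if (method == "per_leaf") {
    for (leaf in seq_len(ntip)) {
      path <- root_path_labels(labels, leaf)
      for (s in seq_len(nrow(path) - 1L))
        add(compare_step(path[s, ], path[s + 1L, ]), 1)
    }
  } else {
    zero <- rep(0L, nb)
    for (leaf in seq_len(ntip))
      add(compare_step(zero, lab[leaf, ]), 1)
    nl <- n_descendant_leaves(tree)
    for (e in seq_len(nrow(tree$edge))) {
      par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      add(compare_step(lab[ch, ], lab[par, ]), nl[ch])
    }
  }
  structure(W, class = c("connectivity_graph", class(W)),
            informative_steps = steps)
}

# number of leaves below each node (tips count themselves)
n_descendant_leaves <- function(tree) {
  ntip <- length(tree$tip.label)
  nl <- c(rep(1L, ntip), rep(0L, tree$Nnode))
  po <- ape::reorder.phylo(tree, "postorder")$edge
  for (e in seq_len(nrow(po)))
    nl[po[e, 1]] <- nl[po[e, 1]] + nl[po[e, 2]]
  nl
}

#' Export a connectivity graph as a TSV edge list
#'
#' One row per candidate bond with 1-based residue positions of the two
#' cysteines and the accumulated weight.
#'
#' @param graph A `"connectivity_graph"`.
#' @param positions Integer vector of oxidized residue positions (1-based);
#'   defaults to the cysteine indices themselves.
#' @param path Optional output file; when `NULL` the data frame is returned.
#' @return Data frame `(cys_i, cys_j, weight)`.
#' @export
write_graph_tsv <- function(graph, positions = NULL, path = NULL) {
  W <- unclass(graph)
  n <- nrow(W)
  if (is.null(positions)) positions <- seq_len(n)
  pr <- t(combn(seq_len(n), 2L))
  df <- data.frame(cys_i = positions[pr[, 1]], cys_j = positions[pr[, 2]],
                   weight = W[pr])
  if (!is.null(path))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  df
}
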