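#' Binary cysteine-presence label for one aligned row
#'
#' Bit k is 1 iff the row holds a cysteine at the k-th oxidized alignment
#' column. Gaps and all non-C residues count as absence.
#'
#' @param row Aligned sequence string.
#' @param oxidized_columns Integer vector of alignment columns.
#' @return Integer 0/1 vector of length `length(oxidized_columns)`.
#' @export
leaf_label <- function(row, oxidized_columns) {
  chars <- strsplit(row, "")[[1]]
  if (max(oxidized_columns) > length(chars))
    stop("row too short for the oxidized columns")
  as.integer(chars[oxidized_columns] == "C")
}

#' Parity of a cysteine-presence label
#'
#' Even parity means the number of present cysteines is compatible with a set
#' of intact disulfide bonds; odd parity marks a parity-breaking state.
#'
#' @param label Integer 0/1 vector.
#' @return `"even"` or `"odd"`.
#' @export
label_parity <- function(label) {
  if (sum(label) %% 2L == 0L) "even" else "odd"
}

#' Infer ancestral cysteine-presence labels on a rooted tree
#'
#' Every inner node receives the bitwise OR of its children's labels, computed
#' in a single post-order pass. Under the loss-only model (an oxidized
#' cysteine, once lost, is not regained within the family) this is the
#' maximum-parsimony reconstruction: a node carries a cysteine iff any leaf
#' below it does, so each bit flips at most once per lineage. The result is
#' identical to a leaf-initiated recursion with backtracking (OR is
#' associative, commutative and idempotent) and is independent of child
#' order. Multifurcations are handled by OR over all children.
#'
#' @param tree A rooted `ape::phylo`.
#' @param leaf_labels Matrix of 0/1 labels, one row per tip, rownames matching
#'   `tree$tip.label` (or in tip order if unnamed).
#' @return Object of class `"cys_labels"`: integer matrix with one row per
#'   tree node (tips first, ape numbering), plus attribute `"tree"`.
#' @export
assign_inner_labels <- function(tree, leaf_labels) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  leaf_labels <- as.matrix(leaf_labels)
  if (nrow(leaf_labels) != ntip)
    stop("need one label per leaf (", ntip, "), got ", nrow(leaf_labels))
  if (!is.null(rownames(leaf_labels))) {
    miss <- setdiff(tree$tip.label, rownames(leaf_labels))
    if (length(miss))
      stop("unlabeled leaf: ", paste(miss, collapse = ", "))
    leaf_labels <- leaf_labels[tree$tip.label, , drop = FALSE]
  }
  nb <- ncol(leaf_labels)
  nnode <- ntip + tree$Nnode
  lab <- matrix(0L, nnode, nb)
  lab[seq_len(ntip), ] <- as.integer(leaf_labels > 0)
  po <- ape::reorder.phylo(tree, "postorder")$edge
  for (e in seq_len(nrow(po))) {
    par <- po[e, 1]; ch <- po[e, 2]
    lab[par, ] <- pmax(lab[par, ], lab[ch, ])
  }
  rownames(lab) <- c(tree$tip.label, paste0("node", (ntip + 1L):nnode))
  structure(lab, class = c("cys_labels", class(lab)), tree = tree)
}

#' Leaf labels for every row of a family
#'
#' @param family An [aligned_family()] with mapped oxidized columns.
#' @return 0/1 integer matrix, one row per family row.
#' @export
leaf_labels <- function(family) {
  stopifnot(inherits(family, "aligned_family"))
  if (is.null(family$oxidized_columns))
    stop("oxidized columns not mapped; call map_oxidized_columns() first")
  t(vapply(family$rows, leaf_label, integer(length(family$oxidized_columns)),
           oxidized_columns = family$oxidized_columns))
}

#' Annotated Newick export of a labeled tree (debug aid)
#'
#' Writes the tree with each node's label appended as a comment, e.g.
#' `[&label=1100]`, for visual inspection of the reconstruction.
#'
#' @param labels A `"cys_labels"` object from [assign_inner_labels()].
#' @return Newick string with label comments.
#' @export
labeled_newick <- function(labels) {
  tree <- attr(labels, "tree")
  ntip <- length(tree$tip.label)
  bits <- apply(unclass(labels), 1, paste, collapse = "")
  tree$tip.label <- paste0(tree$tip.label, "[&label=", bits[seq_len(ntip)], "]")
  tree$node.label <- paste0("[&label=", bits[(ntip + 1L):length(bits)], "]")
  ape::write.tree(tree)
}
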