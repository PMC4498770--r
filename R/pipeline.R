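#' Predict disulfide connectivity from a protein family
#'
#' The package's main entry point. Given a query protein with known oxidized
#' cysteines and an alignment of homologs, runs the full evolutionary
#' pipeline: map oxidized positions to alignment columns; retain homologs
#' with an even cysteine count at those columns; append a shuffled-query
#' outgroup; build a neighbor-joining tree on pairwise distances (unless a
#' precomputed tree is supplied); root at the outgroup and drop it; infer
#' ancestral cysteine-presence labels by the loss-only parsimony model;
#' accumulate tandem-loss evidence into a connectivity graph; and resolve it
#' by maximum-weight perfect matching.
#'
#' If fewer than two homolog rows survive the parity filter there is no tree
#' to interpret; the connectivity is then guessed by a seeded uniform random
#' matching and the fit is flagged as a fallback.
#'
#' @param msa An [aligned_family()], or a path to an alignment file.
#' @param query A [query_protein()], or NULL to build one from `query_id`,
#'   the alignment and `cys`.
#' @param cys Integer vector of oxidized positions (1-based, in the ungapped
#'   query sequence); ignored when `query` is given.
#' @param query_id Id of the query row (defaults to the family's query row).
#' @param tree Optional precomputed rooted `ape::phylo` over the filtered
#'   family rows (e.g. from an external tree builder); when supplied, the
#'   distance/NJ/rooting steps are skipped.
#' @param correction Distance correction passed to [pairwise_distances()].
#' @param drop_outgroup Drop the outgroup leaf after rooting (default TRUE).
#' @param format Alignment format when `msa` is a path.
#' @param seed Integer seed (outgroup shuffle and random fallback).
#' @return An object of class `"cysbond"` with components `pattern` (the
#'   predicted [bond_pattern()]), `bonds` (data frame of bonded residue
#'   positions), `graph` (connectivity weight matrix), `tree` (rooted tree
#'   used), `labels`, `family` (filtered), `query`, `fallback` (logical) and
#'   `n_informative_steps`.
#' @examples
#' fam <- evolve_family(sim_config(n_leaves = 16, bonds = 2, seed = 7))
#' fit <- cysbond_family(fam, seed = 7)
#' fit
#' coef(fit)[1:3, 1:3]
#' @export
cysbond <- function(msa, query = NULL, cys = NULL, query_id = NULL,
                    tree = NULL, correction = c("none", "kimura"),
                    drop_outgroup = TRUE, format = c("fasta", "a3m"),
                    seed = 1L) {
  correction <- match.arg(correction)
  if (is.character(msa) && length(msa) == 1L)
    msa <- read_alignment(msa, format = match.arg(format), query_id = query_id)
  stopifnot(inherits(msa, "aligned_family"))
  if (!is.null(query_id)) msa$query_id <- query_id
  if (is.null(query)) {
    if (is.null(cys)) stop("either 'query' or 'cys' must be given")
    qrow <- msa$rows[[msa$query_id]]
    ungapped <- gsub("[-.]", "", qrow)
    query <- query_protein(msa$query_id, ungapped, cys)
  }
  msa <- map_oxidized_columns(msa, query)
  filtered <- filter_even_cysteine_homologs(msa)
  n_cys <- length(query$oxidized_positions)

  if (length(filtered$rows) < 2L) {
    pattern <- random_matching(n_cys, seed = seed)
    fit <- list(pattern = pattern, graph = NULL, tree = NULL, labels = NULL,
                family = filtered, query = query, fallback = TRUE,
                n_informative_steps = 0)
  } else {
    tree_kept <- tree
    if (is.null(tree)) {
      og <- make_outgroup(query, seed = seed)
      with_og <- add_outgroup(filtered, og)
      D <- pairwise_distances(with_og, correction = correction)
      nj <- neighbor_joining(D)
      rooted <- root_with_outgroup(nj, names(og), drop_outgroup = FALSE)
      tree <- ape::drop.tip(rooted, names(og), collapse.singles = TRUE)
      # outgroup never contributes a leaf path; with drop_outgroup = FALSE
      # it is merely retained in the reported tree
      tree_kept <- if (drop_outgroup) tree else rooted
    }
    labs <- leaf_labels(filtered)
    labels <- assign_inner_labels(tree, labs[tree$tip.label, , drop = FALSE])
    graph <- accumulate_weights(labels)
    pattern <- max_weight_perfect_matching(graph)
    fit <- list(pattern = pattern, graph = graph, tree = tree_kept,
                labels = labels, family = filtered, query = query,
                fallback = FALSE,
                n_informative_steps = attr(graph, "informative_steps"))
  }
  p <- unclass(fit$pattern)
  fit$bonds <- data.frame(
    residue_i = query$oxidized_positions[p[, 1]],
    residue_j = query$oxidized_positions[p[, 2]])
  fit$seed <- as.integer(seed)
  class(fit) <- "cysbond"
  fit
}

#' @describeIn cysbond Run the pipeline on a simulated family from
#'   [evolve_family()] (the root sequence acts as the query and is included
#'   as the first alignment row).
#' @param fam A `"sim_family"` object.
#' @export
cysbond_family <- function(fam, seed = 1L, correction = c("none", "kimura")) {
  stopifnot(inherits(fam, "sim_family"))
  rows <- c(setNames(fam$root_sequence, fam$query$id), fam$alignment)
  msa <- aligned_family(rows, query_id = fam$query$id)
  cysbond(msa, query = fam$query, seed = seed,
          correction = match.arg(correction))
}

#' @export
print.cysbond <- function(x, ...) {
  cat("Disulfide connectivity prediction for '", x$query$id, "'\n", sep = "")
  cat(sprintf("  %d oxidized cysteines, %d bonds\n",
              length(x$query$oxidized_positions), x$query$n_bonds))
  if (x$fallback) {
    cat("  [fallback] no informative family after filtering;",
        "connectivity guessed randomly (seed", x$seed, ")\n")
  }
  cat("  Predicted bonds (residue positions): ",
      paste(sprintf("%d-%d", x$bonds$residue_i, x$bonds$residue_j),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
summary.cysbond <- function(object, ...) {
  x <- object
  cat("Call: connectivity prediction from tandem cysteine losses\n")
  print(x)
  cat(sprintf("  Family rows after parity filter: %d (removed: %d)\n",
              length(x$family$rows), length(attr(x$family, "removed"))))
  if (!x$fallback) {
    cat(sprintf("  Informative steps (= total graph weight): %.6g\n",
                x$n_informative_steps))
    cat(sprintf("  Matched weight: %.6g of %.6g total\n",
                attr(x$pattern, "weight"), sum(unclass(x$graph)) / 2))
  }
  invisible(x)
}

#' @export
coef.cysbond <- function(object, ...) {
  if (is.null(object$graph)) return(NULL)
  W <- unclass(object$graph)
  dimnames(W) <- list(object$query$oxidized_positions,
                      object$query$oxidized_positions)
  W
}

#' @export
predict.cysbond <- function(object, ...) {
  object$bonds
}

#' @export
plot.cysbond <- function(x, ...) {
  if (is.null(x$tree)) {
    warning("fallback fit has no tree to plot")
    return(invisible(x))
  }
  lab <- unclass(x$labels)
  tr <- attr(x$labels, "tree")
  ntip <- length(tr$tip.label)
  tr$tip.label <- paste0(tr$tip.label, " ",
                         apply(lab[seq_len(ntip), , drop = FALSE], 1,
                               paste, collapse = ""))
  ape::plot.phylo(tr, ...)
  invisible(x)
}

#' Convert residue-position bond pairs to a cysteine-index pattern
#'
#' Maps a two-column matrix of bonded residue positions onto ranks within the
#' sorted set of all positions involved, yielding a [bond_pattern()] over
#' cysteine indices `1..n`.
#'
#' @param m Two-column matrix of residue positions.
#' @param positions Optional full vector of oxidized positions (defaults to
#'   those present in `m`).
#' @return A [bond_pattern()].
#' @export
pattern_from_positions <- function(m, positions = NULL) {
  m <- as.matrix(m)
  if (is.null(positions)) positions <- sort(unique(as.vector(m)))
  idx <- matrix(match(as.vector(m), positions), ncol = 2L)
  if (any(is.na(idx))) stop("bond position not among the oxidized positions")
  bond_pattern(idx, length(positions))
}

#' Score predictions against a truth file
#'
#' Reads truth and prediction TSVs (columns `protein_id`, `residue_i`,
#' `residue_j`) and produces the per-bond-count performance table with
#' random baselines.
#'
#' @param truth_path,pred_path TSV file paths (see [read_bonds_tsv()]).
#' @param round Round percentages for display.
#' @return A [performance_table()] data frame.
#' @export
evaluate_predictions <- function(truth_path, pred_path, round = TRUE) {
  truth <- read_bonds_tsv(truth_path)
  pred <- read_bonds_tsv(pred_path)
  missing <- setdiff(names(truth), names(pred))
  if (length(missing))
    stop("predictions missing for: ", paste(missing, collapse = ", "))
  if (length(truth) == 0L) stop("empty truth set")
  ids <- names(truth)
  tpat <- list(); ppat <- list()
  for (id in ids) {
    positions <- sort(unique(c(as.vector(truth[[id]]), as.vector(pred[[id]]))))
    tpat[[id]] <- pattern_from_positions(truth[[id]], positions)
    ppat[[id]] <- pattern_from_positions(pred[[id]], positions)
  }
  performance_table(scored_set(ids, tpat, ppat), round = round)
}
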