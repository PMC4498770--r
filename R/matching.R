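#' Construct a bond pattern from cysteine-index pairs
#'
#' A perfect matching on the oxidized cysteines: `n/2` disjoint unordered
#' pairs covering every index. Stored canonically (each pair sorted, pairs
#' sorted by first member).
#'
#' @param pairs Two-column matrix (or data frame) of 1-based cysteine
#'   indices.
#' @param n Total number of cysteines (defaults to `2 * nrow(pairs)`).
#' @return Object of class `"bond_pattern"`: a canonical two-column matrix.
#' @export
bond_pattern <- function(pairs, n = NULL) {
  pairs <- as.matrix(pairs)
  storage.mode(pairs) <- "integer"
  if (ncol(pairs) != 2L) stop("pairs must have two columns")
  if (is.null(n)) n <- 2L * nrow(pairs)
  v <- sort(as.vector(pairs))
  if (!identical(v, seq_len(n)))
    stop("pairs must partition the cysteines 1..", n, " into disjoint pairs")
  pairs <- t(apply(pairs, 1, sort))
  pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  dimnames(pairs) <- list(NULL, c("i", "j"))
  structure(pairs, class = c("bond_pattern", "matrix"))
}

#' @export
print.bond_pattern <- function(x, ...) {
  cat("Bond pattern (", nrow(x), " bonds): ",
      paste(sprintf("%d-%d", x[, 1], x[, 2]), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
format.bond_pattern <- function(x, ...) {
  paste(sprintf("%d-%d", x[, 1], x[, 2]), collapse = " ")
}

pattern_equal <- function(a, b) {
  isTRUE(all.equal(unclass(bond_pattern(a)), unclass(bond_pattern(b)),
                   check.attributes = FALSE))
}

check_weight_matrix <- function(W) {
  W <- unclass(W)
  if (!is.matrix(W) || nrow(W) != ncol(W)) stop("weight matrix must be square")
  n <- nrow(W)
  if (n < 2L || n %% 2L != 0L)
    stop("oxidized cysteine count must be even and >= 2, got ", n)
  if (any(!is.finite(W))) stop("weights must be finite")
  if (any(W < 0)) stop("weights must be non-negative")
  if (max(abs(W - t(W))) > 1e-9) stop("weight matrix must be symmetric")
  W
}

#' Maximum-weight perfect matching of the connectivity graph
#'
#' Resolves the accumulated pairwise evidence into the most likely disulfide
#' pattern: the perfect matching of maximum total weight. Computed by an
#' exact dynamic program over vertex subsets (optimal by construction, no
#' heuristic), with ties broken deterministically by the lexicographically
#' smallest sorted pair list. Perfectness is inherent: every cysteine is
#' matched even when its incident weights are all zero.
#'
#' @param graph A `"connectivity_graph"` or plain symmetric non-negative
#'   weight matrix with even dimension.
#' @return A [bond_pattern()] with attribute `"weight"` (total matched
#'   weight).
#' @seealso [brute_force_matching()] for the enumeration oracle,
#'   [random_matching()] for the seeded random baseline.
#' @export
max_weight_perfect_matching <- function(graph) {
  W <- check_weight_matrix(graph)
  n <- nrow(W)
  pairs <- if (n == 2L) matrix(c(1L, 2L), 1) else mwpm_dp(W)
  bp <- bond_pattern(pairs, n)
  attr(bp, "weight") <- sum(W[unclass(bp)])
  bp
}

#' Brute-force matching oracle by exhaustive enumeration
#'
#' Enumerates all `(n-1)!!` perfect matchings (lowest free cysteine paired
#' with each remaining partner, recursively) and keeps the maximum-weight
#' one under the same lexicographic tie-break as
#' [max_weight_perfect_matching()]. Desk-scale only: guarded at `n <= 16`.
#'
#' @inheritParams max_weight_perfect_matching
#' @return A [bond_pattern()] with attributes `"weight"` and
#'   `"n_enumerated"` (the number of matchings visited).
#' @export
brute_force_matching <- function(graph) {
  W <- check_weight_matrix(graph)
  n <- nrow(W)
  if (n > 16L) stop("brute force limited to n <= 16 ((n-1)!! growth)")
  best_w <- -Inf
  best <- NULL
  count <- 0L
  pairs <- matrix(0L, n / 2L, 2L)
  recurse <- function(free, depth, acc) {
    if (length(free) == 0L) {
      count <<- count + 1L
      # strict improvement keeps the first (lexicographically smallest) max
      if (acc > best_w + 1e-12) {
        best_w <<- acc
        best <<- pairs[seq_len(depth - 1L), , drop = FALSE]
      }
      return()
    }
    i <- free[1]
    for (j in free[-1]) {
      pairs[depth, ] <<- c(i, j)
      recurse(setdiff(free[-1], j), depth + 1L, acc + W[i, j])
    }
  }
  recurse(seq_len(n), 1L, 0)
  bp <- bond_pattern(best, n)
  attr(bp, "weight") <- best_w
  attr(bp, "n_enumerated") <- count
  bp
}

#' Seeded uniform random bond pattern
#'
#' Draws uniformly over all `(n-1)!!` perfect matchings (a uniform random
#' permutation paired off consecutively is uniform over matchings). Used as
#' the fallback when no informative family is available, and as the random
#' baseline in evaluation.
#'
#' @param n Even number of cysteines.
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used.
#' @return A [bond_pattern()].
#' @export
random_matching <- function(n, seed = NULL) {
  n <- as.integer(n)
  if (n < 2L || n %% 2L != 0L)
    stop("oxidized cysteine count must be even and >= 2, got ", n)
  draw <- function() matrix(sample.int(n), ncol = 2L, byrow = TRUE)
  pairs <- if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
  bond_pattern(pairs, n)
}

#' Write predicted bonds as TSV
#'
#' One bond per line: the 1-based residue positions of the two cysteines,
#' followed by the pattern's total matched weight in a trailing comment-free
#' `weight` column.
#'
#' @param pattern A [bond_pattern()].
#' @param positions Oxidized residue positions (1-based) used to translate
#'   cysteine indices; defaults to the indices themselves.
#' @param path Optional output path.
#' @return Data frame `(residue_i, residue_j, weight)`.
#' @export
write_bonds_tsv <- function(pattern, positions = NULL, path = NULL) {
  p <- unclass(pattern)
  if (is.null(positions)) positions <- seq_len(2L * nrow(p))
  w <- attr(pattern, "weight")
  df <- data.frame(residue_i = positions[p[, 1]], residue_j = positions[p[, 2]],
                   weight = if (is.null(w)) NA_real_ else w)
  if (!is.null(path))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  df
}
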