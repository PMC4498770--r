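#' Amino-acid frequency profile of one alignment column
#'
#' Relative frequency of each of the 20 standard amino acids among the
#' non-gap characters of the column; an all-gap column yields the zero
#' vector. Gaps carry no mass, so the 20 frequencies sum to at most 1 (less
#' than 1 only through non-standard residue codes).
#'
#' @param family An [aligned_family()].
#' @param column Alignment column index (1-based).
#' @return Named numeric vector of length 20.
#' @export
column_profile <- function(family, column) {
  stopifnot(inherits(family, "aligned_family"))
  width <- nchar(family$rows[[1]])
  if (column < 1L || column > width) stop("column out of alignment range")
  chars <- vapply(family$rows, function(s) substr(s, column, column),
                  character(1))
  chars <- chars[!is_gap(chars)]
  prof <- setNames(numeric(20), AA20)
  if (length(chars)) {
    tab <- table(factor(chars, levels = AA20))
    prof[] <- as.numeric(tab) / length(chars)
  }
  prof
}

# 13-column profile block (6 left, 6 right) around one oxidized cysteine,
# addressed in query-sequence coordinates; off-sequence positions give zero
# profiles. Returns a 260-vector.
window_block <- function(family, query, center_pos) {
  qrow <- strsplit(family$rows[[family$query_id]], "")[[1]]
  nongap <- which(!is_gap(qrow))
  blocks <- lapply((center_pos - 6L):(center_pos + 6L), function(p) {
    if (p < 1L || p > length(nongap)) return(setNames(numeric(20), AA20))
    column_profile(family, nongap[p])
  })
  unlist(blocks, use.names = FALSE)
}

#' Encode a cysteine pair as the 523-dimension benchmark feature vector
#'
#' The encoding used by supervised disulfide-connectivity predictors:
#' 20 x 2 x 13 = 520 dimensions of alignment-column amino-acid frequencies
#' over a 13-residue window (6 each side) around each of the two oxidized
#' cysteines; 1 dimension for the sequence separation `ln|c_i - c_j|`; and
#' 2 dimensions for the pair's relative order, the 1-based ranks of the two
#' cysteines among all `n` oxidized cysteines divided by `n`.
#'
#' @param family An [aligned_family()] (profiles are computed over all its
#'   rows; pass the unfiltered family for benchmark-faithful encodings).
#' @param query A [query_protein()].
#' @param i,j Cysteine indices into `query$oxidized_positions`, `i < j`.
#' @return Numeric vector of length 523 with names
#'   `win1_*`, `win2_*`, `separation`, `order_i`, `order_j`.
#' @export
encode_pair <- function(family, query, i, j) {
  stopifnot(inherits(family, "aligned_family"), inherits(query, "query_protein"))
  n <- length(query$oxidized_positions)
  i <- as.integer(i); j <- as.integer(j)
  if (i >= j || i < 1L || j > n)
    stop("need cysteine indices 1 <= i < j <= ", n)
  ci <- query$oxidized_positions[i]
  cj <- query$oxidized_positions[j]
  v <- c(window_block(family, query, ci),
         window_block(family, query, cj),
         log(abs(ci - cj)),
         i / n, j / n)
  names(v) <- c(paste0("win1_", rep(1:13, each = 20), "_", rep(AA20, 13)),
                paste0("win2_", rep(1:13, each = 20), "_", rep(AA20, 13)),
                "separation", "order_i", "order_j")
  v
}

#' Feature matrix for all candidate cysteine pairs
#'
#' One row per unordered pair of oxidized cysteines, `n(n-1)/2` rows in all.
#'
#' @inheritParams encode_pair
#' @param path Optional TSV output path (written with a header).
#' @return Numeric matrix, rownames `"i-j"` give the cysteine indices.
#' @export
encode_pairs <- function(family, query, path = NULL) {
  n <- length(query$oxidized_positions)
  pr <- t(combn(seq_len(n), 2L))
  X <- t(apply(pr, 1, function(k) encode_pair(family, query, k[1], k[2])))
  rownames(X) <- paste0(pr[, 1], "-", pr[, 2])
  if (!is.null(path))
    write.table(data.frame(pair = rownames(X), X, check.names = FALSE),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
  X
}

#' Append an unsupervised prediction bit to pair feature vectors
#'
#' Utility for the stacked benchmark encoding: adds one binary dimension per
#' pair, 1 where the pair is a predicted bond, giving 524-dimension vectors.
#'
#' @param X Feature matrix from [encode_pairs()].
#' @param pattern A [bond_pattern()] over the same cysteine indices.
#' @return `X` with an extra `predicted` column.
#' @export
append_prediction_bit <- function(X, pattern) {
  keys <- paste0(unclass(pattern)[, 1], "-", unclass(pattern)[, 2])
  cbind(X, predicted = as.numeric(rownames(X) %in% keys))
}
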