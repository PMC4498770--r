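#' Collect true and predicted bond patterns for scoring
#'
#' @param ids Character vector of protein ids.
#' @param truth,predicted Lists of [bond_pattern()]s (same length as `ids`);
#'   per protein, both patterns must cover the same cysteine set.
#' @return Object of class `"scored_set"`.
#' @export
scored_set <- function(ids, truth, predicted) {
  stopifnot(length(ids) == length(truth), length(ids) == length(predicted))
  if (length(ids) == 0L) stop("scored set must be non-empty")
  truth <- lapply(truth, bond_pattern)
  predicted <- lapply(predicted, bond_pattern)
  for (k in seq_along(ids)) {
    if (nrow(truth[[k]]) != nrow(predicted[[k]]))
      stop("protein '", ids[k], "': true and predicted patterns cover ",
           "different cysteine sets")
  }
  structure(list(ids = as.character(ids), truth = truth, predicted = predicted),
            class = "scored_set")
}

n_correct_bonds <- function(truth, predicted) {
  tk <- paste(truth[, 1], truth[, 2])
  pk <- paste(predicted[, 1], predicted[, 2])
  length(intersect(tk, pk))
}

#' Rb: fraction of correctly predicted bonds
#'
#' The number of correctly predicted disulfide bonds divided by the total
#' number of observed bonds. Micro-averaged by default (bond counts summed
#' over proteins before dividing); `macro = TRUE` averages the per-protein
#' fractions instead.
#'
#' @param s A [scored_set()].
#' @param macro Average per-protein Rb instead of pooling bonds.
#' @return Fraction in `[0, 1]`.
#' @export
score_rb <- function(s, macro = FALSE) {
  stopifnot(inherits(s, "scored_set"))
  correct <- mapply(n_correct_bonds, s$truth, s$predicted)
  total <- vapply(s$truth, nrow, integer(1))
  if (macro) mean(correct / total) else sum(correct) / sum(total)
}

#' Qp: fraction of proteins with fully correct connectivity
#'
#' A protein counts as correct only when the predicted pattern equals the
#' true one exactly. With `folds` given, Qp is computed per fold and the
#' fold values averaged (the cross-validation-style averaging used on
#' benchmark datasets; note this is subject to small-fold sampling bias and
#' can differ from the whole-dataset value).
#'
#' @param s A [scored_set()].
#' @param folds Optional integer/factor vector assigning each protein to a
#'   fold; `NULL` (default) scores the whole set at once.
#' @return Fraction in `[0, 1]`.
#' @export
score_qp <- function(s, folds = NULL) {
  stopifnot(inherits(s, "scored_set"))
  exact <- mapply(function(t, p) pattern_equal(t, p), s$truth, s$predicted)
  if (is.null(folds)) return(mean(exact))
  if (length(folds) != length(exact))
    stop("folds must assign every protein")
  mean(tapply(exact, folds, mean))
}

#' Closed-form random baselines for Rb and Qp
#'
#' For a protein with `d` bonds (`2d` oxidized cysteines) a uniformly random
#' perfect matching pairs any given cysteine with each of the other `2d - 1`
#' uniformly, so the expected fraction of correct bonds is `1/(2d - 1)`; the
#' probability of drawing the one fully correct pattern out of the
#' `(2d - 1)!!` matchings is `1/(2d - 1)!!`.
#'
#' @param d Number of disulfide bonds (vectorized, `d >= 1`).
#' @return Data frame with columns `d`, `rb` and `qp` in percent.
#' @examples
#' random_baseline(2:5)
#' @export
random_baseline <- function(d) {
  d <- as.integer(d)
  if (any(d < 1L)) stop("number of bonds must be >= 1")
  data.frame(d = d,
             rb = 100 / (2 * d - 1),
             qp = 100 / double_factorial(2L * d - 1L))
}

#' Double factorial
#'
#' `(2d - 1)!! = 1 * 3 * 5 * ... * (2d - 1)` counts the perfect matchings on
#' `2d` labeled vertices.
#'
#' @param k Non-negative integer(s).
#' @return Numeric vector.
#' @export
double_factorial <- function(k) {
  vapply(as.integer(k), function(x) {
    if (x < 0L) stop("k must be non-negative")
    if (x <= 1L) return(1)
    prod(seq.int(x, 1L, by = -2L))
  }, numeric(1))
}

#' Read / write truth or prediction TSV files
#'
#' Format: columns `protein_id`, `residue_i`, `residue_j` (1-based), one bond
#' per row.
#'
#' @param path File path.
#' @return For the reader, a named list of two-column matrices of residue
#'   positions (one per protein).
#' @export
read_bonds_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("protein_id", "residue_i", "residue_j")
  if (!all(need %in% names(df)))
    stop("bonds file must have columns: ", paste(need, collapse = ", "))
  split_df <- split(df[, c("residue_i", "residue_j")], df$protein_id)
  lapply(split_df, as.matrix)
}

#' @rdname read_bonds_tsv
#' @param bonds Named list of two-column matrices of residue positions.
#' @export
write_bonds_set_tsv <- function(bonds, path) {
  rows <- do.call(rbind, lapply(names(bonds), function(id) {
    m <- bonds[[id]]
    data.frame(protein_id = id, residue_i = m[, 1], residue_j = m[, 2])
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Benchmark-style performance table stratified by bond count
#'
#' One row per number of bonds `d` with micro-averaged Rb, Qp, the
#' closed-form random baselines and the protein count; a final row gives the
#' protein-weighted averages over strata. Percentages are rounded to the
#' nearest integer (values below 0.5 to one decimal) when `round = TRUE`, as
#' is conventional in this literature; raw values with `round = FALSE`.
#'
#' @param s A [scored_set()].
#' @param round Round percentages for display.
#' @return Data frame with columns `d`, `n`, `rb`, `qp`, `random_rb`,
#'   `random_qp`.
#' @export
performance_table <- function(s, round = TRUE) {
  stopifnot(inherits(s, "scored_set"))
  d <- vapply(s$truth, nrow, integer(1))
  strata <- sort(unique(d))
  rows <- lapply(strata, function(dd) {
    idx <- which(d == dd)
    sub <- scored_set(s$ids[idx], s$truth[idx], s$predicted[idx])
    base <- random_baseline(dd)
    data.frame(d = dd, n = length(idx),
               rb = 100 * score_rb(sub), qp = 100 * score_qp(sub),
               random_rb = base$rb, random_qp = base$qp)
  })
  tab <- do.call(rbind, rows)
  wavg <- function(x) sum(x * tab$n) / sum(tab$n)
  tab <- rbind(tab, data.frame(d = NA, n = sum(tab$n),
                               rb = wavg(tab$rb), qp = wavg(tab$qp),
                               random_rb = wavg(tab$random_rb),
                               random_qp = wavg(tab$random_qp)))
  if (round) {
    for (cl in c("rb", "qp", "random_rb", "random_qp"))
      tab[[cl]] <- ifelse(tab[[cl]] < 0.5, round(tab[[cl]], 1), round(tab[[cl]]))
  }
  tab
}
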