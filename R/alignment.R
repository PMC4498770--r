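#' Describe a query protein with known oxidized cysteines
#'
#' Bundles a protein sequence with the ordered positions of its oxidized
#' (disulfide-bonded) cysteines. Oxidation states are taken as known input;
#' the package predicts only which cysteines pair with which.
#'
#' @param id Character scalar, sequence identifier.
#' @param sequence Amino-acid string (upper or lower case).
#' @param oxidized_positions Strictly increasing integer vector of 1-based
#'   positions in `sequence`, each of which must hold a cysteine. The count
#'   must be even and at least 2; the number of disulfide bonds is half of it.
#'
#' @return An object of class `"query_protein"` with elements `id`,
#'   `sequence`, `oxidized_positions` and `n_bonds`.
#' @examples
#' q <- query_protein("toy", "MCACCAC", c(2, 4, 5, 7))
#' q$n_bonds
#' @export
query_protein <- function(id, sequence, oxidized_positions) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  pos <- as.integer(oxidized_positions)
  if (length(pos) < 2L || length(pos) %% 2L != 0L)
    stop("oxidized cysteine count must be even and >= 2, got ", length(pos))
  if (any(diff(pos) <= 0L))
    stop("oxidized positions must be strictly increasing")
  if (any(pos < 1L) || any(pos > nchar(sequence)))
    stop("oxidized position out of sequence range")
  res <- strsplit(sequence, "")[[1]][pos]
  if (any(res != "C"))
    stop("oxidized position(s) ", paste(pos[res != "C"], collapse = ", "),
         " do not hold a cysteine")
  structure(list(id = id, sequence = sequence,
                 oxidized_positions = pos,
                 n_bonds = length(pos) %/% 2L),
            class = "query_protein")
}

#' Read a multiple sequence alignment (aligned FASTA or A3M)
#'
#' In the A3M dialect, lowercase letters mark insertion states relative to the
#' query/master sequence; these (and `.` padding) are removed so that every
#' row lives in the query's match-column frame. Aligned FASTA is read as-is.
#'
#' @param path Path to the alignment file.
#' @param format `"fasta"` (aligned, all rows equal length) or `"a3m"`.
#' @param query_id Identifier of the query row; defaults to the first row.
#'
#' @return An object of class `"aligned_family"`: a list with `rows` (named
#'   character vector of equal-length aligned sequences, uppercase),
#'   `query_id`, and `oxidized_columns` (NULL until
#'   [map_oxidized_columns()] is applied).
#' @seealso [map_oxidized_columns()], [filter_even_cysteine_homologs()]
#' @export
read_alignment <- function(path, format = c("fasta", "a3m"), query_id = NULL) {
  format <- match.arg(format)
  seqs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             forceDNAtolower = FALSE, seqonly = FALSE)
  rows <- vapply(seqs, function(s) as.character(s)[1], character(1))
  names(rows) <- sanitize_ids(names(seqs))
  if (format == "a3m")
    rows <- vapply(rows, strip_insertion_states, character(1))
  rows <- toupper(rows)
  len <- nchar(rows)
  if (length(unique(len)) != 1L) {
    bad <- names(rows)[which(len != len[1])[1]]
    stop("ragged alignment: row '", bad, "' has length ", nchar(rows[bad]),
         ", expected ", len[1])
  }
  aligned_family(rows, query_id = if (is.null(query_id)) names(rows)[1] else query_id)
}

#' Construct an aligned family from sequences in memory
#'
#' @param rows Named character vector of aligned sequences (equal length).
#' @param query_id Name of the query row (must be present in `rows`).
#' @param oxidized_columns Optional integer vector of alignment columns
#'   corresponding to the query's oxidized cysteines.
#' @return An `"aligned_family"` object.
#' @export
aligned_family <- function(rows, query_id, oxidized_columns = NULL) {
  stopifnot(is.character(rows), length(rows) >= 1L)
  if (is.null(names(rows)) || any(!nzchar(names(rows))))
    stop("all alignment rows must be named")
  names(rows) <- sanitize_ids(names(rows))
  if (length(unique(nchar(rows))) != 1L)
    stop("aligned rows must have equal length")
  query_id <- sanitize_ids(query_id)
  if (!query_id %in% names(rows))
    stop("query row '", query_id, "' not found in alignment")
  structure(list(rows = toupper(rows), query_id = query_id,
                 oxidized_columns = oxidized_columns),
            class = "aligned_family")
}

# Drop a3m insertion states: lowercase letters and '.' padding.
strip_insertion_states <- function(s) {
  gsub("[a-z.]", "", s)
}

# Newick-unsafe characters replaced by '_'; duplicate ids get ordinal suffixes.
sanitize_ids <- function(ids) {
  ids <- gsub("[^A-Za-z0-9_.|-]", "_", ids)
  dup <- duplicated(ids)
  if (any(dup)) {
    for (i in which(dup)) {
      k <- 2L
      while (paste0(ids[i], "_", k) %in% ids) k <- k + 1L
      ids[i] <- paste0(ids[i], "_", k)
    }
  }
  ids
}

#' Map the query's oxidized sequence positions to alignment columns
#'
#' Walks the (gapped) query row and returns, for each oxidized position, the
#' alignment column it occupies. The returned columns are also stored on the
#' family object.
#'
#' @param family An [aligned_family()] object.
#' @param query A [query_protein()] whose ungapped sequence equals the
#'   family's query row with gaps removed.
#' @return The family with `oxidized_columns` filled in.
#' @export
map_oxidized_columns <- function(family, query) {
  stopifnot(inherits(family, "aligned_family"), inherits(query, "query_protein"))
  qrow <- family$rows[[family$query_id]]
  chars <- strsplit(qrow, "")[[1]]
  nongap <- which(!is_gap(chars))
  ungapped <- paste(chars[nongap], collapse = "")
  if (!identical(ungapped, query$sequence))
    stop("query row (ungapped) does not match the query sequence")
  cols <- nongap[query$oxidized_positions]
  if (any(chars[cols] != "C"))
    stop("mapped column(s) ", paste(cols[chars[cols] != "C"], collapse = ", "),
         " do not hold 'C' in the query row")
  family$oxidized_columns <- as.integer(cols)
  family$query <- query
  family
}

#' Retain only homologs with an even cysteine count at the oxidized columns
#'
#' Homologs with an odd number of cysteines across the oxidized alignment
#' columns carry a parity-breaking signal (a spurious single mutation) and are
#' removed. Zero cysteines is even, so cysteine-free homologs are retained;
#' their all-zero labels are uninformative but harmless. The query row is
#' always retained (its count is the full even set by construction), and row
#' order is preserved.
#'
#' @param family An [aligned_family()] with `oxidized_columns` mapped.
#' @return The filtered family; attribute `"removed"` lists dropped row ids.
#' @export
filter_even_cysteine_homologs <- function(family) {
  stopifnot(inherits(family, "aligned_family"))
  if (is.null(family$oxidized_columns))
    stop("oxidized columns not mapped; call map_oxidized_columns() first")
  counts <- vapply(family$rows, function(s) {
    sum(strsplit(s, "")[[1]][family$oxidized_columns] == "C")
  }, integer(1))
  keep <- counts %% 2L == 0L
  keep[names(family$rows) == family$query_id] <- TRUE
  removed <- names(family$rows)[!keep]
  family$rows <- family$rows[keep]
  attr(family, "removed") <- removed
  family
}

#' Generate the shuffled-query outgroup sequence
#'
#' A deliberately distant sequence obtained by randomly permuting the query's
#' residues. Appended as the last row of the alignment, it branches outside
#' the family tree and provides a consistently defined root. It is machinery
#' for rooting, not a homolog, so it bypasses the even-cysteine filter.
#'
#' @param query A [query_protein()].
#' @param seed Integer seed for the shuffle (reproducible).
#' @param id Identifier for the outgroup row.
#' @return Named character vector of length 1: the shuffled sequence.
#' @export
make_outgroup <- function(query, seed = 1L, id = "OUTGROUP") {
  stopifnot(inherits(query, "query_protein"))
  chars <- strsplit(query$sequence, "")[[1]]
  shuffled <- withr::with_seed(as.integer(seed), sample(chars))
  setNames(paste(shuffled, collapse = ""), id)
}

#' Append an outgroup row to an aligned family
#'
#' The outgroup is placed in the query's match-column frame: its residues are
#' laid over the query row's non-gap columns, with gaps elsewhere.
#'
#' @param family An [aligned_family()].
#' @param outgroup Named character vector as returned by [make_outgroup()].
#' @return The family with the outgroup as last row.
#' @export
add_outgroup <- function(family, outgroup) {
  stopifnot(inherits(family, "aligned_family"))
  qrow <- strsplit(family$rows[[family$query_id]], "")[[1]]
  og <- strsplit(unname(outgroup), "")[[1]]
  nongap <- which(!is_gap(qrow))
  if (length(og) != length(nongap))
    stop("outgroup length does not match the ungapped query")
  row <- rep("-", length(qrow))
  row[nongap] <- og
  rows <- c(family$rows, setNames(paste(row, collapse = ""), names(outgroup)))
  family$rows <- rows
  family$outgroup_id <- names(outgroup)
  family
}

#' @export
print.aligned_family <- function(x, ...) {
  cat("Aligned family: ", length(x$rows), " rows x ",
      nchar(x$rows[[1]]), " columns\n", sep = "")
  cat("Query row: ", x$query_id, "\n", sep = "")
  if (!is.null(x$oxidized_columns))
    cat("Oxidized columns: ", paste(x$oxidized_columns, collapse = ", "), "\n",
        sep = "")
  invisible(x)
}

#' Write an aligned family to FASTA
#' @param family An [aligned_family()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(family, path) {
  seqinr::write.fasta(as.list(unname(family$rows)), names(family$rows),
                      file.out = path)
  invisible(path)
}
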