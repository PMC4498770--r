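# shared fixtures and small oracles for the test suite

# write a named character vector of sequences as a FASTA file, return path
write_fasta_tmp <- function(rows, ext = ".fasta") {
  path <- tempfile(fileext = ext)
  writeLines(unlist(lapply(names(rows), function(id) c(paste0(">", id), rows[[id]]))),
             path)
  path
}

# a tiny hand-built family: query MCACCA with oxidized cysteines 2,4,5,
# plus one extra bonded pair position to make 4 cysteines where needed
toy_family <- function() {
  rows <- c(q = "MCACCACA", h1 = "MCACCACA", h2 = "MAACCACA", h3 = "MCAACACA")
  aligned_family(rows, query_id = "q")
}

# random symmetric non-negative weight matrix with zero diagonal
random_graph <- function(n, seed = NULL) {
  draw <- function() {
    W <- matrix(0, n, n)
    W[upper.tri(W)] <- runif(n * (n - 1) / 2)
    W + t(W)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# partner-vector representation of a bond pattern (partner[i] = j)
partner_vec <- function(pattern) {
  p <- unclass(pattern)
  n <- 2L * nrow(p)
  out <- integer(n)
  out[p[, 1]] <- p[, 2]
  out[p[, 2]] <- p[, 1]
  out
}

# fast empirical Rb/Qp of uniform random matchings against a fixed truth
empirical_random_scores <- function(d, n_draws, seed) {
  n <- 2L * d
  truth <- partner_vec(bond_pattern(matrix(seq_len(n), ncol = 2, byrow = TRUE)))
  swap <- as.vector(rbind(seq(2, n, by = 2), seq(1, n, by = 2)))
  withr::with_seed(seed, {
    correct <- integer(n_draws)
    for (r in seq_len(n_draws)) {
      perm <- sample.int(n)
      partner <- integer(n)
      partner[perm] <- perm[swap]
      correct[r] <- sum(partner == truth)
    }
    list(rb = mean(correct) / n, qp = mean(correct == n))
  })
}

# additive distance matrix (path lengths) from a tree with branch lengths
additive_matrix <- function(tree) {
  D <- ape::cophenetic.phylo(tree)
  ids <- sort(rownames(D))
  D[ids, ids]
}

# the 20 standard amino acids in the profile-block order
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}
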