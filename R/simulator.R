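#' Random rooted binary tree for simulation
#'
#' Topology by successive random splitting of leaf edges, branch lengths
#' drawn from an exponential distribution.
#'
#' @param n_leaves Number of leaves (>= 2).
#' @param seed Integer seed.
#' @param rate Rate of the exponential branch-length distribution.
#' @return A rooted binary `ape::phylo` with tip labels `t1..tn`.
#' @export
random_tree <- function(n_leaves, seed = 1L, rate = 10) {
  n_leaves <- as.integer(n_leaves)
  if (n_leaves < 2L) stop("need at least 2 leaves")
  withr::with_seed(as.integer(seed), {
    if (n_leaves == 2L) {
      tr <- read_newick("(t1:1,t2:1);")
      tr$edge.length <- rexp(2, rate)
      tr
    } else {
      ape::rtree(n_leaves, rooted = TRUE, br = function(k) rexp(k, rate))
    }
  })
}

#' Simulation settings for a synthetic disulfide-bonded family
#'
#' The generator emulates the loss-only tandem-mutation model: along each
#' branch, background (non-cysteine) sites substitute independently; each
#' member of an intact disulfide bond is lost with base per-branch hazard
#' `p_loss / 2`, and when exactly one member falls, evolutionary pressure
#' drags its partner down in the same step with probability `p_tandem` (the
#' compensatory signal; the bond as a whole thus suffers a first loss with
#' probability close to `p_loss`). An orphaned cysteine keeps the same
#' per-site hazard, so with `p_tandem = 0` all cysteine losses are i.i.d.
#' and carry no pairing signal. Restoration of a lost cysteine has
#' probability `p_restore`, zero by default so that oxidized cysteines can
#' only be lost.
#'
#' @param n_leaves Number of homolog leaves.
#' @param seq_length Ungapped sequence length.
#' @param bonds A [bond_pattern()] over residue *positions*, or an integer
#'   `d` to plant `d` bonds at evenly spread positions.
#' @param p_sub Per-branch substitution probability of a background site.
#' @param p_loss Per-branch loss probability of a bonded cysteine.
#' @param p_tandem Probability that the partner is lost in the same step.
#' @param p_restore Per-branch restoration probability of a lost cysteine.
#' @param seed Integer seed.
#' @return A `"sim_config"` list.
#' @export
sim_config <- function(n_leaves = 64L, seq_length = 100L, bonds = 3L,
                       p_sub = 0.05, p_loss = 0.3, p_tandem = 1.0,
                       p_restore = 0, seed = 1L) {
  probs <- c(p_sub = p_sub, p_loss = p_loss, p_tandem = p_tandem,
             p_restore = p_restore)
  if (any(probs < 0) || any(probs > 1))
    stop("probabilities must lie in [0, 1]")
  if (length(bonds) == 1L && is.numeric(bonds) && !is.matrix(bonds)) {
    d <- as.integer(bonds)
    pos <- round(seq(5, seq_length - 4, length.out = 2L * d))
    # planted pairing deliberately non-trivial: positions paired at random
    pairs <- withr::with_seed(as.integer(seed) + 1L,
                              matrix(sample(pos), ncol = 2L, byrow = TRUE))
    bonds <- pairs
  }
  positions <- sort(unique(as.vector(as.matrix(bonds))))
  if (max(positions) > seq_length) stop("planted bonds exceed sequence length")
  structure(list(n_leaves = as.integer(n_leaves),
                 seq_length = as.integer(seq_length),
                 bonds = as.matrix(bonds), positions = positions,
                 p_sub = p_sub, p_loss = p_loss, p_tandem = p_tandem,
                 p_restore = p_restore, seed = as.integer(seed)),
            class = "sim_config")
}

#' Evolve a synthetic protein family with a planted connectivity
#'
#' Draws a root sequence with cysteines exactly at the planted bond positions
#' (background sites uniform over the 19 non-C residues, keeping the
#' oxidized-column mapping unambiguous) and evolves it down a random tree
#' under the model described in [sim_config()]. The alignment is gap-free,
#' so sequence positions and alignment columns coincide.
#'
#' @param cfg A [sim_config()].
#' @return A `"sim_family"` list: `tree` (true rooted tree), `alignment`
#'   (named vector of leaf sequences), `bonds` (planted [bond_pattern()] over
#'   cysteine indices), `positions` (oxidized residue positions),
#'   `root_sequence`, `query` (a [query_protein()] built from the root
#'   sequence), and `states` (true 0/1 cysteine retention per tree node).
#' @export
evolve_family <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, {
    tree <- ape::rtree(cfg$n_leaves, rooted = TRUE,
                       br = function(k) rexp(k, 10))
    L <- cfg$seq_length
    pos <- cfg$positions
    nb <- length(pos)
    partner <- integer(nb)
    idx_of <- match(as.vector(cfg$bonds), pos)
    bm <- matrix(idx_of, ncol = 2L)
    partner[bm[, 1]] <- bm[, 2]
    partner[bm[, 2]] <- bm[, 1]

    non_c <- setdiff(AA20, "C")
    root_seq <- sample(non_c, L, replace = TRUE)
    root_seq[pos] <- "C"

    ntip <- length(tree$tip.label)
    nnode <- ntip + tree$Nnode
    seqs <- vector("list", nnode)
    states <- matrix(NA_integer_, nnode, nb)
    root <- ntip + 1L
    seqs[[root]] <- root_seq
    states[root, ] <- 1L

    evolve_branch <- function(s, st) {
      # background substitutions (all non-oxidized sites)
      bg <- setdiff(seq_len(L), pos)
      mut <- bg[runif(length(bg)) < cfg$p_sub]
      if (length(mut))
        s[mut] <- vapply(s[mut], function(a)
          sample(setdiff(non_c, a), 1L), character(1))
      # cysteine dynamics at oxidized sites
      new_st <- st
      done <- rep(FALSE, nb)
      for (k in seq_len(nb)) {
        if (done[k]) next
        p <- partner[k]
        h <- cfg$p_loss / 2        # per-site base hazard per branch
        if (st[k] == 1L && st[p] == 1L) {
          # independent base deaths; the tandem coupling then drags the
          # partner of a lone casualty with probability p_tandem, so at
          # p_tandem = 0 all sites are i.i.d. and carry no pairing signal
          die_k <- runif(1) < h
          die_p <- runif(1) < h
          if (xor(die_k, die_p) && runif(1) < cfg$p_tandem) die_k <- die_p <- TRUE
          if (die_k) new_st[k] <- 0L
          if (die_p) new_st[p] <- 0L
          done[p] <- TRUE
        } else if (st[k] == 1L) {
          # orphan cysteine keeps the same per-site hazard
          if (runif(1) < h) new_st[k] <- 0L
        } else {                         # lost; possible restoration
          if (cfg$p_restore > 0 && runif(1) < cfg$p_restore) new_st[k] <- 1L
        }
        done[k] <- TRUE
      }
      for (k in seq_len(nb)) {
        if (new_st[k] == 1L && st[k] == 0L) s[pos[k]] <- "C"
        if (new_st[k] == 0L) {
          if (st[k] == 1L) s[pos[k]] <- sample(non_c, 1L)
          else if (runif(1) < cfg$p_sub)
            s[pos[k]] <- sample(setdiff(non_c, s[pos[k]]), 1L)
        }
      }
      list(s = s, st = new_st)
    }

    # pre-order traversal over edges
    co <- ape::reorder.phylo(tree, "cladewise")$edge
    for (e in seq_len(nrow(co))) {
      par <- co[e, 1]; ch <- co[e, 2]
      out <- evolve_branch(seqs[[par]], states[par, ])
      seqs[[ch]] <- out$s
      states[ch, ] <- out$st
    }

    alignment <- vapply(seq_len(ntip), function(i)
      paste(seqs[[i]], collapse = ""), character(1))
    names(alignment) <- tree$tip.label
    rownames(states) <- c(tree$tip.label, paste0("node", (ntip + 1L):nnode))

    structure(list(
      tree = tree,
      alignment = alignment,
      bonds = bond_pattern(bm, nb),
      positions = pos,
      root_sequence = paste(root_seq, collapse = ""),
      query = query_protein("query", paste(root_seq, collapse = ""), pos),
      states = states,
      config = cfg), class = "sim_family")
  })
}

#' Write a simulated family to disk
#'
#' Emits the leaf alignment (FASTA, query first), the true tree (Newick) and
#' the planted bonds (TSV), directly consumable by the command-line
#' interface.
#'
#' @param fam A `"sim_family"` from [evolve_family()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three file paths.
#' @export
write_sim_family <- function(fam, dir) {
  stopifnot(inherits(fam, "sim_family"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  msa <- file.path(dir, "family.fasta")
  rows <- c(setNames(fam$root_sequence, fam$query$id), fam$alignment)
  seqinr::write.fasta(as.list(unname(rows)), names(rows), file.out = msa)
  nwk <- file.path(dir, "true_tree.nwk")
  write_newick(fam$tree, file = nwk)
  tsv <- file.path(dir, "truth.tsv")
  bp <- unclass(fam$bonds)
  write_bonds_set_tsv(setNames(list(cbind(fam$positions[bp[, 1]],
                                          fam$positions[bp[, 2]])),
                               fam$query$id), tsv)
  c(msa = msa, tree = nwk, truth = tsv)
}

#' Planted-connectivity recovery experiment
#'
#' For each grid row, simulates families and runs the full pipeline
#' (even-parity filter, shuffled outgroup, neighbor joining, rooting,
#' ancestral labeling, tandem-loss accumulation, maximum-weight matching),
#' then scores recovery of the planted pattern.
#'
#' @param grid Data frame with any of the [sim_config()] fields as columns
#'   (missing ones take the defaults), one experiment per row; an `n_rep`
#'   column sets the replicates (default 20).
#' @param seed Master seed; replicate seeds are derived from it.
#' @param n_rep Default number of replicates per grid row.
#' @return Data frame: the grid plus `mean_qp` (exact-recovery fraction),
#'   `mean_rb` (bond-level recovery), and `random_qp` (closed-form chance
#'   level as a fraction, comparable to `mean_qp`).
#' @export
recovery_experiment <- function(grid, seed = 1L, n_rep = 20L) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1L)
  res <- lapply(seq_len(nrow(grid)), function(g) {
    args <- as.list(grid[g, , drop = FALSE])
    reps <- if (!is.null(args$n_rep)) args$n_rep else n_rep
    args$n_rep <- NULL
    ok <- logical(reps); rb <- numeric(reps)
    for (r in seq_len(reps)) {
      rs <- (as.integer(seed) * 1000L + g * 101L + r) %% .Machine$integer.max
      cfg <- do.call(sim_config, c(args, list(seed = rs)))
      fam <- evolve_family(cfg)
      fit <- cysbond_family(fam, seed = rs)
      ok[r] <- pattern_equal(fit$pattern, fam$bonds)
      rb[r] <- n_correct_bonds(bond_pattern(fam$bonds), fit$pattern) /
        nrow(fam$bonds)
    }
    d <- nrow(sim_config_bonds(args))
    cbind(grid[g, , drop = FALSE],
          data.frame(mean_qp = mean(ok), mean_rb = mean(rb),
                     random_qp = random_baseline(d)$qp / 100))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# resolve the bond pairs implied by a (partial) sim_config argument list
sim_config_bonds <- function(args) {
  cfg <- do.call(sim_config, c(args, list(seed = 1L)))
  cfg$bonds
}
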