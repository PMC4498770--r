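test_that("random trees are binary, seeded, and sized correctly", {
  tr <- random_tree(2, seed = 1)
  expect_equal(length(tr$tip.label), 2L)
  tr50 <- random_tree(50, seed = 2)
  expect_equal(length(tr50$tip.label), 50L)
  expect_equal(tr50$Nnode, 49L)  # rooted binary
  expect_true(all(tabulate(tr50$edge[, 1]) %in% c(0L, 2L)))
  expect_equal(write_newick(random_tree(10, seed = 7)),
               write_newick(random_tree(10, seed = 7)))
  expect_error(random_tree(1), "at least 2")
})

test_that("simulation config validates probabilities and plants bonds", {
  expect_error(sim_config(p_loss = 1.5), "\\[0, 1\\]")
  cfg <- sim_config(n_leaves = 8, bonds = 3, seq_length = 60, seed = 5)
  expect_equal(length(cfg$positions), 6L)
  expect_lte(max(cfg$positions), 60L)
  expect_error(sim_config(bonds = rbind(c(10, 200)), seq_length = 100),
               "exceed")
})

test_that("the root sequence carries cysteines exactly at planted positions", {
  fam <- evolve_family(sim_config(n_leaves = 8, bonds = 3, seed = 6))
  chars <- strsplit(fam$root_sequence, "")[[1]]
  expect_true(all(chars[fam$positions] == "C"))
  expect_false(any(chars[-fam$positions] == "C"))
  # alignment is gap-free with equal lengths
  expect_true(all(nchar(fam$alignment) == fam$config$seq_length))
  expect_false(any(grepl("-", fam$alignment, fixed = TRUE)))
})

test_that("with p_loss = 0 every leaf keeps all cysteines", {
  fam <- evolve_family(sim_config(n_leaves = 12, bonds = 2, p_loss = 0,
                                  seed = 7))
  labs <- t(vapply(fam$alignment, leaf_label, integer(4),
                   oxidized_columns = fam$positions))
  expect_true(all(labs == 1L))
  # uniform weights downstream: prediction falls to the deterministic
  # tie-break, equal to the matching of a constant graph
  fit <- cysbond_family(fam, seed = 7)
  W <- unclass(fit$graph)
  off <- W[upper.tri(W)]
  expect_equal(off, rep(off[1], length(off)))
  const <- matrix(off[1], 4, 4); diag(const) <- 0
  expect_equal(unclass(fit$pattern),
               unclass(max_weight_perfect_matching(const)),
               ignore_attr = TRUE)
})

test_that("under the loss-only model a lost cysteine never reappears", {
  for (s in 1:5) {
    fam <- evolve_family(sim_config(n_leaves = 16, bonds = 3, p_tandem = 0.5,
                                    seed = s))
    tr <- fam$tree
    parent <- integer(max(tr$edge))
    parent[tr$edge[, 2]] <- tr$edge[, 1]
    for (e in seq_len(nrow(tr$edge))) {
      par <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
      # states can only go 1 -> 0 down an edge
      expect_true(all(fam$states[ch, ] <= fam$states[par, ]))
    }
  }
})

test_that("leaf labels computed by the pipeline equal the true states", {
  for (s in 1:5) {
    fam <- evolve_family(sim_config(n_leaves = 16, bonds = 3, p_tandem = 0.7,
                                    seed = s))
    labs <- t(vapply(fam$alignment, leaf_label, integer(6),
                     oxidized_columns = fam$positions))
    expect_equal(unname(labs),
                 unname(fam$states[seq_len(16), ]), ignore_attr = TRUE)
  }
})

test_that("inferred ancestral labels match true states absent homoplasy", {
  for (s in 1:10) {
    fam <- evolve_family(sim_config(n_leaves = 12, bonds = 3, p_loss = 0.15,
                                    seed = s))
    labs <- t(vapply(fam$alignment, leaf_label, integer(6),
                     oxidized_columns = fam$positions))
    inferred <- unclass(assign_inner_labels(fam$tree, labs))
    ntip <- 12L
    # homoplasy check per cysteine: loss events (1->0 edge flips in the true
    # states) unique to one subtree mean true and inferred agree there
    tr <- fam$tree
    flips <- matrix(FALSE, nrow(fam$states), 6)
    for (e in seq_len(nrow(tr$edge))) {
      par <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
      flips[ch, ] <- fam$states[par, ] == 1L & fam$states[ch, ] == 0L
    }
    for (k in 1:6) {
      if (sum(flips[, k]) <= 1L)
        expect_equal(unname(inferred[, k]), unname(fam$states[, k]))
    }
  }
})

test_that("simulated families serialize to FASTA, Newick and truth TSV", {
  fam <- evolve_family(sim_config(n_leaves = 6, bonds = 2, seed = 9))
  dir <- tempfile()
  paths <- write_sim_family(fam, dir)
  expect_true(all(file.exists(paths)))
  msa <- read_alignment(paths["msa"], "fasta")
  expect_equal(length(msa$rows), 7L)  # query + 6 leaves
  expect_equal(msa$query_id, "query")
  tr <- read_newick(file = paths["tree"])
  expect_setequal(tr$tip.label, names(fam$alignment))
  truth <- read_bonds_tsv(paths["truth"])
  expect_equal(nrow(truth$query), 2L)
})

test_that("recovery experiments are reproducible under a fixed master seed", {
  grid <- data.frame(n_leaves = 12, bonds = 2, p_tandem = 1, n_rep = 3)
  r1 <- recovery_experiment(grid, seed = 17)
  r2 <- recovery_experiment(grid, seed = 17)
  expect_identical(r1, r2)
  expect_true(all(r1$mean_qp >= 0 & r1$mean_qp <= 1))
})

test_that("recovery improves with the strength of the tandem coupling", {
  grid <- data.frame(n_leaves = 32, bonds = 2,
                     p_tandem = c(0, 0.5, 1), n_rep = 40)
  res <- recovery_experiment(grid, seed = 19)
  # monotone on average, allowing Monte-Carlo noise at 40 replicates
  expect_lte(res$mean_qp[1], res$mean_qp[2] + 0.1)
  expect_lte(res$mean_qp[2], res$mean_qp[3] + 0.1)
  expect_gt(res$mean_qp[3], res$mean_qp[1])
})
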