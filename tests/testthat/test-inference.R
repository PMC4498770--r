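test_that("root paths prepend the all-zeros label and end at the root", {
  tr <- read_newick("((A:1,B:1):1,C:1);")
  labs <- rbind(A = c(1, 1, 1, 1), B = c(1, 1, 0, 0), C = c(0, 0, 1, 1))
  out <- assign_inner_labels(tr, labs)
  # C sits directly under the root
  pc <- root_path_labels(out, "C")
  expect_equal(nrow(pc), 3L)
  expect_equal(pc[1, ], rep(0L, 4))
  expect_equal(pc[2, ], c(0L, 0L, 1L, 1L))
  expect_equal(pc[3, ], rep(1L, 4))  # root
  # A is one level deeper: zeros, leaf, inner, root
  pa <- root_path_labels(out, "A")
  expect_equal(nrow(pa), 4L)
  expect_error(root_path_labels(out, "Z"), "not a tip")
})

test_that("successive path labels are nested by inclusion on simulated trees", {
  withr::with_seed(71, {
    for (rep in 1:5) {
      fam <- evolve_family(sim_config(n_leaves = 16, bonds = 3, seed = rep))
      labs <- t(vapply(fam$alignment, leaf_label, integer(6),
                       oxidized_columns = fam$positions))
      out <- assign_inner_labels(fam$tree, labs)
      for (leaf in fam$tree$tip.label) {
        p <- root_path_labels(out, leaf)
        for (s in seq_len(nrow(p) - 1L))
          expect_true(all(p[s, ] <= p[s + 1L, ]))
      }
    }
  })
})

test_that("label parity counts ones modulo two", {
  expect_equal(label_parity(c(0, 0, 0, 0)), "even")
  expect_equal(label_parity(c(1, 1, 1, 0)), "odd")
  expect_equal(label_parity(c(1, 1, 1, 1)), "even")
})

test_that("compare_step implements the tandem-mutation weight rules", {
  # identical labels: nothing to infer
  expect_equal(nrow(compare_step(c(1, 1, 0, 0), c(1, 1, 0, 0))), 0L)
  # single tandem pair: unit increment on that edge
  inc <- compare_step(c(1, 1, 0, 0), c(1, 1, 1, 1))
  expect_equal(inc, data.frame(i = 3L, j = 4L, w = 1))
  # mu = 4: all six pairs share the evidence, 2/(4*3) = 1/6 each
  inc4 <- compare_step(c(0, 0, 0, 0), c(1, 1, 1, 1))
  expect_equal(nrow(inc4), 6L)
  expect_equal(inc4$w, rep(1 / 6, 6))
  expect_equal(sum(inc4$w), 1)
  # odd mu (parity breaking): no contribution in the default model
  expect_equal(nrow(compare_step(c(1, 1, 1, 0), c(1, 1, 1, 1))), 0L)
  expect_error(compare_step(c(1, 0), c(1, 1, 1)), "equal length")
})

test_that("accumulated weights match a hand-traced two-leaf family", {
  tr <- read_newick("(A:1,B:1);")
  labs <- rbind(A = c(1, 1, 0, 0), B = c(0, 0, 1, 1))
  out <- assign_inner_labels(tr, labs)
  W <- unclass(accumulate_weights(out))
  # A: (0000,1100,1111) -> edge(1,2)+1 then edge(3,4)+1
  # B: (0000,0011,1111) -> edge(3,4)+1 then edge(1,2)+1
  expected <- matrix(0, 4, 4)
  expected[1, 2] <- expected[2, 1] <- 2
  expected[3, 4] <- expected[4, 3] <- 2
  expect_equal(W, expected, ignore_attr = TRUE)
  expect_equal(attr(accumulate_weights(out), "informative_steps"), 4)
})

test_that("a star of identical all-ones leaves spreads the uniform split", {
  k <- 5
  tr <- read_newick(paste0("(", paste0("L", 1:k, ":1", collapse = ","), ");"))
  nb <- 4
  labs <- matrix(1, k, nb, dimnames = list(paste0("L", 1:k), NULL))
  W <- unclass(accumulate_weights(assign_inner_labels(tr, labs)))
  off <- W[upper.tri(W)]
  expect_equal(off, rep(k * 2 / (nb * (nb - 1)), length(off)))
})

test_that("total graph weight equals the number of informative steps", {
  withr::with_seed(81, {
    for (rep in 1:8) {
      fam <- evolve_family(sim_config(n_leaves = 16, bonds = 3,
                                      p_tandem = runif(1), seed = rep))
      labs <- t(vapply(fam$alignment, leaf_label, integer(6),
                       oxidized_columns = fam$positions))
      out <- assign_inner_labels(fam$tree, labs)
      g <- accumulate_weights(out)
      W <- unclass(g)
      expect_equal(sum(W) / 2, attr(g, "informative_steps"), tolerance = 1e-9)
      expect_true(isSymmetric(W))
      expect_equal(diag(W), rep(0, 6))
      expect_true(all(W >= 0))
    }
  })
})

test_that("single-pass accumulation equals the literal per-leaf traversal", {
  withr::with_seed(91, {
    for (rep in 1:8) {
      fam <- evolve_family(sim_config(n_leaves = 20, bonds = 3,
                                      p_tandem = runif(1), seed = rep))
      labs <- t(vapply(fam$alignment, leaf_label, integer(6),
                       oxidized_columns = fam$positions))
      out <- assign_inner_labels(fam$tree, labs)
      fast <- accumulate_weights(out, method = "edges")
      slow <- accumulate_weights(out, method = "per_leaf")
      expect_equal(unclass(fast), unclass(slow), tolerance = 1e-9)
      expect_equal(attr(fast, "informative_steps"),
                   attr(slow, "informative_steps"), tolerance = 1e-9)
    }
  })
})

test_that("graph TSV export lists all candidate bonds with 1-based positions", {
  tr <- read_newick("(A:1,B:1);")
  labs <- rbind(A = c(1, 1, 0, 0), B = c(0, 0, 1, 1))
  g <- accumulate_weights(assign_inner_labels(tr, labs))
  df <- write_graph_tsv(g, positions = c(5, 14, 23, 40))
  expect_equal(nrow(df), 6L)
  expect_equal(df$weight[df$cys_i == 5 & df$cys_j == 14], 2)
  path <- tempfile(fileext = ".tsv")
  write_graph_tsv(g, positions = c(5, 14, 23, 40), path = path)
  back <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(back$weight, df$weight)
})
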