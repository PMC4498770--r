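test_that("p-distances count mismatches over comparable columns only", {
  fam <- aligned_family(c(a = "AAAA", b = "AAAT", c = "AAAA"), "a")
  D <- pairwise_distances(fam)
  expect_equal(D["a", "c"], 0)
  expect_equal(D["a", "b"], 0.25)
  expect_equal(D["b", "c"], 0.25)
  expect_true(isSymmetric(unclass(D)))
  expect_equal(diag(unclass(D)), setNames(rep(0, 3), c("a", "b", "c")))
  # gaps excluded from the comparison
  fam2 <- aligned_family(c(a = "A-CD", b = "AAC-"), "a")
  expect_equal(pairwise_distances(fam2)["a", "b"], 0)
  # no comparable columns at all -> distance 1
  fam3 <- aligned_family(c(a = "AA--", b = "--AA"), "a")
  expect_equal(pairwise_distances(fam3)["a", "b"], 1)
  expect_error(pairwise_distances(aligned_family(c(a = "AA"), "a")),
               "at least 2")
})

test_that("Kimura correction transforms p below 0.75 and caps beyond", {
  fam <- aligned_family(c(a = "AAAA", b = "AAAT"), "a")
  expect_equal(pairwise_distances(fam, "kimura")["a", "b"],
               -log(1 - 0.25 - 0.25^2 / 5))
  fam2 <- aligned_family(c(a = "AAAA", b = "TTTT"), "a")
  expect_equal(pairwise_distances(fam2, "kimura")["a", "b"], 10)
})

test_that("neighbor joining handles 2 and 3 taxa by closed forms", {
  D2 <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  tr2 <- neighbor_joining(D2)
  expect_equal(sort(tr2$tip.label), c("A", "B"))
  expect_equal(unname(tr2$edge.length), c(0.2, 0.2))

  ids <- c("A", "B", "C")
  D3 <- matrix(c(0, 0.3, 0.5, 0.3, 0, 0.6, 0.5, 0.6, 0), 3,
               dimnames = list(ids, ids))
  tr3 <- neighbor_joining(D3)
  # three-point formulas: l_A = (D_AB + D_AC - D_BC)/2
  lens <- setNames(tr3$edge.length[match(1:3, tr3$edge[, 2])], tr3$tip.label)
  expect_equal(lens[["A"]], (0.3 + 0.5 - 0.6) / 2)
  expect_equal(lens[["B"]], (0.3 + 0.6 - 0.5) / 2)
  expect_equal(lens[["C"]], (0.5 + 0.6 - 0.3) / 2)
})

test_that("NJ recovers the generating topology from additive distances", {
  withr::with_seed(11, {
    for (n in c(4, 5, 6, 8)) {
      true <- ape::rtree(n, rooted = FALSE, br = function(k) rexp(k, 5) + 0.05)
      D <- ape::cophenetic.phylo(true)
      est <- neighbor_joining(D)
      expect_equal(ape::dist.topo(ape::unroot(est), true), 0,
                   ignore_attr = TRUE)
      # independent oracle: ape's own NJ agrees on the topology
      ref <- ape::nj(D)
      expect_equal(ape::dist.topo(ape::unroot(est), ape::unroot(ref)), 0,
                   ignore_attr = TRUE)
    }
  })
})

test_that("only the generating topology fits an additive matrix exactly", {
  skip_if_not_installed("phangorn")
  withr::with_seed(21, {
    true <- ape::rtree(5, rooted = FALSE, br = function(k) rexp(k, 5) + 0.05)
    D <- ape::cophenetic.phylo(true)
    cand <- phangorn::allTrees(5, rooted = FALSE, tip.label = true$tip.label)
    rss <- vapply(cand, function(tp) {
      fit <- phangorn::nnls.tree(D, tp, method = "unrooted")
      sum((ape::cophenetic.phylo(fit)[rownames(D), colnames(D)] - D)^2)
    }, numeric(1))
    best <- which(rss < 1e-12)
    expect_length(best, 1L)
    expect_equal(ape::dist.topo(cand[[best]], true), 0, ignore_attr = TRUE)
    # and NJ returns that unique exact-fit topology
    est <- neighbor_joining(D)
    expect_equal(ape::dist.topo(ape::unroot(est), cand[[best]]), 0,
                 ignore_attr = TRUE)
  })
})

test_that("NJ rejects malformed distance matrices", {
  D <- matrix(c(0, 1, 2, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(neighbor_joining(D), "symmetric")
  D2 <- matrix(c(0, NA, NA, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(neighbor_joining(D2), "finite")
})

test_that("outgroup rooting preserves leaves and path lengths", {
  withr::with_seed(31, {
    true <- ape::rtree(8, rooted = FALSE, br = function(k) rexp(k, 5) + 0.05)
    og <- "t1"
    before <- ape::cophenetic.phylo(true)
    rooted <- root_with_outgroup(true, og, drop_outgroup = TRUE)
    expect_true(ape::is.rooted(rooted))
    expect_setequal(rooted$tip.label, setdiff(true$tip.label, og))
    after <- ape::cophenetic.phylo(rooted)
    keep <- rooted$tip.label
    expect_equal(after[keep, keep], before[keep, keep], tolerance = 1e-8)
    # rooted trees are single-rooted with >= 2 children at the root
    ntip <- length(rooted$tip.label)
    root <- ntip + 1L
    expect_false(root %in% rooted$edge[, 2])
    expect_gte(sum(rooted$edge[, 1] == root), 2)
  })
  # minimal 3-leaf case
  tr <- read_newick("(A:0.1,B:0.2,OG:0.9);")
  r <- root_with_outgroup(tr, "OG")
  expect_setequal(r$tip.label, c("A", "B"))
  expect_error(root_with_outgroup(tr, "ZZ"), "not a leaf")
})

test_that("Newick round-trips preserve topology, ids and lengths", {
  tr <- read_newick("(A:0.1,B:0.2);")
  expect_equal(length(tr$tip.label), 2L)
  expect_equal(sort(tr$edge.length), c(0.1, 0.2))
  # missing lengths default to zero
  tr0 <- read_newick("((A,B),C);")
  expect_equal(tr0$edge.length, rep(0, nrow(tr0$edge)))
  # random 50-leaf round trip
  withr::with_seed(41, {
    big <- ape::rtree(50)
    back <- read_newick(write_newick(big))
    expect_equal(ape::dist.topo(ape::unroot(back), ape::unroot(big)), 0,
                 ignore_attr = TRUE)
    expect_equal(sort(back$edge.length), sort(big$edge.length),
                 tolerance = 1e-8)
    expect_setequal(back$tip.label, big$tip.label)
  })
  expect_error(read_newick("((A,B,C);"), "parse|Newick|failed")
})
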