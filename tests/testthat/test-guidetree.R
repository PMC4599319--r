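dist_from_values <- function(vals, labels) {
  dimnames(vals) <- list(labels, labels)
  structure(list(labels = labels, values = vals, method = NULL),
            class = "dist_matrix")
}

random_tiefree_matrix <- function(n, seed, labels = sprintf("t%02d", 1:n)) {
  withr::with_seed(seed, {
    v <- matrix(0, n, n)
    # continuous draws: exact ties (also among derived averages) have
    # probability zero
    vals <- stats::runif(n * (n - 1) / 2, 0.01, 0.99)
    v[upper.tri(v)] <- vals
    v[lower.tri(v)] <- t(v)[lower.tri(v)]
    dist_from_values(v, labels)
  })
}

permute_matrix <- function(m, perm) {
  dist_from_values(m$values[perm, perm], m$labels[perm])
}

test_that("upgma reproduces a hand-traced 3-taxon tree with no ties", {
  v <- matrix(c(0, 1, 4, 1, 0, 4, 4, 4, 0), 3, 3)
  m <- dist_from_values(v, c("A", "B", "C"))
  res <- upgma(m)
  expect_length(res$tie_events, 0)
  expect_identical(to_newick(res$tree), "((A:0.5,B:0.5):1.5,C:2);")
  expect_equal(sort(tree_heights(res$tree)), c(0.5, 2))
})

test_that("an all-tied 4x4 matrix triggers a 6-pair tie event and policy-dependent merges", {
  v <- matrix(1, 4, 4); diag(v) <- 0
  m <- dist_from_values(v, c("A", "B", "C", "D"))
  ws <- testthat::capture_warnings(res <- upgma(m, policy = "input_order_first"))
  expect_true(any(grepl("potential instability", ws)))
  ev <- res$tie_events[[1]]
  expect_equal(ev$step, 1)
  expect_length(ev$tied_pairs, 6)
  expect_identical(ev$chosen, "A | B")  # first row-major pair
  res_last <- quiet_upgma(m, policy = "input_order_last")
  expect_identical(res_last$tie_events[[1]]$chosen, "C | D")
})

test_that("tie-free matrices give one tree under every policy and any input order", {
  m <- random_tiefree_matrix(8, seed = 5)
  base <- upgma(m)
  expect_length(base$tie_events, 0)
  for (pol in c("input_order_last", "lexicographic", "random")) {
    expect_true(same_topology(base$tree, upgma(m, policy = pol)$tree))
  }
  for (seed in 1:10) {
    perm <- withr::with_seed(seed, sample(8))
    pt <- upgma(permute_matrix(m, perm))
    expect_true(same_topology(base$tree, pt$tree))
    expect_equal(sort(tree_heights(pt$tree)), sort(tree_heights(base$tree)))
  }
})

test_that("upgma agrees with hclust average linkage on tie-free matrices", {
  for (seed in 1:5) {
    m <- random_tiefree_matrix(8, seed = seed)
    ours <- upgma(m)
    hc <- stats::hclust(stats::as.dist(m$values), method = "average")
    phy <- ape::as.phylo(hc)
    ref_tree <- from_newick(ape::write.tree(phy))
    expect_true(same_topology(ours$tree, ref_tree))
    # hclust heights are merge distances; our heights are half that
    expect_equal(sort(tree_heights(ours$tree)), sort(hc$height) / 2,
                 tolerance = 1e-12)
  }
})

test_that("lexicographic policy is input-order invariant even with massive ties", {
  # few possible values ==> ties guaranteed
  withr::with_seed(42, {
    v <- matrix(0, 9, 9)
    vals <- sample(c(0.2, 0.4, 0.6), 36, replace = TRUE)
    v[upper.tri(v)] <- vals
    v[lower.tri(v)] <- t(v)[lower.tri(v)]
  })
  m <- dist_from_values(v, sprintf("q%02d", 1:9))
  base <- quiet_upgma(m, policy = "lexicographic")
  expect_gt(length(base$tie_events), 0)
  for (seed in 1:10) {
    perm <- withr::with_seed(seed, sample(9))
    pt <- quiet_upgma(permute_matrix(m, perm), policy = "lexicographic")
    expect_true(same_topology(base$tree, pt$tree))
    expect_length(pt$tie_events, length(base$tie_events))
  }
})

test_that("input-order policies produce different topologies on tied matrices", {
  v <- matrix(1, 4, 4); diag(v) <- 0
  m <- dist_from_values(v, c("A", "B", "C", "D"))
  fwd <- quiet_upgma(m, policy = "input_order_first")
  rev_m <- permute_matrix(m, 4:1)
  bwd <- quiet_upgma(rev_m, policy = "input_order_first")
  expect_false(same_topology(fwd$tree, bwd$tree))
})

test_that("upgma rejects asymmetric matrices and merge heights never decrease", {
  v <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(upgma(dist_from_values(v, c("a", "b"))), "symmetric")
  for (seed in 6:9) {
    m <- random_tiefree_matrix(10, seed = seed)
    tr <- upgma(m)$tree
    # heights in merge-step order are non-decreasing
    steps <- new.env(); steps$h <- numeric(0)
    rec <- function(node) {
      if (node$leaf) return(invisible())
      steps$h[node$step] <- node$height
      rec(node$children[[1]]); rec(node$children[[2]])
    }
    rec(tr$root)
    expect_true(all(diff(steps$h) >= -1e-12))
  }
})

test_that("chained_tree is the input-order caterpillar", {
  s <- seq_set(c("a", "b", "c"), c("AAA", "CCC", "DDD"))
  t3 <- chained_tree(s)
  expect_identical(to_newick(t3), "((a:1,b:1):1,c:2);")
  n <- 12
  sn <- random_seq_set(n, 10, seed = 2)
  tn <- chained_tree(sn)
  depth <- function(node) {
    if (node$leaf) return(0L)
    1L + max(depth(node$children[[1]]), depth(node$children[[2]]))
  }
  expect_equal(depth(tn$root), n - 1)
  trev <- chained_tree(reverse_order(sn))
  expect_false(same_topology(tn, trev))
})

test_that("newick serialization round-trips and quotes awkward labels", {
  m <- random_tiefree_matrix(7, seed = 11)
  tr <- upgma(m)$tree
  back <- from_newick(to_newick(tr))
  expect_true(same_topology(tr, back))
  expect_equal(sort(tree_heights(back)), sort(tree_heights(tr)),
               tolerance = 1e-6)
  m2 <- random_tiefree_matrix(3, seed = 12, labels = c("sp one", "sp two", "x"))
  nk <- to_newick(upgma(m2)$tree)
  expect_match(nk, "'sp one'", fixed = TRUE)
  expect_true(same_topology(upgma(m2)$tree, from_newick(nk)))
})

test_that("same_topology ignores child order and heights but not shape", {
  t1 <- from_newick("((a:1,b:1):1,c:2);")
  t2 <- from_newick("(c:5,(b:2,a:2):3);")
  t3 <- from_newick("((a:1,c:1):1,b:2);")
  expect_true(same_topology(t1, t1))
  expect_true(same_topology(t1, t2))
  expect_false(same_topology(t1, t3))
  t4 <- from_newick("((a:1,b:1):1,d:2);")
  expect_error(same_topology(t1, t4), "leaf sets")
})
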