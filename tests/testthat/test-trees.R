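# Neighbor joining ------------------------------------------------------------

test_that("NJ recovers additive distances exactly and is deterministic", {
  set.seed(51)
  tr <- ape::rtree(7)
  d <- ape::cophenetic.phylo(tr)
  nj1 <- nj_tree(d)
  expect_equal(rf_distance(nj1, tr), 0)
  # branch lengths on additive input are recovered too
  expect_equal(sort(ape::cophenetic.phylo(nj1)[rownames(d), colnames(d)]),
               sort(d), tolerance = 1e-8)
  expect_identical(ape::write.tree(nj_tree(d)), ape::write.tree(nj1))
})

test_that("three-taxon trees use the three-point formulas", {
  d <- matrix(c(0, 2, 3, 2, 0, 5, 3, 5, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  expect_equal(sort(tr$tip.label), c("a", "b", "c"))
  el <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(el[c("a", "b", "c")]), c(0, 2, 3))
})

test_that("JC correction errors on saturated pairs, naming them", {
  aln <- rbind(a = c(0, 0, 0, 0), b = c(1, 1, 1, 0), c = c(1, 0, 1, 1))
  expect_error(nj_tree(aln), "a - b")
})

test_that("alignment input goes through JC-corrected p-distances", {
  m <- quartet_model()
  g <- simulate_genome(m, n_windows = 60, window_len = 5000, seed = 53)
  aln <- t(haplotypes(g))
  tr <- nj_tree(aln, n_invariant = g$length - ncol(aln))
  expect_equal(rf_distance(tr, ape::unroot(m$tree)), 0)
})

# Bootstrap -------------------------------------------------------------------

test_that("bootstrap replicates are seeded and B = 0 gives an empty set", {
  m <- quartet_model()
  g <- simulate_genome(m, n_windows = 50, window_len = 5000, seed = 57)
  aln <- t(haplotypes(g))
  ninv <- g$length - ncol(aln)
  b1 <- bootstrap_trees(aln, B = 20, seed = 1, n_invariant = ninv)
  b2 <- bootstrap_trees(aln, B = 20, seed = 1, n_invariant = ninv)
  expect_identical(vapply(b1$trees, ape::write.tree, ""),
                   vapply(b2$trees, ape::write.tree, ""))
  expect_equal(length(bootstrap_trees(aln, B = 0)), 0)
  # strong signal: the species split has high support
  cf <- clade_frequencies(b1)
  expect_gte(cf$freq[cf$clade == "P1,P2"], 0.95)
})

# Clade frequencies and consensus ----------------------------------------------

test_that("clade frequencies equal brute-force enumeration", {
  set.seed(59)
  trees <- tree_set(lapply(1:40, function(i) ape::rtree(6)))
  cf <- clade_frequencies(trees)
  # oracle: per-tree split enumeration from the edge matrix
  keys <- unlist(lapply(trees$trees, function(t)
    gsub("\\|", ",", oracle_splits(t, sort(t$tip.label)))))
  tab <- table(keys) / 40
  expect_equal(nrow(cf), length(tab))
  expect_equal(cf$freq[match(names(tab), cf$clade)], unname(as.numeric(tab)))
  expect_true(all(cf$freq >= 0 & cf$freq <= 1))
})

test_that("identical trees give a consensus equal to the input with support 1", {
  tr <- ape::read.tree(text = "((a,b),((c,d),e));")
  cons <- consensus_tree(tree_set(rep(list(tr), 10)))
  expect_equal(rf_distance(cons, tr), 0)
  sup <- as.numeric(cons$node.label[cons$node.label != ""])
  expect_true(all(sup == 1))
})

test_that("consensus keeps the majority split with its frequency as support", {
  t1 <- ape::read.tree(text = "((A,B),(C,D),E);")
  t2 <- ape::read.tree(text = "((A,C),(B,D),E);")
  cons <- consensus_tree(tree_set(c(rep(list(t1), 7), rep(list(t2), 3))))
  cf <- clade_frequencies(tree_set(c(rep(list(t1), 7), rep(list(t2), 3))))
  # the A,B | C,D,E split (frequency 0.7) must be in the consensus
  expect_equal(rf_distance(cons, t1), 0)
  sup <- as.numeric(cons$node.label[cons$node.label != ""])
  expect_true(all(sort(sup) == sort(cf$freq[cf$freq > 0.5])))
})

test_that("consensus is exactly the greedy compatible prefix of sorted splits", {
  set.seed(61)
  trees <- tree_set(lapply(1:30, function(i) ape::rtree(6)))
  cons <- consensus_tree(trees)
  cf <- clade_frequencies(trees)
  # oracle: greedy scan over the sorted split list
  accepted <- list()
  for (i in seq_len(nrow(cf))) {
    cl <- strsplit(cf$clade[i], ",")[[1]]
    ok <- all(vapply(accepted, function(a) {
      ov <- length(intersect(a, cl))
      ov == 0 || ov == length(cl) || ov == length(a)
    }, logical(1)))
    if (ok) accepted[[length(accepted) + 1]] <- cl
  }
  got <- .bip_keys_for_test(cons)
  want <- sort(vapply(accepted, function(cl) paste(sort(cl), collapse = ","), ""))
  expect_setequal(got, want)
})

# Robinson-Foulds --------------------------------------------------------------

test_that("RF distance is a metric matching brute-force split comparison", {
  set.seed(63)
  trees <- lapply(1:40, function(i) ape::rtree(6))
  for (k in 1:60) {
    i <- sample(40, 1); j <- sample(40, 1)
    expect_equal(rf_distance(trees[[i]], trees[[j]]),
                 oracle_rf(trees[[i]], trees[[j]]))
  }
  expect_equal(rf_distance(trees[[1]], trees[[1]]), 0)
  # symmetry and triangle inequality on random triples
  for (k in 1:20) {
    idx <- sample(40, 3)
    d12 <- rf_distance(trees[[idx[1]]], trees[[idx[2]]])
    d21 <- rf_distance(trees[[idx[2]]], trees[[idx[1]]])
    d13 <- rf_distance(trees[[idx[1]]], trees[[idx[3]]])
    d23 <- rf_distance(trees[[idx[2]]], trees[[idx[3]]])
    expect_equal(d12, d21)
    expect_lte(d13, d12 + d23)
  }
  # bound 2(n - 3) for binary trees, and cross-check against phangorn
  n <- 6
  rfs <- outer(1:10, 1:10, Vectorize(function(i, j)
    rf_distance(trees[[i]], trees[[j]])))
  expect_true(all(rfs <= 2 * (n - 3)))
  ph <- as.matrix(phangorn::RF.dist(structure(trees[1:10], class = "multiPhylo")))
  expect_equal(unname(rfs), unname(ph))
  expect_error(rf_distance(trees[[1]], ape::rtree(5)), "leaf sets")
})

# STAR --------------------------------------------------------------------------

test_that("STAR recovers the species topology from concordant gene trees", {
  m <- example_species_tree(6)
  g <- simulate_genome(m, n_windows = 200, window_len = 2000, seed = 65,
                       trees = TRUE)
  st <- star_species_tree(g$trees, "O")
  expect_equal(rf_distance(ape::unroot(st), ape::unroot(m$tree)), 0)
  # invariance to gene-tree input order
  perm <- sample(length(g$trees$trees))
  st2 <- star_species_tree(tree_set(g$trees$trees[perm]), "O")
  expect_identical(ape::write.tree(st2), ape::write.tree(st))
  # trees missing the outgroup are skipped with a count
  dropped <- ape::drop.tip(g$trees$trees[[1]], "O")
  st3 <- star_species_tree(tree_set(c(list(dropped), g$trees$trees[-1])), "O")
  expect_equal(attr(st3, "n_skipped"), 1)
})

test_that("STAR handles the two-taxa-plus-outgroup degenerate case", {
  m <- species_tree_model("((P1:20000,P2:20000):20000,O:40000);",
                          Ne = 1e4, mu = 1e-8, outgroup = "O")
  g <- simulate_genome(m, n_windows = 30, window_len = 2000, seed = 67,
                       trees = TRUE)
  st <- star_species_tree(g$trees, "O")
  expect_setequal(st$tip.label, c("P1", "P2", "O"))
})
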