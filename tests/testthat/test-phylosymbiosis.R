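# UPGMA, Robinson-Foulds congruence, the randomized-topology null, and
# Mantel correlation with patristic distance.

dm_from <- function(m, labels) {
  dimnames(m) <- list(labels, labels)
  distance_matrix(m)
}

test_that("UPGMA reproduces hand-executed average linkage", {
  # two points: a cherry with both tips at height d/2
  d2 <- dm_from(matrix(c(0, 6, 6, 0), 2), c("a", "b"))
  tr2 <- upgma(d2)
  expect_equal(sort(ape::node.depth.edgelength(tr2)[1:2]), c(3, 3))
  # three points: (a,b) merge at 2 -> height 1; c joins at 8 -> height 4
  d3 <- dm_from(matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3), c("a", "b", "c"))
  tr3 <- upgma(d3)
  cop <- ape::cophenetic.phylo(tr3)
  expect_equal(cop["a", "b"], 2)
  expect_equal(cop["a", "c"], 8)
  expect_equal(max(ape::node.depth.edgelength(tr3)), 4)
  # ultrametric input is reproduced exactly
  expect_equal(cop[c("a", "b", "c"), c("a", "b", "c")], unclass(d3),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("UPGMA matches the naive O(n^3) linkage oracle", {
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(4:8, 1)
    pts <- matrix(rnorm(n * 3), n)
    d <- as.matrix(dist(pts))
    dimnames(d) <- list(sprintf("x%d", 1:n), sprintf("x%d", 1:n))
    tr <- upgma(distance_matrix(d))
    expect_true(ape::is.ultrametric(tr, tol = 1e-9))
    cop <- ape::cophenetic.phylo(tr)[rownames(d), rownames(d)]
    expect_equal(cop, oracle_upgma_cophenetic(d), tolerance = 1e-9)
  }
})

test_that("tied merges resolve identically regardless of input order", {
  d <- matrix(4, 4, 4); diag(d) <- 0
  d[1, 2] <- d[2, 1] <- 1; d[3, 4] <- d[4, 3] <- 1   # two equal-height cherries
  t1 <- upgma(dm_from(d, c("a", "b", "c", "d")))
  perm <- c(3, 1, 4, 2)
  t2 <- upgma(dm_from(d[perm, perm], c("a", "b", "c", "d")[perm]))
  expect_equal(ape::cophenetic.phylo(t1)[letters[1:4], letters[1:4]],
               ape::cophenetic.phylo(t2)[letters[1:4], letters[1:4]])
})

test_that("Robinson-Foulds counts unshared splits, normalized to [0,1]", {
  ta <- read_newick(text = "((a,b),(c,d));")
  tb <- read_newick(text = "((a,c),(b,d));")
  expect_equal(robinson_foulds(ta, ta), 0)
  expect_equal(robinson_foulds(ta, tb), 1)
  expect_equal(robinson_foulds(ta, tb, normalized = FALSE), 2)
  star <- read_newick(text = "(a,b,c,d);")
  expect_equal(robinson_foulds(star, ta), 1)  # 0 shared of 0 + 1 splits
  tc <- read_newick(text = "((a,b),(c,e));")
  expect_error(robinson_foulds(ta, tc), "d|e")
})

test_that("RF is a metric and matches oracles on random trees", {
  set.seed(31)
  trees <- replicate(12, ape::rtree(8, tip.label = sprintf("t%d", 1:8)),
                     simplify = FALSE)
  for (i in 1:11) {
    t1 <- trees[[i]]; t2 <- trees[[i + 1]]
    expect_equal(robinson_foulds(t1, t2), oracle_rf(t1, t2), tolerance = 1e-12)
    expect_equal(robinson_foulds(t1, t2), robinson_foulds(t2, t1))
  }
  skip_if_not_installed("phangorn")
  for (i in 1:11) {
    expect_equal(robinson_foulds(trees[[i]], trees[[i + 1]], normalized = FALSE),
                 phangorn::RF.dist(trees[[i]], trees[[i + 1]]))
  }
  # triangle inequality over a sample of triples
  for (k in 1:10) {
    tri <- sample(trees, 3)
    expect_lte(robinson_foulds(tri[[1]], tri[[3]]),
               robinson_foulds(tri[[1]], tri[[2]]) +
                 robinson_foulds(tri[[2]], tri[[3]]) + 1e-12)
  }
})

test_that("random topologies preserve tips and respect the seed", {
  labs <- sprintf("sp%02d", 1:15)
  t1 <- random_topology(labs, seed = 4)
  expect_setequal(t1$tip.label, labs)
  expect_true(ape::is.binary(t1))
  expect_true(ape::all.equal.phylo(t1, random_topology(labs, seed = 4)))
  expect_error(random_topology(c("a", "b")), "3")
})

test_that("RF randomization test: identical trees give the minimal p", {
  labs <- sprintf("sp%02d", 1:15)
  host <- random_topology(labs, seed = 1)
  res <- rf_randomization_test(host, host, n_null = 200, seed = 2)
  expect_equal(res$observed_rf, 0)
  expect_equal(res$p_value, 1 / 201)
  expect_length(res$null_rf, 200)
  expect_error(rf_randomization_test(host, host, n_null = 0), "n_null")
})

test_that("most random 15-tip trees share no splits with a fixed tree", {
  labs <- sprintf("sp%02d", 1:15)
  host <- random_topology(labs, seed = 9)
  set.seed(10)
  nulls <- replicate(400, robinson_foulds(host, random_topology(labs)))
  expect_gt(mean(nulls), 0.9)
})

test_that("patristic distances sum branch lengths along tip paths", {
  expect_equal(patristic_distances(read_newick(text = "(a:1,b:2);"))["a", "b"], 3)
  pat <- patristic_distances(read_newick(text = "((a:1,b:1):2,c:4);"))
  expect_equal(pat["a", "c"], 7)
  expect_equal(pat["a", "b"], 2)
  # ultrametric: d(i,j) = 2 * height of the MRCA
  tr <- simulate_yule_tree(6, seed = 3)
  pat2 <- patristic_distances(tr)
  depths <- ape::node.depth.edgelength(tr)
  for (pair in list(c(1, 2), c(2, 5), c(3, 6))) {
    mrca <- ape::getMRCA(tr, pair)
    expect_equal(pat2[pair[1], pair[2]], 2 * (max(depths) - depths[mrca]),
                 tolerance = 1e-9)
  }
})

test_that("Mantel r is the Pearson correlation of off-diagonal distances", {
  set.seed(12)
  d1 <- as.matrix(dist(matrix(rnorm(20), 10)))
  labs <- sprintf("s%d", 1:10)
  dimnames(d1) <- list(labs, labs)
  m1 <- distance_matrix(d1)
  expect_equal(mantel_test(m1, m1, 99, 1)$r, 1, tolerance = 1e-12)
  m_aff <- distance_matrix(dm_from(3 * d1 + 0.5 * (1 - diag(10)), labs))
  expect_equal(mantel_test(m1, m_aff, 99, 1)$r, 1, tolerance = 1e-12)
  # label alignment: permuting one matrix's label order changes nothing
  perm <- sample(10)
  m_perm <- distance_matrix(d1[perm, perm])
  expect_equal(mantel_test(m1, m_perm, 99, 1)$r, 1, tolerance = 1e-12)
  # mismatched label sets
  d2 <- d1; rownames(d2)[1] <- colnames(d2)[1] <- "other"
  expect_error(mantel_test(m1, distance_matrix(d2), 99, 1), "other")
})
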