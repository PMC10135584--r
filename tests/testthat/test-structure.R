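# --- LD pruning ---------------------------------------------------------

test_that("duplicated and perfectly correlated loci are pruned greedily", {
  set.seed(4)
  base <- rbinom(40, 2, 0.5)
  d <- cbind(a = base, b = base, c = base,
             d = rbinom(40, 2, 0.5))
  g <- toy_genotypes(d)
  pr <- ld_prune(g, window = 10, step = 5, r2 = 0.2)
  # one survivor of the correlated triple (the first), plus the free locus
  expect_equal(pr$kept_locus_ids, c("L1", "L4"))
})

test_that("independent loci are essentially untouched", {
  set.seed(8)
  d <- matrix(rbinom(100 * 500, 2, 0.5), 100, 500)
  g <- toy_genotypes(d)
  pr <- ld_prune(g, window = 50, step = 5, r2 = 0.2)
  expect_gt(length(pr$kept_locus_ids) / 500, 0.95)
})

test_that("pruning respects linkage-group boundaries", {
  set.seed(5)
  base <- rbinom(30, 2, 0.5)
  # identical columns on different LGs must both survive
  g <- toy_genotypes(cbind(a = base, b = base), lg = c("LG1", "LG2"),
                     pos = c(1000L, 1000L))
  expect_equal(ld_prune(g, window = 10, step = 5, r2 = 0.2)$kept_locus_ids,
               c("L1", "L2"))
})

# --- PCA ----------------------------------------------------------------

test_that("leading component separates fixed-difference clusters", {
  set.seed(12)
  d <- rbind(matrix(rbinom(10 * 100, 2, 0.05), 10, 100),
             matrix(rbinom(10 * 100, 2, 0.95), 10, 100))
  g <- toy_genotypes(d)
  pc <- pca_genotypes(g)
  s1 <- pc$scores[1:10, 1]; s2 <- pc$scores[11:20, 1]
  gap <- abs(mean(s1) - mean(s2))
  spread <- max(stats::sd(s1), stats::sd(s2))
  expect_gt(gap, 3 * spread)
  expect_true(all(diff(pc$explained_fraction) <= 1e-12))
  expect_lte(sum(pc$explained_fraction), 1 + 1e-12)
})

test_that("duplicated samples receive identical scores and sample order
           only permutes rows", {
  set.seed(13)
  d <- matrix(rbinom(8 * 60, 2, 0.4), 8, 60)
  d[8, ] <- d[1, ]
  g <- toy_genotypes(d)
  pc <- pca_genotypes(g)
  expect_equal(pc$scores[8, ], pc$scores[1, ])
  perm <- sample(8)
  pc2 <- pca_genotypes(subset_genotypes(g, samples = perm))
  expect_equal(abs(pc2$scores[, 1:3]),
               abs(pc$scores[perm, 1:3]), tolerance = 1e-8)
})

# --- p-distance ---------------------------------------------------------

test_that("p-distance follows the allele-difference definition", {
  g <- toy_genotypes(rbind(s1 = c(0L, 1L, 2L), s2 = c(2L, 1L, 0L),
                           s3 = c(0L, 1L, 2L)))
  expect_equal(p_distance(g, 1, 3), 0)
  expect_equal(p_distance(g, 1, 2), 2 / 3)
  g2 <- toy_genotypes(rbind(s1 = rep(0L, 4), s2 = rep(2L, 4)))
  expect_equal(p_distance(g2, 1, 2), 1)
  # matrix agrees with pairwise calls and handles missing data
  set.seed(3)
  d <- matrix(sample(c(0:2, NA), 6 * 50, replace = TRUE,
                     prob = c(.3, .3, .3, .1)), 6, 50)
  g3 <- toy_genotypes(d)
  m <- p_distance_matrix(g3)
  for (i in 1:5) for (j in (i + 1):6)
    expect_equal(m[i, j], p_distance(g3, i, j))
})

test_that("p-distance is a metric on complete data", {
  set.seed(21)
  for (rep in 1:5) {
    d <- matrix(sample(0:2, 7 * 40, replace = TRUE), 7, 40)
    m <- p_distance_matrix(toy_genotypes(d))
    expect_equal(m, t(m))
    expect_true(all(diag(m) == 0))
    for (i in 1:7) for (j in 1:7) for (k in 1:7)
      expect_lte(m[i, j], m[i, k] + m[k, j] + 1e-12)
  }
})

# --- neighbor joining ---------------------------------------------------

test_that("NJ recovers a 4-taxon additive tree exactly", {
  # tree ((A:1,B:2):1,(C:3,D:4)) -> additive distances
  d <- matrix(0, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                       c("A", "B", "C", "D")))
  d["A", "B"] <- 3; d["A", "C"] <- 5; d["A", "D"] <- 6
  d["B", "C"] <- 6; d["B", "D"] <- 7; d["C", "D"] <- 7
  d <- d + t(d)
  tr <- nj_tree(d)
  ref <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):0);")
  expect_equal(ape::dist.topo(ape::unroot(tr$phylo), ape::unroot(ref)), 0,
               ignore_attr = TRUE)
  expect_equal(ape::cophenetic.phylo(tr$phylo)[rownames(d), colnames(d)],
               d, tolerance = 1e-9)
})

test_that("3 and 2 taxa reduce to the closed forms", {
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr3 <- nj_tree(d3)
  co <- ape::cophenetic.phylo(tr3$phylo)
  expect_equal(co[c("A", "B", "C"), c("A", "B", "C")], d3,
               tolerance = 1e-9)
  edge_len <- stats::setNames(
    tr3$phylo$edge.length, tr3$phylo$tip.label[tr3$phylo$edge[, 2]])
  expect_equal(edge_len[c("A", "B", "C")], c(A = 1, B = 2, C = 3))

  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, 2,
               dimnames = list(c("x", "y"), c("x", "y")))
  tr2 <- nj_tree(d2)
  expect_equal(ape::cophenetic.phylo(tr2$phylo)["x", "y"], 0.4)
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("NJ reconstructs random additive trees", {
  set.seed(17)
  for (rep in 1:10) {
    nt <- sample(4:8, 1)
    ref <- ape::rtree(nt, br = function(n) runif(n, 0.1, 2))
    d <- ape::cophenetic.phylo(ref)
    tr <- nj_tree(d)
    expect_equal(ape::dist.topo(ape::unroot(tr$phylo), ape::unroot(ref)),
                 0, ignore_attr = TRUE)
    expect_equal(ape::cophenetic.phylo(tr$phylo)[rownames(d), colnames(d)],
                 d, tolerance = 1e-8)
  }
})

test_that("bootstrap supports are deterministic and certain for clear
           clusters", {
  set.seed(14)
  d <- rbind(matrix(rbinom(8 * 200, 2, 0.1), 8, 200),
             matrix(rbinom(8 * 200, 2, 0.9), 8, 200))
  rownames(d) <- c(paste0("a", 1:8), paste0("b", 1:8))
  g <- toy_genotypes(d)
  bt <- nj_bootstrap(g, n_boot = 100, seed = 6)
  key <- paste(sort(paste0("b", 1:8)), collapse = "|")
  expect_true(key %in% names(bt$support))
  expect_gte(bt$support[[key]], 0.99)
  bt2 <- nj_bootstrap(g, n_boot = 100, seed = 6)
  expect_identical(bt$support, bt2$support)
  b1 <- nj_bootstrap(g, n_boot = 1, seed = 2)
  expect_true(all(b1$support %in% c(0, 1)))
})
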