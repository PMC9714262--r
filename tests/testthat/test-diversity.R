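test_that("clr_transform matches the definition", {
  m <- matrix(c(1, 2, 4, 5, 5, 5, 0, 3, 1), nrow = 3,
              dimnames = list(c("a", "b", "c"), c("S1", "S2", "S3")))
  tb <- taxa_table(m, "bacteria")

  # tiny pseudocount approximates the zero-free limit: (1,2,4) -> (-ln2,0,ln2)
  x <- clr_transform(taxa_table(m[, 1:2, drop = FALSE], "bacteria"), 1e-9)
  expect_equal(unname(x[, "S1"]), c(-log(2), 0, log(2)), tolerance = 1e-6)
  # uniform column -> all zeros
  expect_equal(unname(x[, "S2"]), c(0, 0, 0), tolerance = 1e-12)

  # hand evaluation with zeros and pseudocount 1: column (0,3) -> (-ln2, ln2)
  m2 <- matrix(c(0, 3, 1, 1), nrow = 2,
               dimnames = list(c("a", "b"), c("S1", "S2")))
  y <- clr_transform(taxa_table(m2, "bacteria"), 1)
  expect_equal(unname(y[, "S1"]), c(-log(2), log(2)))

  # every column sums to zero
  full <- clr_transform(tb, 1)
  expect_lt(max(abs(colSums(full))), 1e-9)

  expect_error(clr_transform(tb, 0), "pseudocount")
  expect_error(clr_transform(tb, -1), "pseudocount")
})

test_that("aitchison distance is scale-invariant on zero-free data", {
  set.seed(1)
  m <- matrix(rpois(30, 20) + 1, nrow = 5,
              dimnames = list(paste0("t", 1:5), paste0("S", 1:6)))
  tb <- taxa_table(m, "bacteria")
  d1 <- beta_diversity(tb, "aitchison", pseudocount = 1e-9)
  m2 <- m; m2[, 3] <- m[, 3] * 7    # depth rescaling of one sample
  d2 <- beta_diversity(taxa_table(m2, "bacteria"), "aitchison",
                       pseudocount = 1e-9)
  expect_equal(d1$values, d2$values, tolerance = 1e-6)
  expect_true(isSymmetric(d1$values))
  expect_equal(unname(diag(d1$values)), rep(0, 6))
})

test_that("alpha diversity closed forms hold", {
  m <- matrix(c(1, 1, 1, 1,   4, 0, 0, 0,   2, 1, 1, 0), nrow = 4,
              dimnames = list(paste0("t", 1:4), c("uniform", "single", "mix")))
  tb <- taxa_table(m, "bacteria")
  sh <- alpha_diversity(tb, "shannon")
  si <- alpha_diversity(tb, "simpson")
  expect_equal(unname(sh["uniform"]), log(4))
  expect_equal(unname(si["uniform"]), 0.75)
  expect_equal(unname(sh["single"]), 0)
  expect_equal(unname(si["single"]), 0)
  # proportions (0.5, 0.25, 0.25) -> 1.5 ln 2
  expect_equal(unname(sh["mix"]), 1.5 * log(2))
  # Shannon is maximal iff uniform; Simpson <= 1 - 1/S
  set.seed(2)
  for (i in 1:20) {
    p <- as.matrix(rmultinom(1, 100, runif(4)))
    rownames(p) <- paste0("t", 1:4); colnames(p) <- "x"
    tt <- taxa_table(cbind(p, uniform = rep(25, 4)), "bacteria")
    a <- alpha_diversity(tt, "shannon")
    expect_lte(a[["x"]], a[["uniform"]] + 1e-12)
    expect_lte(alpha_diversity(tt, "simpson")[["x"]], 1 - 1/4 + 1e-12)
  }
  expect_error(alpha_diversity(tb, "chao1"))
})

test_that("bray-curtis matches its definition and bounds", {
  m <- matrix(c(1, 0, 0, 1, 2, 2), nrow = 2,
              dimnames = list(c("a", "b"), c("S1", "S2", "S3")))
  d <- beta_diversity(taxa_table(m, "fungi"), "bray_curtis")
  expect_equal(d$values["S1", "S2"], 1)           # disjoint
  expect_equal(d$values["S3", "S3"], 0)
  expect_equal(d$values["S1", "S3"], 0.5)         # (1,0) vs (.5,.5)
  expect_true(all(d$values >= 0 & d$values <= 1))
})

test_that("unweighted unifrac matches hand computation and bounds", {
  tree <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1):0;")
  m <- matrix(c(1, 1, 0, 0,
                0, 0, 1, 1,
                1, 0, 1, 0,
                1, 1, 0, 0), nrow = 4,
              dimnames = list(c("a", "b", "c", "d"),
                              c("AB", "CD", "AC", "AB2")))
  tb <- taxa_table(m, "fungi")
  d <- beta_diversity(tb, "unweighted_unifrac", tree = tree)
  # disjoint clades share no branches
  expect_equal(d$values["AB", "CD"], 1)
  # identical presence sets
  expect_equal(d$values["AB", "AB2"], 0)
  # AB = {a,b}: edges a,b,(ab); AC = {a,c}: edges a,(ab),c,(cd)
  # shared = a + (ab) = 2; union = 5; unshared = 3
  expect_equal(d$values["AB", "AC"], 3 / 5)
  expect_true(all(d$values >= 0 & d$values <= 1))
  expect_true(isSymmetric(d$values))

  # taxa with nonzero counts missing from the tree are named
  m_bad <- rbind(m, zz = c(1, 0, 0, 0))
  expect_error(beta_diversity(taxa_table(m_bad, "fungi"),
                              "unweighted_unifrac", tree = tree), "zz")
})

test_that("unweighted unifrac agrees with phyloseq on a random instance", {
  skip_if_not_installed("phyloseq")
  set.seed(31)
  tree <- ape::rtree(12)
  tree$tip.label <- paste0("t", 1:12)
  m <- matrix(rbinom(12 * 8, 1, 0.6) * rpois(12 * 8, 5), nrow = 12,
              dimnames = list(paste0("t", 1:12), paste0("S", 1:8)))
  m[, colSums(m) == 0] <- 1   # guard against empty samples
  d <- beta_diversity(taxa_table(m, "bacteria"), "unweighted_unifrac",
                      tree = tree)
  ps <- phyloseq::phyloseq(phyloseq::otu_table(m, taxa_are_rows = TRUE),
                           ape::multi2di(tree))
  ref <- as.matrix(phyloseq::UniFrac(ps, weighted = FALSE))
  expect_equal(d$values, ref[d$sample_ids, d$sample_ids], tolerance = 1e-10)
})

test_that("pcoa embeds Euclidean distances exactly and matches cmdscale", {
  set.seed(4)
  pts <- matrix(rnorm(8), ncol = 2)
  rownames(pts) <- paste0("S", 1:4)
  D <- as.matrix(dist(pts))
  ord <- pcoa(as_distmat(D))
  expect_lt(max(abs(as.matrix(dist(ord$coordinates)) - D)), 1e-8)
  # axes ordered by non-increasing eigenvalue, proportions valid
  expect_true(all(diff(ord$eigenvalues) <= 1e-12))
  expect_true(all(ord$proportion_explained >= 0 &
                    ord$proportion_explained <= 1))
  expect_lte(sum(ord$proportion_explained), 1 + 1e-12)
  # oracle: classical MDS
  ref <- cmdscale(D, k = 2)
  expect_equal(abs(ord$coordinates[, 1:2]), abs(ref), ignore_attr = TRUE,
               tolerance = 1e-8)

  # equidistant points: n-1 equal positive eigenvalues
  De <- matrix(1, 5, 5) - diag(5)
  rownames(De) <- colnames(De) <- paste0("S", 1:5)
  orde <- pcoa(as_distmat(De))
  expect_length(orde$eigenvalues, 4)
  expect_lt(diff(range(orde$eigenvalues)), 1e-10)

  expect_error(pcoa(as_distmat(matrix(c(0, 1, 2, 0), 2,
                                      dimnames = list(c("a","b"), c("a","b"))))),
               "at least 3")
  Dasym <- D; Dasym[1, 2] <- Dasym[1, 2] + 1
  expect_error(pcoa(as_distmat(Dasym)), "symmetric")
})

test_that("pcoa on aitchison distances reproduces the matrix (no negative axes)", {
  co <- null_cohort(12, n_bact = 8, n_fung = 5, depth = 1000, seed = 8)
  d <- beta_diversity(co$bacteria, "aitchison")
  ord <- pcoa(d)
  expect_equal(ord$negative_eigenvalue_sum, 0, tolerance = 1e-6)
  rec <- as.matrix(dist(ord$coordinates))
  expect_lt(max(abs(rec - d$values)), 1e-8)
})
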