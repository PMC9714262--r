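test_that("prevalence filter boundary is inclusive at 'at least 30%'", {
  m <- matrix(0, nrow = 3, ncol = 10,
              dimnames = list(c("keep3", "drop2", "keep10"), paste0("S", 1:10)))
  m["keep3", 1:3] <- 5        # 3 of 10 = exactly 30%
  m["drop2", 1:2] <- 5        # 2 of 10
  m["keep10", ] <- 1
  tb <- taxa_table(m, "bacteria")
  expect_message(f <- prevalence_filter(tb, 0.30), "dropped 1")
  expect_identical(f$taxa_ids, c("keep3", "keep10"))

  # threshold 1 keeps only ubiquitous taxa; threshold 0 is rejected
  f1 <- suppressMessages(prevalence_filter(tb, 1))
  expect_identical(f1$taxa_ids, "keep10")
  expect_error(prevalence_filter(tb, 0), "min_prevalence")
  expect_error(suppressMessages(
    prevalence_filter(taxa_table(m[1:2, , drop = FALSE] * 0 + 0, "bacteria"),
                      0.3)))
})

test_that("spearman_edge handles perfect monotone cases and exact enumeration", {
  x <- 1:10
  expect_equal(spearman_edge(x, x^3 + 2)[["rho"]], 1)
  expect_equal(spearman_edge(x, x^3)[["p"]], 0)
  expect_equal(spearman_edge(1:5, 5:1)[["rho"]], -1)

  # frozen enumeration case: rho = 0.6, p = 10/24 over all 4! rankings
  e <- spearman_edge(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(e[["rho"]], 0.6)
  expect_equal(e[["p"]], 10 / 24)

  # oracle: independent full enumeration at n = 5
  set.seed(41)
  x5 <- rnorm(5); y5 <- rnorm(5)
  obs <- spearman_edge(x5, y5)
  rhos <- vapply(oracle_permutations(5),
                 function(p) cor(rank(x5), rank(y5)[p]), numeric(1))
  expect_equal(obs[["p"]], mean(abs(rhos) >= abs(obs[["rho"]]) - 1e-12))

  # large-n t approximation matches cor.test's asymptotic p
  set.seed(42)
  x30 <- rnorm(30); y30 <- x30 + rnorm(30)
  e30 <- spearman_edge(x30, y30)
  ref <- cor.test(x30, y30, method = "spearman", exact = FALSE)
  expect_equal(e30[["rho"]], unname(ref$estimate), tolerance = 1e-12)
  expect_equal(e30[["p"]], ref$p.value, tolerance = 1e-9)

  expect_error(spearman_edge(rep(1, 10), 1:10), "constant")
  expect_error(spearman_edge(1:3, 3:1), "at least 4")
})

test_that("build_network edges, signs, and connectedness are definitionally exact", {
  set.seed(43)
  co <- null_cohort(50, n_bact = 10, n_fung = 8, depth = 3000, seed = 17)
  bact <- co$bacteria; fung <- co$fungi
  # plant two deterministic monotone relationships on the count scale
  fung$counts["fung001", ] <- bact$counts["bact001", ] * 2 + 1
  fung$counts["fung002", ] <- max(bact$counts["bact002", ]) - bact$counts["bact002", ] + 1
  net <- suppressMessages(build_network(bact, fung, alpha = 0.05))
  expect_s3_class(net, "interkingdom_network")
  expect_true(all(net$edges$p < 0.05))
  expect_equal(net$edges$sign, ifelse(net$edges$rho >= 0, "positive", "negative"))
  expect_true(all(net$edges$bact %in% net$nodes$taxon[net$nodes$kingdom == "bacteria"]))
  expect_true(all(net$edges$fung %in% net$nodes$taxon[net$nodes$kingdom == "fungi"]))
  expect_true(all(abs(net$edges$rho) <= 1))
  # connectedness = |E| / |V| against an independent igraph recount
  g <- igraph::graph_from_data_frame(net$edges[, c("bact", "fung")],
                                     directed = FALSE,
                                     vertices = net$nodes$taxon)
  expect_equal(net$connectedness,
               igraph::ecount(g) / igraph::vcount(g))
  # node roster includes edge-free taxa under node_mode = "all"
  expect_true(nrow(net$nodes) >= length(unique(c(net$edges$bact, net$edges$fung))))

  expect_error(build_network(bact, taxa_table(fung$counts[, 50:1], "fungi")),
               "align")
})

test_that("network edges are invariant to per-sample depth rescaling", {
  co <- null_cohort(30, n_bact = 8, n_fung = 6, depth = 2000, seed = 18)
  net1 <- suppressMessages(build_network(co$bacteria, co$fungi))
  scale_counts <- function(tb, f) taxa_table(sweep(tb$counts, 2, f, "*"),
                                             tb$kingdom)
  set.seed(44)
  f <- sample(1:9, 30, replace = TRUE)
  net2 <- suppressMessages(build_network(scale_counts(co$bacteria, f),
                                         scale_counts(co$fungi, f)))
  expect_equal(net1$edges, net2$edges, tolerance = 1e-12)
  expect_equal(net1$connectedness, net2$connectedness)
})

test_that("spearman rank invariance holds for monotone transforms", {
  set.seed(45)
  for (i in 1:10) {
    x <- runif(20); y <- runif(20)
    base <- spearman_edge(x, y)
    tx <- exp(3 * x); ty <- y^3 + 10
    expect_equal(spearman_edge(tx, ty), base, tolerance = 1e-12)
  }
})

test_that("removing a sample keeps the roster unless prevalence crosses 30%", {
  co <- null_cohort(20, n_bact = 10, n_fung = 8, depth = 2000, seed = 19)
  net <- suppressMessages(build_network(co$bacteria, co$fungi))
  prev_b <- rowMeans(co$bacteria$counts >= 1)
  prev_f <- rowMeans(co$fungi$counts >= 1)
  for (drop in c(1, 7, 20)) {
    keep <- setdiff(1:20, drop)
    nb <- taxa_table(co$bacteria$counts[, keep], "bacteria")
    nf <- taxa_table(co$fungi$counts[, keep], "fungi")
    crosses <- any(
      (prev_b >= 0.3) != (rowMeans(nb$counts >= 1) >= 0.3),
      (prev_f >= 0.3) != (rowMeans(nf$counts >= 1) >= 0.3))
    net2 <- suppressMessages(build_network(nb, nf))
    if (!crosses) expect_identical(net2$nodes$taxon, net$nodes$taxon)
  }
})

test_that("compare_connectedness handles identical and separated networks", {
  co <- null_cohort(30, n_bact = 8, n_fung = 6, depth = 2000, seed = 20)
  net <- suppressMessages(build_network(co$bacteria, co$fungi))
  for (u in c("edge_rate", "degree")) {
    same <- compare_connectedness(net, net, unit = u)
    expect_equal(same$t, 0)
    expect_equal(same$p, 1)
    expect_equal(same$connectedness_diff, 0)
  }

  # all-degree-2 vs all-degree-0 (zero variance handled explicitly)
  netA <- net; netA$nodes$degree <- 2L
  netB <- net; netB$nodes$degree <- 0L
  sep <- compare_connectedness(netA, netB, unit = "degree")
  expect_lt(sep$p, 1e-6)
  expect_gt(sep$t, 0)

  # edge-rate unit: saturated vs empty edge set
  full <- net
  full$edges <- expand.grid(bact = net$nodes$taxon[net$nodes$kingdom == "bacteria"],
                            fung = net$nodes$taxon[net$nodes$kingdom == "fungi"],
                            stringsAsFactors = FALSE)
  empty <- net; empty$edges <- net$edges[0, , drop = FALSE]
  sep2 <- compare_connectedness(full, empty)
  expect_lt(sep2$p, 1e-6)
  expect_gt(sep2$t, 0)
  expect_identical(sep2$unit, "edge_rate")

  small <- net; small$nodes <- small$nodes[1, , drop = FALSE]
  expect_error(compare_connectedness(small, net), "at least 2")
})

test_that("dyad wilcoxon p-values are conservative but perm_p is calibrated-by-design", {
  # the per-repetition rank-sum p's share samples between the compared sets;
  # under a null cohort they concentrate well away from the rejection region
  cfg <- cohort_config(n_dyads = 15, n_bact = 10, n_fung = 6,
                       sample_types = c("milk", "feces_1mo"),
                       prevalence = 1, dyad_effect_sd = 0, seed = 71)
  co <- generate_cohort(cfg)
  d <- beta_diversity(co$bacteria, "aitchison")
  res <- dyad_distance_test(d, co$metadata, "feces_1mo",
                            n_repetitions = 39, seed = 5)
  expect_true(res$perm_p >= 2 / 40 && res$perm_p <= 1)
  expect_gt(res$median_p, 0.05)   # conservative rank-sum under the null
})

test_that("layout is deterministic, finite, and keeps nodes apart", {
  co <- null_cohort(20, n_bact = 6, n_fung = 5, depth = 2000, seed = 22)
  net <- suppressMessages(build_network(co$bacteria, co$fungi))
  l1 <- layout_network(net, seed = 3)
  l2 <- layout_network(net, seed = 3)
  expect_identical(l1, l2)
  expect_true(all(is.finite(l1)))
  expect_false(identical(l1, layout_network(net, seed = 4)))

  # edgeless graph: pure repulsion keeps nodes distinct
  net0 <- net; net0$edges <- net$edges[0, , drop = FALSE]
  l0 <- layout_network(net0, seed = 5)
  expect_gt(min(dist(l0)), 0)

  # two nodes, one edge: bounded final separation
  net2 <- net
  net2$nodes <- data.frame(taxon = c("b1", "f1"),
                           kingdom = c("bacteria", "fungi"), degree = 1L)
  net2$edges <- data.frame(bact = "b1", fung = "f1", rho = 0.9, p = 0.01,
                           sign = "positive")
  l2n <- layout_network(net2, seed = 6)
  k <- sqrt(1 / 2)
  sep <- sqrt(sum((l2n[1, ] - l2n[2, ])^2))
  expect_gt(sep, 0)
  expect_lt(sep, 4 * k)
})

test_that("network exports write edge TSV and GraphML", {
  co <- null_cohort(30, n_bact = 8, n_fung = 6, depth = 2000, seed = 23)
  net <- suppressMessages(build_network(co$bacteria, co$fungi))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_network_edges(net, tsv)
  back <- utils::read.delim(tsv)
  expect_equal(nrow(back), nrow(net$edges))
  write_network_graphml(net, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), nrow(net$nodes))
  expect_equal(igraph::ecount(g), nrow(net$edges))
  expect_setequal(igraph::vertex_attr(g, "kingdom"), unique(net$nodes$kingdom))
})
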