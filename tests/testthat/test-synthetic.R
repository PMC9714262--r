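test_that("generate_cohort is deterministic and correctly shaped", {
  cfg <- cohort_config(n_dyads = 5, n_bact = 6, n_fung = 4, seed = 42,
                       planted_edges = data.frame(bact = 1, fung = 1, rho = 0.7))
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$bacteria$counts, b$bacteria$counts)
  expect_identical(a$fungi$counts, b$fungi$counts)
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$truth$latent, b$truth$latent)

  expect_equal(dim(a$bacteria$counts), c(6, 15))   # 3 sample types x 5 dyads
  expect_equal(dim(a$fungi$counts), c(4, 15))
  expect_identical(a$bacteria$sample_ids, a$metadata$sample_id)
  expect_setequal(unique(a$metadata$sample_type),
                  c("milk", "feces_1mo", "feces_6mo"))

  # different seed, different draws
  cfg2 <- cohort_config(n_dyads = 5, n_bact = 6, n_fung = 4, seed = 43,
                        planted_edges = data.frame(bact = 1, fung = 1, rho = 0.7))
  expect_false(identical(generate_cohort(cfg2)$bacteria$counts, a$bacteria$counts))
})

test_that("planted latent correlations are realized within +/- 0.05", {
  cfg <- cohort_config(
    n_dyads = 400, n_bact = 8, n_fung = 6, sample_types = "feces_1mo",
    planted_edges = data.frame(bact = c(1, 2), fung = c(1, 2),
                               rho = c(0.8, -0.5)),
    seed = 7)
  co <- generate_cohort(cfg)
  z <- co$truth$latent
  expect_gt(nrow(z), 399)
  expect_lt(abs(cor(z[, "bact001"], z[, "fung001"]) - 0.8), 0.05)
  expect_lt(abs(cor(z[, "bact002"], z[, "fung002"]) + 0.5), 0.05)
  # unplanted pair stays near zero (3 sd of a null correlation)
  expect_lt(abs(cor(z[, "bact003"], z[, "fung003"])), 3 / sqrt(nrow(z)))
})

test_that("configured prevalence is realized and planted taxa are protected", {
  prev <- c(rep(0.5, 4), rep(0.95, 4), rep(0.7, 6))
  cfg <- cohort_config(n_dyads = 300, n_bact = 8, n_fung = 6,
                       sample_types = "milk", prevalence = prev,
                       planted_edges = data.frame(bact = 1, fung = 1, rho = 0.6),
                       seed = 9)
  co <- generate_cohort(cfg)
  keep_rate <- colMeans(co$truth$keep_mask)
  # planted taxa forced to prevalence 1
  expect_equal(unname(co$truth$prevalence[c("bact001", "fung001")]), c(1, 1))
  expect_equal(unname(keep_rate[1]), 1)
  # binomial error at n = 300: 3 sd of p = 0.5 is ~0.087
  expect_lt(abs(keep_rate[2] - 0.5), 0.09)
  expect_lt(abs(keep_rate[5] - 0.95), 0.05)
})

test_that("non-PSD planted edge sets are rejected at construction", {
  # one bacterium near-perfectly correlated with two near-orthogonal fungi
  # forces a negative eigenvalue
  bad <- data.frame(bact = c(1, 1, 2), fung = c(1, 2, 1),
                    rho = c(0.95, 0.95, -0.95))
  expect_error(cohort_config(n_dyads = 5, n_bact = 3, n_fung = 3,
                             planted_edges = bad),
               "positive semi-definite")
  expect_error(cohort_config(n_dyads = 5, n_bact = 3, n_fung = 3,
                             planted_edges = data.frame(bact = 1, fung = 1, rho = 1.2)),
               "rho")
  # a multiplier that pushes |rho| past 1 is also rejected
  expect_error(cohort_config(
    n_dyads = 5, n_bact = 3, n_fung = 3,
    planted_edges = data.frame(bact = 1, fung = 1, rho = 0.6),
    covariate_effects = list(covariate_effect("perinatal_abx", rho_multiplier = 2))),
    "exceeds 1")
})

test_that("null_cohort yields requested shape and independent kingdoms", {
  co <- null_cohort(40, n_bact = 10, n_fung = 8, depth = 2000, seed = 5)
  expect_equal(ncol(co$bacteria$counts), 40)
  expect_equal(ncol(co$fungi$counts), 40)
  expect_null(co$truth$planted_edges)
  # cross-kingdom latent correlations are unstructured
  z <- co$truth$latent
  cc <- cor(z[, 1:10], z[, 11:18])
  expect_lt(max(abs(cc)), 0.6)   # loose: 40 samples, null rho
})

test_that("covariate log-fold effects shift exposed samples", {
  cfg <- cohort_config(
    n_dyads = 150, n_bact = 6, n_fung = 4, sample_types = "feces_1mo",
    covariate_effects = list(covariate_effect(
      "birth_mode", prob = 0.5, taxa_log_fc = c(bact001 = 2.0))),
    seed = 21)
  co <- generate_cohort(cfg)
  rel <- to_relative(co$bacteria)$counts["bact001", ]
  cs <- co$metadata$birth_mode == "cesarean"
  expect_gt(mean(rel[cs]), mean(rel[!cs]))
})
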