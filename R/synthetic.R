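# Synthetic paired-kingdom cohort generator.
#
# Latent model: one multivariate-normal draw per sample over all taxa of both
# kingdoms (a Gaussian copula). Planted bacteria-fungus correlations live in
# the cross-kingdom block of the latent correlation matrix; Spearman's rho is
# invariant to the monotone exp/closure maps downstream, so a planted latent
# rho is directly interpretable as a target rank correlation (attenuated only
# by multinomial counting noise and structural zeros).

#' Describe one covariate effect for the cohort generator
#'
#' @param variable metadata variable carrying the exposure: `"birth_mode"`
#'   (exposed = cesarean) or one of the four antibiotic flags.
#' @param prob probability a dyad is exposed; `NULL` uses cohort-realistic
#'   defaults (cesarean 0.15, prenatal 0.22, perinatal 0.25, maternal
#'   postpartum 0.20, infant postnatal 0.13).
#' @param taxa_log_fc named numeric vector of log-fold changes applied to the
#'   latent log-abundance of named taxa in exposed samples.
#' @param rho_multiplier multiplier applied to every planted latent
#'   correlation for exposed dyads (emulates connectedness contrasts between
#'   exposure groups). At most one covariate effect in a config may set this.
#' @return a list of class `covariate_effect`.
#' @export
covariate_effect <- function(variable, prob = NULL, taxa_log_fc = NULL,
                             rho_multiplier = 1) {
  allowed <- c("birth_mode", ABX_FLAGS)
  if (!variable %in% allowed) {
    stop("covariate variable must be one of: ", paste(allowed, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(prob) && (prob <= 0 || prob >= 1)) {
    stop("exposure probability must lie in (0,1)", call. = FALSE)
  }
  if (!is.null(taxa_log_fc) && is.null(names(taxa_log_fc))) {
    stop("taxa_log_fc must be a named vector of taxon ids", call. = FALSE)
  }
  structure(list(variable = variable, prob = prob,
                 taxa_log_fc = taxa_log_fc, rho_multiplier = rho_multiplier),
            class = "covariate_effect")
}

default_exposure_prob <- function(variable) {
  switch(variable,
         birth_mode = 0.15,
         prenatal_abx = 0.22,
         perinatal_abx = 0.25,
         maternal_postpartum_abx = 0.20,
         infant_postnatal_abx = 0.13)
}

# Latent correlation matrix over (bacteria, fungi) with planted cross edges.
latent_correlation <- function(n_bact, n_fung, planted_edges, multiplier = 1) {
  p <- n_bact + n_fung
  R <- diag(p)
  if (!is.null(planted_edges) && nrow(planted_edges)) {
    rho <- planted_edges$rho * multiplier
    if (any(abs(rho) > 1)) {
      stop("planted |rho| x multiplier exceeds 1 for edge(s): ",
           paste(which(abs(rho) > 1), collapse = ", "), call. = FALSE)
    }
    for (k in seq_len(nrow(planted_edges))) {
      i <- planted_edges$bact[k]
      j <- n_bact + planted_edges$fung[k]
      R[i, j] <- R[j, i] <- rho[k]
    }
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("planted edge set does not define a positive semi-definite latent ",
         "correlation matrix (multiplier = ", multiplier, "); edges: ",
         paste(sprintf("(%d,%d,%.2f)", planted_edges$bact, planted_edges$fung,
                       planted_edges$rho), collapse = " "), call. = FALSE)
  }
  R
}

matrix_sqrt <- function(R) {
  e <- eigen(R, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Configure a synthetic dyad cohort
#'
#' Defaults state a realistic exclusively-breastfeeding cohort: three samples
#' per dyad (mother's milk, infant feces at 1 and 6 months), lognormal
#' sequencing depths centered at the field-typical per-sample averages
#' (about 30k bacterial and 7k fungal reads in milk, 34k and 6k in feces),
#' sparse overdispersed counts, and optional planted interkingdom rank
#' correlations, dyad-shared shifts, and covariate effects.
#'
#' @param n_dyads number of mother-infant pairs (>= 3).
#' @param n_bact,n_fung taxa counts per kingdom.
#' @param sample_types subset of `c("milk","feces_1mo","feces_6mo")`, one
#'   sample per dyad per type.
#' @param depth_meanlog named list of lognormal medians for sequencing depth
#'   by kingdom and niche.
#' @param depth_sdlog lognormal sigma of depth.
#' @param base_logabund_sd SD of per-taxon, per-sample-type baseline
#'   log-abundances (controls how distinct niches are and how uneven the
#'   community is).
#' @param taxon_sigma SD multiplier on the per-sample latent normal (the
#'   overdispersion of taxa across samples on the log scale).
#' @param prevalence per-taxon probability a taxon is structurally present in
#'   a sample (thinning applied after counting). Scalar, vector of length
#'   `n_bact + n_fung`, or `NULL` to draw once per taxon from U(0.4, 1).
#'   Taxa involved in planted edges are forced to prevalence 1 so planted
#'   correlations are not destroyed by thinning.
#' @param planted_edges data frame with columns `bact`, `fung` (taxon indices
#'   within kingdom) and `rho` (target latent correlation in `[-1, 1]`).
#' @param dyad_effect_sd SD of a latent shift shared by all samples of a dyad.
#' @param covariate_effects list of [covariate_effect()] objects.
#' @param seed integer RNG seed; outputs are bit-reproducible from
#'   (config, seed).
#' @return a list of class `cohort_config` (validated; in particular the
#'   implied latent correlation matrices must be positive semi-definite).
#' @export
cohort_config <- function(n_dyads = 60, n_bact = 30, n_fung = 20,
                          sample_types = SAMPLE_TYPES,
                          depth_meanlog = list(bact_milk = log(29762),
                                               bact_feces = log(34286),
                                               fung_milk = log(7162),
                                               fung_feces = log(6191)),
                          depth_sdlog = 0.5,
                          base_logabund_sd = 1.2,
                          taxon_sigma = 1.0,
                          prevalence = NULL,
                          planted_edges = NULL,
                          dyad_effect_sd = 0,
                          covariate_effects = list(),
                          seed = 1) {
  if (n_dyads < 3) stop("n_dyads must be >= 3", call. = FALSE)
  stopifnot(n_bact >= 1, n_fung >= 1, depth_sdlog >= 0,
            base_logabund_sd >= 0, taxon_sigma >= 0, dyad_effect_sd >= 0)
  sample_types <- match.arg(sample_types, SAMPLE_TYPES, several.ok = TRUE)
  if (any(exp(unlist(depth_meanlog)) < 1)) stop("depths must be >= 1", call. = FALSE)
  if (!is.null(planted_edges)) {
    planted_edges <- as.data.frame(planted_edges)
    stopifnot(all(c("bact", "fung", "rho") %in% colnames(planted_edges)))
    if (any(abs(planted_edges$rho) > 1)) stop("|rho| must be <= 1", call. = FALSE)
    if (any(planted_edges$bact < 1 | planted_edges$bact > n_bact) ||
        any(planted_edges$fung < 1 | planted_edges$fung > n_fung)) {
      stop("planted edge taxon index out of range", call. = FALSE)
    }
  }
  if (!is.null(prevalence)) {
    if (length(prevalence) == 1L) prevalence <- rep(prevalence, n_bact + n_fung)
    stopifnot(length(prevalence) == n_bact + n_fung,
              all(prevalence > 0), all(prevalence <= 1))
  }
  mult <- vapply(covariate_effects, function(e) e$rho_multiplier, numeric(1))
  if (sum(mult != 1) > 1L) {
    stop("at most one covariate effect may set rho_multiplier != 1", call. = FALSE)
  }
  # validate PSD of the base and (if any) exposed-group correlation matrix
  latent_correlation(n_bact, n_fung, planted_edges, 1)
  if (any(mult != 1)) {
    latent_correlation(n_bact, n_fung, planted_edges, mult[mult != 1][1])
  }
  structure(list(n_dyads = n_dyads, n_bact = n_bact, n_fung = n_fung,
                 sample_types = sample_types, depth_meanlog = depth_meanlog,
                 depth_sdlog = depth_sdlog, base_logabund_sd = base_logabund_sd,
                 taxon_sigma = taxon_sigma, prevalence = prevalence,
                 planted_edges = planted_edges, dyad_effect_sd = dyad_effect_sd,
                 covariate_effects = covariate_effects, seed = seed),
            class = "cohort_config")
}

#' Generate a paired-kingdom dyad cohort with known truth
#'
#' Per sample: a latent multivariate normal over all taxa of both kingdoms
#' (correlation matrix encodes the planted edges; exposed dyads use the
#' rho-multiplied matrix), plus a dyad-shared shift and covariate log-fold
#' effects; the exponentiated vector is closed to a composition per kingdom;
#' counts are multinomial at a lognormal depth; structural zeros are applied
#' by per-taxon Bernoulli thinning.
#'
#' @param config a [cohort_config()].
#' @return list with `bacteria` and `fungi` ([taxa_table()]s, `scale =
#'   "counts"`), `metadata` (data frame), and `truth` (latent matrix, planted
#'   edges, per-dyad covariate assignments, prevalence, baselines).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  nb <- config$n_bact; nf <- config$n_fung; p <- nb + nf
  nd <- config$n_dyads
  types <- config$sample_types
  ns <- nd * length(types)
  bact_ids <- sprintf("bact%03d", seq_len(nb))
  fung_ids <- sprintf("fung%03d", seq_len(nf))
  taxa_ids <- c(bact_ids, fung_ids)

  edges <- config$planted_edges
  R_base <- latent_correlation(nb, nf, edges, 1)
  sqrt_base <- matrix_sqrt(R_base)
  mult_effect <- Filter(function(e) e$rho_multiplier != 1, config$covariate_effects)
  sqrt_exp <- if (length(mult_effect)) {
    matrix_sqrt(latent_correlation(nb, nf, edges, mult_effect[[1]]$rho_multiplier))
  } else NULL

  with_seed(config$seed, {
    # 1. per-(taxon, sample type) baseline log-abundances
    baselines <- matrix(stats::rnorm(p * length(types), 0, config$base_logabund_sd),
                        nrow = p, dimnames = list(taxa_ids, types))
    # 2. per-taxon structural prevalence
    prevalence <- config$prevalence %||% stats::runif(p, 0.4, 1)
    if (!is.null(edges) && nrow(edges)) {
      prevalence[unique(edges$bact)] <- 1
      prevalence[nb + unique(edges$fung)] <- 1
    }
    names(prevalence) <- taxa_ids
    # 3. dyad-level covariate assignments
    dyad_cov <- data.frame(dyad = seq_len(nd))
    dyad_cov$birth_mode <- ifelse(
      stats::rbinom(nd, 1, prob_for(config, "birth_mode")) == 1, "cesarean", "vaginal")
    for (fl in ABX_FLAGS) {
      dyad_cov[[fl]] <- stats::rbinom(nd, 1, prob_for(config, fl)) == 1
    }
    # 4. dyad-shared latent shifts
    dyad_shift <- matrix(stats::rnorm(nd * p, 0, config$dyad_effect_sd), nrow = nd)
    # 5. correlated latent normals, one row per sample
    dyad_of <- rep(seq_len(nd), each = length(types))
    type_of <- rep(types, times = nd)
    exposed_dyad <- if (length(mult_effect)) {
      is_exposed(dyad_cov, mult_effect[[1]]$variable)
    } else rep(FALSE, nd)
    Z <- matrix(stats::rnorm(ns * p), nrow = ns)
    latent <- Z %*% sqrt_base
    if (any(exposed_dyad)) {
      rows <- which(exposed_dyad[dyad_of])
      latent[rows, ] <- Z[rows, , drop = FALSE] %*% sqrt_exp
    }
    # 6. assemble log-abundances
    logab <- t(baselines[, type_of, drop = FALSE]) +
      dyad_shift[dyad_of, , drop = FALSE] +
      config$taxon_sigma * latent
    for (eff in config$covariate_effects) {
      if (is.null(eff$taxa_log_fc)) next
      idx <- match(names(eff$taxa_log_fc), taxa_ids)
      if (anyNA(idx)) {
        stop("covariate effect names unknown taxa: ",
             paste(names(eff$taxa_log_fc)[is.na(idx)], collapse = ", "),
             call. = FALSE)
      }
      rows <- which(is_exposed(dyad_cov, eff$variable)[dyad_of])
      if (length(rows)) {
        logab[rows, idx] <- logab[rows, idx] +
          matrix(eff$taxa_log_fc, nrow = length(rows), ncol = length(idx), byrow = TRUE)
      }
    }
    # 7. depths, multinomial counts, thinning
    dm <- config$depth_meanlog
    milk <- type_of == "milk"
    depth_b <- pmax(1, round(stats::rlnorm(
      ns, ifelse(milk, dm$bact_milk, dm$bact_feces), config$depth_sdlog)))
    depth_f <- pmax(1, round(stats::rlnorm(
      ns, ifelse(milk, dm$fung_milk, dm$fung_feces), config$depth_sdlog)))
    counts_b <- matrix(0L, nrow = nb, ncol = ns)
    counts_f <- matrix(0L, nrow = nf, ncol = ns)
    for (s in seq_len(ns)) {
      eb <- exp(logab[s, seq_len(nb)])
      ef <- exp(logab[s, nb + seq_len(nf)])
      counts_b[, s] <- stats::rmultinom(1, depth_b[s], eb / sum(eb))
      counts_f[, s] <- stats::rmultinom(1, depth_f[s], ef / sum(ef))
    }
    keep <- matrix(stats::rbinom(ns * p, 1, rep(prevalence, each = ns)),
                   nrow = ns) == 1
    counts_b <- counts_b * t(keep[, seq_len(nb), drop = FALSE])
    counts_f <- counts_f * t(keep[, nb + seq_len(nf), drop = FALSE])

    sample_ids <- sprintf("D%03d_%s", dyad_of, type_of)
    dimnames(counts_b) <- list(bact_ids, sample_ids)
    dimnames(counts_f) <- list(fung_ids, sample_ids)
    meta <- data.frame(
      sample_id = sample_ids,
      subject_id = ifelse(type_of == "milk", sprintf("M%03d", dyad_of),
                          sprintf("I%03d", dyad_of)),
      dyad_id = sprintf("D%03d", dyad_of),
      sample_type = type_of,
      birth_mode = dyad_cov$birth_mode[dyad_of],
      stringsAsFactors = FALSE
    )
    for (fl in ABX_FLAGS) meta[[fl]] <- dyad_cov[[fl]][dyad_of]
    rownames(latent) <- sample_ids
    colnames(latent) <- taxa_ids
    list(
      bacteria = taxa_table(counts_b, "bacteria", "counts"),
      fungi = taxa_table(counts_f, "fungi", "counts"),
      metadata = validate_metadata(meta),
      truth = list(latent = latent, planted_edges = edges,
                   dyad_covariates = dyad_cov, prevalence = prevalence,
                   baselines = baselines, keep_mask = keep,
                   config = config)
    )
  })
}

prob_for <- function(config, variable) {
  for (eff in config$covariate_effects) {
    if (eff$variable == variable && !is.null(eff$prob)) return(eff$prob)
  }
  default_exposure_prob(variable)
}

is_exposed <- function(dyad_cov, variable) {
  if (variable == "birth_mode") dyad_cov$birth_mode == "cesarean"
  else dyad_cov[[variable]]
}

#' Generate a fully independent null cohort
#'
#' Convenience wrapper around [generate_cohort()]: no planted edges, no dyad
#' effect, no covariate effects, a single sample type (so niche structure
#' cannot induce spurious interkingdom correlation), and no structural zeros.
#'
#' @param n_samples number of samples (columns) per kingdom.
#' @param n_bact,n_fung taxa per kingdom.
#' @param depth lognormal median sequencing depth for both kingdoms.
#' @param seed RNG seed.
#' @return list as in [generate_cohort()] with `n_samples` columns per table.
#' @export
null_cohort <- function(n_samples, n_bact = 20, n_fung = 20,
                        depth = 5000, seed = 1) {
  cfg <- cohort_config(
    n_dyads = n_samples, n_bact = n_bact, n_fung = n_fung,
    sample_types = "feces_1mo",
    depth_meanlog = list(bact_milk = log(depth), bact_feces = log(depth),
                         fung_milk = log(depth), fung_feces = log(depth)),
    depth_sdlog = 0.3, base_logabund_sd = 1.0, taxon_sigma = 0.8,
    prevalence = 1, planted_edges = NULL, dyad_effect_sd = 0,
    covariate_effects = list(), seed = seed)
  generate_cohort(cfg)
}
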