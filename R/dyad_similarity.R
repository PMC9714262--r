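# Related- vs unrelated-dyad community similarity by distance resampling.

#' Test whether related mother-infant pairs are more similar than unrelated pairs
#'
#' The related set holds one milk-to-feces distance per dyad. Each repetition
#' draws a random derangement over dyads (every mother is paired with a
#' different dyad's infant, never her own), yielding an equal-size unrelated
#' set, and compares the two sets with a two-sided Wilcoxon rank-sum test
#' (exact when there are at most 25 tie-free dyads, otherwise the normal
#' approximation with continuity correction).
#' Summaries report the per-repetition p distribution (median, fraction
#' < 0.05) and a pooled variant (all repetitions' unrelated distances in one
#' test), clearly labeled as such.
#'
#' Because the related and every unrelated set share the same milk (and
#' fecal) samples, the per-repetition rank-sum statistic has far less spread
#' than its independence null assumes, making those p-values strongly
#' conservative under the no-dyad-effect null. The result therefore also
#' carries `perm_p`, a calibrated derangement permutation test: the observed
#' mean related distance is ranked within the per-repetition mean unrelated
#' distances, `perm_p = min(1, 2 min(p_lo, p_hi))` with the usual add-one
#' tail estimates. `perm_p` is the recommended significance summary.
#'
#' @param dist a `distance_matrix` over combined milk and fecal samples.
#' @param meta sample metadata (see [read_sample_metadata()]).
#' @param fecal_type `"feces_1mo"` or `"feces_6mo"`.
#' @param n_repetitions number of random derangements (default 100).
#' @param seed RNG seed.
#' @param alternative passed to the Wilcoxon test (default two-sided; the
#'   "related pairs are closer" direction corresponds to `"less"`).
#' @return object of class `dyad_test_result`: `related` (named distances),
#'   `p_values` (per repetition), `unrelated_median` (per repetition),
#'   `median_p`, `fraction_significant`, `pooled_p`, `perm_p`, `n_dyads`,
#'   `n_repetitions`, `seed`.
#' @export
dyad_distance_test <- function(dist, meta, fecal_type = c("feces_1mo", "feces_6mo"),
                               n_repetitions = 100, seed = 1,
                               alternative = c("two.sided", "less", "greater")) {
  stopifnot(inherits(dist, "distance_matrix"))
  fecal_type <- match.arg(fecal_type)
  alternative <- match.arg(alternative)
  ids <- dist$sample_ids
  meta <- meta[meta$sample_id %in% ids, , drop = FALSE]
  milk <- meta[meta$sample_type == "milk", c("sample_id", "dyad_id")]
  fec <- meta[meta$sample_type == fecal_type, c("sample_id", "dyad_id")]
  dyads <- intersect(milk$dyad_id, fec$dyad_id)
  n <- length(dyads)
  if (n < 3) stop("need at least 3 complete dyads with milk and ", fecal_type,
                  " samples", call. = FALSE)
  milk_id <- milk$sample_id[match(dyads, milk$dyad_id)]
  fec_id <- fec$sample_id[match(dyads, fec$dyad_id)]
  D <- dist$values
  mi <- match(milk_id, ids)
  fi <- match(fec_id, ids)
  related <- D[cbind(mi, fi)]
  names(related) <- dyads

  res <- with_seed(seed, {
    p_values <- numeric(n_repetitions)
    unrelated_median <- numeric(n_repetitions)
    pooled <- vector("list", n_repetitions)
    for (r in seq_len(n_repetitions)) {
      der <- random_derangement(n)
      stopifnot(all(der != seq_len(n)))   # a mother never gets her own infant
      unrelated <- D[cbind(mi, fi[der])]
      use_exact <- n <= 25 && anyDuplicated(c(related, unrelated)) == 0
      p_values[r] <- suppressWarnings(
        stats::wilcox.test(related, unrelated, alternative = alternative,
                           exact = use_exact, correct = TRUE)$p.value)
      unrelated_median[r] <- stats::median(unrelated)
      pooled[[r]] <- unrelated
    }
    pooled_p <- suppressWarnings(
      stats::wilcox.test(related, unlist(pooled), alternative = alternative,
                         exact = FALSE, correct = TRUE)$p.value)
    # derangement permutation test on the mean related distance
    t_obs <- mean(related)
    t_null <- vapply(pooled, mean, numeric(1))
    p_lo <- (sum(t_null <= t_obs) + 1) / (n_repetitions + 1)
    p_hi <- (sum(t_null >= t_obs) + 1) / (n_repetitions + 1)
    perm_p <- switch(alternative,
                     two.sided = min(1, 2 * min(p_lo, p_hi)),
                     less = p_lo,
                     greater = p_hi)
    list(p_values = p_values, unrelated_median = unrelated_median,
         pooled_p = pooled_p, perm_p = perm_p)
  })
  structure(list(related = related,
                 p_values = res$p_values,
                 unrelated_median = res$unrelated_median,
                 median_p = stats::median(res$p_values),
                 fraction_significant = mean(res$p_values < 0.05),
                 pooled_p = res$pooled_p,
                 perm_p = res$perm_p,
                 n_dyads = n, n_repetitions = n_repetitions,
                 fecal_type = fecal_type, alternative = alternative,
                 seed = seed),
            class = "dyad_test_result")
}

#' @export
print.dyad_test_result <- function(x, ...) {
  cat(sprintf(
    "<dyad_test_result> %d dyads, %d repetitions (%s): permutation p = %.4g, median rank-sum p = %.4g\n",
    x$n_dyads, x$n_repetitions, x$fecal_type, x$perm_p, x$median_p))
  invisible(x)
}

#' Export per-repetition dyad test results
#'
#' @param res a `dyad_test_result`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_dyad_test <- function(res, path) {
  stopifnot(inherits(res, "dyad_test_result"))
  df <- data.frame(repetition = seq_along(res$p_values),
                   p = res$p_values,
                   unrelated_median = res$unrelated_median)
  df <- rbind(df, data.frame(repetition = NA, p = res$median_p,
                             unrelated_median = stats::median(res$related)))
  write_tsv(df, path)
}
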