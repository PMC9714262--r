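# Per-taxon group comparisons: Wilcoxon rank-sum + Hodges-Lehmann shift,
# Benjamini-Hochberg FDR across taxa.

#' Wilcoxon rank-sum test with Hodges-Lehmann shift estimate
#'
#' Exact enumeration when the combined sample size is at most 20 and there
#' are no ties; otherwise the tie-corrected normal approximation with
#' continuity correction (toggle with `correct`). The Hodges-Lehmann estimate
#' is the median of all pairwise differences `x_i - y_j`; the confidence
#' interval inverts the rank-sum test (order statistics of the pairwise
#' differences at the critical rank).
#'
#' @param x,y numeric vectors with at least 2 values each.
#' @param conf_level confidence level for the shift interval.
#' @param correct apply continuity correction in the normal approximation.
#' @return list: `statistic` (Mann-Whitney U for x), `p`, `hl_estimate`,
#'   `ci_lower`, `ci_upper`, `exact`.
#' @export
wilcoxon_hl <- function(x, y, conf_level = 0.95, correct = TRUE) {
  if (length(x) < 2 || length(y) < 2) {
    stop("both groups need at least 2 values", call. = FALSE)
  }
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- (length(x) + length(y) <= 20) && !ties
  ht <- suppressWarnings(stats::wilcox.test(
    x, y, conf.int = TRUE, conf.level = conf_level,
    exact = use_exact, correct = correct))
  list(statistic = unname(ht$statistic),
       p = ht$p.value,
       hl_estimate = unname(ht$estimate),
       ci_lower = ht$conf.int[1],
       ci_upper = ht$conf.int[2],
       exact = use_exact)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up procedure: `q_(i) = min_{j >= i} (p_(j) * m / j)`, capped at 1 and
#' mapped back to the input order.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return q-values in input order.
#' @export
bh_fdr <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  if (anyNA(pvalues) || any(pvalues < 0) || any(pvalues > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(pvalues)
  o <- order(pvalues)
  q_sorted <- pmin(1, rev(cummin(rev(pvalues[o] * m / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

#' Per-taxon differential abundance between two groups
#'
#' For every taxon, a two-sided Wilcoxon rank-sum test on relative abundances
#' between the two levels of `variable`, with Hodges-Lehmann shift and CI,
#' then BH FDR across all taxa of the run (one FDR family per call; do not
#' pool across sample types).
#'
#' @param table a [taxa_table()] (counts are converted to proportions).
#' @param meta sample metadata containing `variable`.
#' @param variable name of a two-level metadata variable.
#' @param q_threshold significance threshold on the q-value (the reference
#'   analysis used 0.25).
#' @param conf_level confidence level for the shift interval.
#' @param correct continuity correction flag, passed to [wilcoxon_hl()].
#' @return data frame, one row per taxon: group sizes, statistic, p, HL shift
#'   with CI, q, significance flag. Taxa constant across all samples are
#'   skipped with a message.
#' @export
diff_abundance <- function(table, meta, variable, q_threshold = 0.25,
                           conf_level = 0.95, correct = TRUE) {
  stopifnot(inherits(table, "taxa_table"))
  if (!variable %in% colnames(meta)) {
    stop("metadata lacks column '", variable, "'", call. = FALSE)
  }
  meta <- meta[match(table$sample_ids, meta$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id)) stop("metadata missing analyzed samples", call. = FALSE)
  g <- meta[[variable]]
  keep <- !is.na(g)
  g <- g[keep]
  lv <- sort(unique(as.character(g)))
  if (length(lv) != 2) {
    stop("variable '", variable, "' must have exactly 2 levels on the analyzed samples",
         call. = FALSE)
  }
  rel <- if (table$scale == "counts") to_relative(table) else table
  m <- rel$counts[, keep, drop = FALSE]
  ia <- g == lv[1]
  rows <- lapply(table$taxa_ids, function(tx) {
    v <- m[tx, ]
    if (length(unique(v)) < 2) return(NULL)
    w <- wilcoxon_hl(v[ia], v[!ia], conf_level = conf_level, correct = correct)
    data.frame(taxon = tx, group1 = lv[1], group2 = lv[2],
               n1 = sum(ia), n2 = sum(!ia),
               statistic = w$statistic, p = w$p,
               hl_estimate = w$hl_estimate,
               ci_lower = w$ci_lower, ci_upper = w$ci_upper,
               stringsAsFactors = FALSE)
  })
  skipped <- sum(vapply(rows, is.null, logical(1)))
  if (skipped) message("diff_abundance: skipped ", skipped, " constant taxa")
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("no testable taxa", call. = FALSE)
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out$significant <- out$q < q_threshold
  rownames(out) <- NULL
  out
}
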