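# Permutational multivariate ANOVA on a distance matrix (McArdle-Anderson).

#' PERMANOVA with sequential sums of squares
#'
#' Gower-centers `G = -1/2 J D^2 J` and partitions its trace sequentially over
#' an ordered list of design terms (Type-I, term order is part of the analysis
#' and is recorded in the result). Significance per term comes from free
#' permutation of sample labels: the pseudo-F of each term is recomputed for
#' each permuted G and `p = (#{F_perm >= F_obs} + 1) / (n_perm + 1)`.
#'
#' Rows with missing values in any term are dropped (and counted). Repeated
#' measures are not modeled; analyze sample types separately.
#'
#' @param dist a `distance_matrix` or symmetric numeric matrix.
#' @param meta data frame with one row per sample (`sample_id` column used to
#'   align against the distance matrix when present).
#' @param terms character vector of metadata variable names, in entry order.
#' @param n_perm number of random permutations (>= 99 recommended).
#' @param seed RNG seed for the permutation set.
#' @param exact if `TRUE` (only allowed for n <= 7) enumerate all `n!`
#'   permutations; p is then the exact proportion `#{F_perm >= F_obs} / n!`.
#' @return object of class `permanova_result`: a per-term table (df, SS,
#'   pseudo-F, p) plus residual/total rows and provenance attributes.
#' @export
permanova <- function(dist, meta, terms, n_perm = 999, seed = 1, exact = FALSE) {
  if (inherits(dist, "distance_matrix")) {
    ids <- dist$sample_ids
    D <- dist$values
  } else {
    D <- as.matrix(dist)
    ids <- rownames(D) %||% as.character(seq_len(nrow(D)))
  }
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix is not symmetric", call. = FALSE)
  if (!all(terms %in% colnames(meta))) {
    stop("terms not in metadata: ",
         paste(setdiff(terms, colnames(meta)), collapse = ", "), call. = FALSE)
  }
  if ("sample_id" %in% colnames(meta)) {
    keep_ids <- intersect(ids, meta$sample_id)
    meta <- meta[match(keep_ids, meta$sample_id), , drop = FALSE]
    D <- D[match(keep_ids, ids), match(keep_ids, ids), drop = FALSE]
    ids <- keep_ids
  }
  cc <- stats::complete.cases(meta[, terms, drop = FALSE])
  n_dropped <- sum(!cc)
  if (n_dropped) {
    message("permanova: dropped ", n_dropped, " sample(s) with missing term values")
    D <- D[cc, cc, drop = FALSE]
    meta <- meta[cc, , drop = FALSE]
    ids <- ids[cc]
  }
  n <- nrow(D)
  if (n < 4) stop("too few complete samples for PERMANOVA", call. = FALSE)
  for (tm in terms) {
    v <- meta[[tm]]
    if (length(unique(v)) < 2) {
      stop("term '", tm, "' is constant on the analyzed samples", call. = FALSE)
    }
  }
  if (!exact && n_perm < 99) warning("n_perm < 99 gives a coarse p-value grid")
  if (exact && n > 7) stop("exact enumeration only supported for n <= 7", call. = FALSE)

  J <- diag(n) - matrix(1 / n, n, n)
  G <- -0.5 * J %*% (D^2) %*% J
  G <- (G + t(G)) / 2

  # cumulative hat matrices, intercept first
  X <- matrix(1, n, 1)
  hats <- vector("list", length(terms) + 1L)
  ranks <- integer(length(terms) + 1L)
  qr0 <- qr(X)
  ranks[1] <- qr0$rank
  Q <- qr.Q(qr0)[, seq_len(qr0$rank), drop = FALSE]
  hats[[1]] <- tcrossprod(Q)
  for (k in seq_along(terms)) {
    v <- meta[[terms[k]]]
    cols <- if (is.numeric(v)) matrix(as.numeric(v), ncol = 1) else {
      stats::model.matrix(~f, data.frame(f = factor(v)))[, -1, drop = FALSE]
    }
    X <- cbind(X, cols)
    qk <- qr(X)
    ranks[k + 1] <- qk$rank
    if (ranks[k + 1] == ranks[k]) {
      stop("term '", terms[k], "' is collinear with earlier terms (adds 0 df)",
           call. = FALSE)
    }
    Q <- qr.Q(qk)[, seq_len(qk$rank), drop = FALSE]
    hats[[k + 1]] <- tcrossprod(Q)
  }
  df_terms <- diff(ranks)
  df_res <- n - ranks[length(ranks)]
  if (df_res < 1) stop("model saturates the data (no residual df)", call. = FALSE)

  # tr(H G H) = tr(H G) for symmetric idempotent H. Sums of squares are
  # clamped at 0: a degenerate configuration (e.g. zero within-group
  # distances) can make the residual trace a tiny negative float, which would
  # flip the pseudo-F's sign instead of sending it to +Inf.
  stat_fun <- function(Gp) {
    ssm <- vapply(hats, function(H) sum(H * Gp), numeric(1))
    ss <- pmax(diff(ssm), 0)
    ss_res <- max(sum(diag(Gp)) - ssm[length(ssm)], 0)
    f <- (ss / df_terms) / (ss_res / df_res)
    list(ss = ss, ss_res = ss_res, f = f)
  }
  obs <- stat_fun(G)

  perms <- if (exact) {
    all_permutations(n)
  } else {
    with_seed(seed, replicate(n_perm, sample.int(n), simplify = FALSE))
  }
  f_perm <- vapply(perms, function(p) stat_fun(G[p, p, drop = FALSE])$f,
                   numeric(length(terms)))
  f_perm <- matrix(f_perm, nrow = length(terms))
  if (exact) {
    pvals <- rowMeans(f_perm >= obs$f - 1e-12)
    n_perm_used <- length(perms)
  } else {
    pvals <- (rowSums(f_perm >= obs$f - 1e-12) + 1) / (n_perm + 1)
    n_perm_used <- n_perm
  }

  ss_total <- sum(diag(G))
  tab <- data.frame(
    term = c(terms, "residual", "total"),
    df = c(df_terms, df_res, n - 1),
    SS = c(obs$ss, obs$ss_res, ss_total),
    F = c(obs$f, NA, NA),
    p = c(pvals, NA, NA),
    stringsAsFactors = FALSE
  )
  structure(tab, class = c("permanova_result", "data.frame"),
            n_perm = n_perm_used, seed = seed, exact = exact,
            n_samples = n, n_dropped = n_dropped, term_order = terms)
}

#' Export a PERMANOVA table with provenance
#'
#' @param res a `permanova_result`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_permanova <- function(res, path) {
  stopifnot(inherits(res, "permanova_result"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_samples=%d n_perm=%d seed=%s term_order=%s",
                     attr(res, "n_samples"), attr(res, "n_perm"),
                     attr(res, "seed"),
                     paste(attr(res, "term_order"), collapse = "+")), con)
  utils::write.table(as.data.frame(res), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
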