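# Symmetric Procrustes congruence of two ordinations with Monte-Carlo p.

#' Procrustes test of ordination congruence
#'
#' Both configurations are centered and scaled to unit sum of squares; the
#' optimal rotation (reflections permitted) comes from the SVD of the
#' cross-covariance, giving the symmetric Procrustes statistic
#' `m2 = 1 - (sum of singular values)^2`, in `[0, 1]`, with correlation-style
#' companion `t = sqrt(1 - m2)`. The null distribution is obtained by
#' randomly permuting the rows of the second configuration and re-fitting;
#' `p = (#{m2_perm <= m2_obs} + 1) / (n_perm + 1)`.
#'
#' @param ordA,ordB `ordination` objects (see [pcoa()]) over the same sample
#'   roster in the same order, or plain coordinate matrices with row names.
#' @param n_axes number of leading axes to compare (default: all axes
#'   available in both).
#' @param n_perm Monte-Carlo permutations (the reference analysis used 1000).
#' @param seed RNG seed.
#' @return object of class `procrustes_result` with `m2`, `t`, `p`,
#'   `n_axes`, `n_perm`, `seed`.
#' @export
procrustes_test <- function(ordA, ordB, n_axes = NULL, n_perm = 999, seed = 1) {
  A <- if (inherits(ordA, "ordination")) ordA$coordinates else as.matrix(ordA)
  B <- if (inherits(ordB, "ordination")) ordB$coordinates else as.matrix(ordB)
  if (is.null(rownames(A)) || is.null(rownames(B))) {
    stop("configurations must carry sample ids as row names", call. = FALSE)
  }
  if (!identical(rownames(A), rownames(B))) {
    bad <- c(setdiff(rownames(A), rownames(B)), setdiff(rownames(B), rownames(A)))
    stop("sample rosters differ or are ordered differently",
         if (length(bad)) paste0("; symmetric difference: ",
                                 paste(unique(bad), collapse = ", ")),
         call. = FALSE)
  }
  n_axes <- n_axes %||% min(ncol(A), ncol(B))
  if (n_axes < 2) stop("need at least 2 axes", call. = FALSE)
  if (n_axes > min(ncol(A), ncol(B))) {
    stop("n_axes exceeds available axes", call. = FALSE)
  }
  A <- A[, seq_len(n_axes), drop = FALSE]
  B <- B[, seq_len(n_axes), drop = FALSE]

  m2_obs <- procrustes_m2(A, B)
  m2_perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    procrustes_m2(A, B[sample.int(nrow(B)), , drop = FALSE])
  }, numeric(1)))
  p <- (sum(m2_perm <= m2_obs + 1e-12) + 1) / (n_perm + 1)
  structure(list(m2 = m2_obs, t = sqrt(max(0, 1 - m2_obs)), p = p,
                 n_axes = n_axes, n_perm = n_perm, seed = seed,
                 n_samples = nrow(A)),
            class = "procrustes_result")
}

# Symmetric Procrustes residual of two configurations (no id checks).
procrustes_m2 <- function(A, B) {
  A <- scale(A, center = TRUE, scale = FALSE)
  B <- scale(B, center = TRUE, scale = FALSE)
  A <- A / sqrt(sum(A^2))
  B <- B / sqrt(sum(B^2))
  d <- svd(crossprod(A, B))$d
  max(0, 1 - sum(d)^2)
}

#' @export
print.procrustes_result <- function(x, ...) {
  cat(sprintf("<procrustes_result> m2 = %.4f, t = %.4f, p = %.4g (%d axes, %d permutations)\n",
              x$m2, x$t, x$p, x$n_axes, x$n_perm))
  invisible(x)
}

#' Export a Procrustes result as TSV
#'
#' @param res a `procrustes_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_procrustes <- function(res, path) {
  stopifnot(inherits(res, "procrustes_result"))
  write_tsv(data.frame(m2 = res$m2, t = res$t, p = res$p, n_axes = res$n_axes,
                       n_perm = res$n_perm, seed = res$seed,
                       n_samples = res$n_samples), path)
}
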