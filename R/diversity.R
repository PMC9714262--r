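# CLR normalization, alpha diversity, beta diversity, and PCoA.

#' Centered log-ratio transform
#'
#' Per sample j: `x_ij = ln(c_ij + pseudocount) - mean_i ln(c_ij + pseudocount)`,
#' so every transformed column sums to zero. The pseudocount (default 1 added
#' to every count) handles zeros; it is a reported analysis knob, not a fact
#' of the data.
#'
#' @param table a [taxa_table()] with `scale = "counts"`.
#' @param pseudocount positive offset added to every count.
#' @return a taxa x samples numeric matrix.
#' @export
clr_transform <- function(table, pseudocount = 1) {
  stopifnot(inherits(table, "taxa_table"))
  if (table$scale != "counts") stop("CLR expects a counts-scale table", call. = FALSE)
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount <= 0) {
    stop("pseudocount must be a single positive number", call. = FALSE)
  }
  lg <- log(table$counts + pseudocount)
  sweep(lg, 2, colMeans(lg), "-")
}

#' Within-sample (alpha) diversity
#'
#' Shannon entropy `-sum p_i ln p_i` (natural log) or Simpson's index in the
#' complement form `1 - sum p_i^2` (reported as such because "Simpson" is
#' ambiguous across ecosystems), computed on within-sample proportions.
#'
#' @param table a [taxa_table()]; counts are converted to proportions.
#' @param metric `"shannon"` or `"simpson"`.
#' @return named numeric vector, one value per sample.
#' @export
alpha_diversity <- function(table, metric = c("shannon", "simpson")) {
  stopifnot(inherits(table, "taxa_table"))
  metric <- match.arg(metric)
  m <- table$counts
  cs <- colSums(m)
  if (any(cs == 0)) {
    stop("all-zero sample(s): ",
         paste(table$sample_ids[cs == 0], collapse = ", "), call. = FALSE)
  }
  pr <- sweep(m, 2, cs, "/")
  out <- if (metric == "shannon") {
    apply(pr, 2, function(p) { p <- p[p > 0]; -sum(p * log(p)) })
  } else {
    1 - colSums(pr^2)
  }
  stats::setNames(out, table$sample_ids)
}

new_distance_matrix <- function(values, sample_ids, metric) {
  dimnames(values) <- list(sample_ids, sample_ids)
  structure(list(sample_ids = sample_ids, metric = metric, values = values),
            class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("<distance_matrix> %s over %d samples\n", x$metric,
              length(x$sample_ids)))
  invisible(x)
}

#' Between-sample (beta) diversity
#'
#' * `aitchison`: Euclidean distance between CLR-transformed samples
#'   (requires counts and a pseudocount).
#' * `bray_curtis`: `sum |p_i - q_i| / sum (p_i + q_i)` on proportions.
#' * `unweighted_unifrac`: unshared branch length over total branch length
#'   spanned by either community, presence defined as count >= 1; requires a
#'   rooted tree with branch lengths whose tips cover all taxa with nonzero
#'   counts.
#'
#' @param table a [taxa_table()].
#' @param metric one of `"aitchison"`, `"bray_curtis"`, `"unweighted_unifrac"`.
#' @param pseudocount CLR pseudocount (aitchison only).
#' @param tree an `ape::phylo` tree (unweighted_unifrac only).
#' @return a `distance_matrix` (symmetric, zero diagonal).
#' @export
beta_diversity <- function(table,
                           metric = c("aitchison", "bray_curtis",
                                      "unweighted_unifrac"),
                           pseudocount = 1, tree = NULL) {
  stopifnot(inherits(table, "taxa_table"))
  metric <- match.arg(metric)
  if (metric == "aitchison") {
    d <- as.matrix(stats::dist(t(clr_transform(table, pseudocount))))
    return(new_distance_matrix(d, table$sample_ids, metric))
  }
  if (metric == "bray_curtis") {
    m <- table$counts
    cs <- colSums(m)
    if (any(cs == 0)) stop("all-zero sample(s) present", call. = FALSE)
    pr <- sweep(m, 2, cs, "/")
    n <- ncol(pr)
    d <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      pi <- pr[, i]
      rest <- (i + 1):n
      num <- colSums(abs(pr[, rest, drop = FALSE] - pi))
      den <- colSums(pr[, rest, drop = FALSE] + pi)
      d[i, rest] <- d[rest, i] <- num / den
    }
    return(new_distance_matrix(d, table$sample_ids, metric))
  }
  # unweighted UniFrac
  if (is.null(tree)) stop("unweighted_unifrac requires a tree", call. = FALSE)
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object", call. = FALSE)
  if (is.null(tree$edge.length)) stop("tree must have branch lengths", call. = FALSE)
  present_taxa <- table$taxa_ids[rowSums(table$counts >= 1) > 0]
  missing <- setdiff(present_taxa, tree$tip.label)
  if (length(missing)) {
    stop("taxa with nonzero counts missing from tree: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  d <- unifrac_unweighted(table$counts >= 1, tree)
  new_distance_matrix(d, table$sample_ids, "unweighted_unifrac")
}

# Presence propagation up the tree: each edge contributes its length to the
# "unshared" sum when exactly one community has a tip below it, and to the
# "union" sum when either does.
unifrac_unweighted <- function(presence, tree) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  ns <- ncol(presence)
  node_pres <- matrix(FALSE, nrow = ntip + nnode, ncol = ns)
  idx <- match(tree$tip.label, rownames(presence))
  has <- !is.na(idx)
  node_pres[which(has), ] <- presence[idx[has], , drop = FALSE]
  for (k in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[k, 1]; child <- tree$edge[k, 2]
    node_pres[parent, ] <- node_pres[parent, ] | node_pres[child, ]
  }
  # edge k "contains" sample s iff its child subtree holds a present tip
  M <- node_pres[tree$edge[, 2], , drop = FALSE] * 1
  len <- tree$edge.length
  shared <- crossprod(M, len * M)           # sum len over edges in both
  tot <- colSums(len * M)                   # sum len over edges in each
  either <- outer(tot, tot, "+") - shared
  unshared <- outer(tot, tot, "+") - 2 * shared
  d <- ifelse(either > 0, unshared / either, 0)
  diag(d) <- 0
  dimnames(d) <- NULL
  d
}

#' Principal coordinates analysis (classical metric scaling)
#'
#' Double-centers `-D^2/2`, eigendecomposes, and returns coordinates scaled by
#' the square root of each positive eigenvalue. Axes with negative eigenvalues
#' are discarded; their total magnitude is kept so non-Euclidean metrics
#' (e.g. Bray-Curtis) are explicit about distortion.
#'
#' @param dist a `distance_matrix` (from [beta_diversity()]) or a symmetric
#'   numeric matrix with zero diagonal.
#' @return an object of class `ordination`: `sample_ids`, `coordinates`
#'   (samples x axes), `eigenvalues`, `proportion_explained`,
#'   `negative_eigenvalue_sum`.
#' @export
pcoa <- function(dist) {
  if (inherits(dist, "distance_matrix")) {
    ids <- dist$sample_ids
    D <- dist$values
  } else {
    D <- as.matrix(dist)
    ids <- rownames(D) %||% as.character(seq_len(nrow(D)))
  }
  n <- nrow(D)
  if (n < 3) stop("PCoA needs at least 3 samples", call. = FALSE)
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix is not symmetric", call. = FALSE)
  J <- diag(n) - matrix(1 / n, n, n)
  G <- -0.5 * J %*% (D^2) %*% J
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  tol <- 1e-8 * max(abs(e$values), 1)
  pos <- which(e$values > tol)
  if (!length(pos)) stop("no positive eigenvalues; degenerate distances", call. = FALSE)
  neg_sum <- sum(abs(e$values[e$values < -tol]))
  coords <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(e$values[pos]),
                                                    length(pos))
  rownames(coords) <- ids
  colnames(coords) <- paste0("PCo", seq_along(pos))
  structure(list(sample_ids = ids,
                 coordinates = coords,
                 eigenvalues = e$values[pos],
                 proportion_explained = e$values[pos] / sum(e$values[pos]),
                 negative_eigenvalue_sum = neg_sum),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("<ordination> %d samples, %d axes (first axis %.1f%%)\n",
              length(x$sample_ids), ncol(x$coordinates),
              100 * x$proportion_explained[1]))
  invisible(x)
}

#' Export a distance matrix as square TSV
#'
#' @param dist a `distance_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(dist, path) {
  stopifnot(inherits(dist, "distance_matrix"))
  df <- data.frame(sample_id = dist$sample_ids, dist$values,
                   check.names = FALSE)
  colnames(df) <- c("sample_id", dist$sample_ids)
  write_tsv(df, path)
}
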