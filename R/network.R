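# Interkingdom co-abundance networks: prevalence filtering, Spearman edges,
# connectedness, subgroup comparison, force-directed layout, export.

#' Filter taxa by prevalence
#'
#' Keeps taxa present (count >= 1) in at least `min_prevalence` of samples,
#' boundary inclusive: a taxon seen in 3 of 10 samples passes a 30% filter.
#'
#' @param table a [taxa_table()] with `scale = "counts"`.
#' @param min_prevalence fraction in (0, 1].
#' @return the filtered [taxa_table()], original taxon order preserved;
#'   dropped taxa reported via `message()`.
#' @export
prevalence_filter <- function(table, min_prevalence = 0.30) {
  stopifnot(inherits(table, "taxa_table"))
  if (table$scale != "counts") stop("prevalence filter expects counts", call. = FALSE)
  if (!is.numeric(min_prevalence) || length(min_prevalence) != 1L ||
      min_prevalence <= 0 || min_prevalence > 1) {
    stop("min_prevalence must lie in (0, 1]", call. = FALSE)
  }
  prev <- rowMeans(table$counts >= 1)
  keep <- prev >= min_prevalence - 1e-12
  if (!any(keep)) stop("prevalence filter removed all taxa", call. = FALSE)
  if (any(!keep)) {
    message("prevalence_filter: dropped ", sum(!keep), " of ",
            length(keep), " taxa below ", min_prevalence)
  }
  taxa_table(table$counts[keep, , drop = FALSE], table$kingdom, table$scale)
}

#' Spearman correlation between two abundance vectors
#'
#' Tie-corrected rho (Pearson correlation of average ranks). Two-sided p by
#' exact enumeration over all rank permutations when `n <= exact_n_max` and
#' neither vector has ties; otherwise the t approximation
#' `t = rho * sqrt((n-2)/(1-rho^2))` on `n - 2` df, with `|rho| = 1` mapping
#' to `p = 0` by convention.
#'
#' @param x,y numeric vectors of equal length `n >= 4`, not constant.
#' @param exact_n_max largest n for exact enumeration (default 7; `4! = 24`
#'   through `7! = 5040` orderings).
#' @return named numeric vector `c(rho =, p =)`.
#' @export
spearman_edge <- function(x, y, exact_n_max = 7) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  if (n < 4) stop("need at least 4 paired samples", call. = FALSE)
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    stop("constant vector cannot be ranked", call. = FALSE)
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  p <- if (n <= exact_n_max && !ties) {
    perms <- all_permutations(n)
    rho_perm <- vapply(perms, function(pm) stats::cor(rx, ry[pm]), numeric(1))
    mean(abs(rho_perm) >= abs(rho) - 1e-12)
  } else {
    spearman_t_p(rho, n)
  }
  c(rho = rho, p = p)
}

spearman_t_p <- function(rho, n) {
  out <- rho
  at_one <- abs(rho) >= 1 - 1e-15
  tt <- rho[!at_one] * sqrt((n - 2) / (1 - rho[!at_one]^2))
  out[!at_one] <- 2 * stats::pt(-abs(tt), df = n - 2)
  out[at_one] <- 0
  out
}

#' Build a bipartite interkingdom co-abundance network
#'
#' Each kingdom is prevalence-filtered, abundances are converted to
#' proportions, and a Spearman correlation is computed for every
#' bacteria-by-fungus pair. Edges with (uncorrected, by design) `p < alpha`
#' are retained — fidelity to the reference analysis; see `bh` for an
#' optional corrected mode. Connectedness = number of edges / number of
#' nodes, where the node roster by default contains every filtered taxon of
#' both kingdoms, edge-bearing or not (`node_mode = "all"`); this keeps the
#' statistic comparable across subgroups with identical rosters. The
#' alternative (`"connected"`) counts only edge-bearing taxa.
#'
#' @param bact,fung sample-aligned [taxa_table()]s (identical sample ids in
#'   identical order; use [align_paired()]), `scale = "counts"`.
#' @param alpha edge significance threshold (strict `p < alpha`).
#' @param min_prevalence prevalence filter fraction (default 0.30).
#' @param node_mode `"all"` (default) or `"connected"`.
#' @param relative_within `"full"` (default: proportions computed on the full
#'   table before filtering) or `"filtered"` (renormalized within the
#'   filtered taxon set).
#' @param bh apply Benjamini-Hochberg correction to edge p-values before
#'   thresholding (default FALSE, matching the uncorrected reference method).
#' @return object of class `interkingdom_network`: `nodes` (taxon, kingdom,
#'   degree), `edges` (bact, fung, rho, p, sign), `connectedness`,
#'   `n_samples`, `alpha`, `min_prevalence`, provenance fields.
#' @export
build_network <- function(bact, fung, alpha = 0.05, min_prevalence = 0.30,
                          node_mode = c("all", "connected"),
                          relative_within = c("full", "filtered"),
                          bh = FALSE) {
  stopifnot(inherits(bact, "taxa_table"), inherits(fung, "taxa_table"))
  node_mode <- match.arg(node_mode)
  relative_within <- match.arg(relative_within)
  if (!identical(bact$sample_ids, fung$sample_ids)) {
    stop("tables are not sample-aligned; run align_paired() first", call. = FALSE)
  }
  ns <- length(bact$sample_ids)
  if (ns < 4) stop("need at least 4 shared samples", call. = FALSE)

  bf <- prevalence_filter(bact, min_prevalence)
  ff <- prevalence_filter(fung, min_prevalence)
  rel <- function(full, filt) {
    m <- if (relative_within == "full") {
      to_relative(full)$counts[filt$taxa_ids, , drop = FALSE]
    } else {
      to_relative(filt)$counts
    }
    # constant taxa cannot be ranked; drop them (rare, logged)
    const <- apply(m, 1, function(v) length(unique(v)) < 2)
    if (any(const)) {
      message("build_network: dropped ", sum(const),
              " constant-abundance taxa from ", full$kingdom)
    }
    m[!const, , drop = FALSE]
  }
  mb <- rel(bact, bf)
  mf <- rel(fung, ff)
  if (!nrow(mb) || !nrow(mf)) stop("no usable taxa after filtering", call. = FALSE)

  if (ns <= 7) {
    rho <- matrix(NA_real_, nrow(mb), nrow(mf))
    pmat <- rho
    for (i in seq_len(nrow(mb))) for (j in seq_len(nrow(mf))) {
      e <- spearman_edge(mb[i, ], mf[j, ])
      rho[i, j] <- e[["rho"]]; pmat[i, j] <- e[["p"]]
    }
  } else {
    rb <- apply(mb, 1, rank)   # samples x taxa
    rf <- apply(mf, 1, rank)
    rho <- stats::cor(rb, rf)
    pmat <- spearman_t_p(rho, ns)
  }
  dimnames(rho) <- dimnames(pmat) <- list(rownames(mb), rownames(mf))

  pthresh <- if (bh) matrix(bh_fdr(as.vector(pmat)), nrow = nrow(pmat)) else pmat
  hit <- which(pthresh < alpha, arr.ind = TRUE)
  edges <- data.frame(
    bact = rownames(mb)[hit[, 1]],
    fung = rownames(mf)[hit[, 2]],
    rho = rho[hit],
    p = pmat[hit],
    stringsAsFactors = FALSE
  )
  edges$sign <- ifelse(edges$rho >= 0, "positive", "negative")
  edges <- edges[order(edges$p, edges$bact, edges$fung), , drop = FALSE]
  rownames(edges) <- NULL

  nodes <- data.frame(
    taxon = c(rownames(mb), rownames(mf)),
    kingdom = c(rep("bacteria", nrow(mb)), rep("fungi", nrow(mf))),
    stringsAsFactors = FALSE
  )
  deg <- table(factor(c(edges$bact, edges$fung), levels = nodes$taxon))
  nodes$degree <- as.integer(deg[nodes$taxon])
  if (node_mode == "connected") {
    nodes <- nodes[nodes$degree > 0, , drop = FALSE]
  }
  connectedness <- if (nrow(nodes)) nrow(edges) / nrow(nodes) else NA_real_
  structure(list(nodes = nodes, edges = edges,
                 connectedness = connectedness,
                 n_pairs = nrow(mb) * nrow(mf),
                 n_samples = ns, alpha = alpha,
                 min_prevalence = min_prevalence,
                 node_mode = node_mode, relative_within = relative_within,
                 bh = bh),
            class = "interkingdom_network")
}

#' @export
print.interkingdom_network <- function(x, ...) {
  cat(sprintf(
    "<interkingdom_network> %d nodes (%d bacteria, %d fungi), %d edges, connectedness = %.3f (n = %d samples)\n",
    nrow(x$nodes), sum(x$nodes$kingdom == "bacteria"),
    sum(x$nodes$kingdom == "fungi"), nrow(x$edges), x$connectedness,
    x$n_samples))
  invisible(x)
}

#' Compare connectedness between two networks
#'
#' The statistical unit of a connectedness comparison is an interpretation
#' (the reference analyses report "pairwise t-tests" without one), so two are
#' offered and the chosen unit is recorded in the result:
#'
#' * `"edge_rate"` (default): compares the per-pair edge rates
#'   `|E| / (n_bact x n_fung pairs)` of the two networks with a conditional
#'   binomial mid-p test (given the total edge count, edges fall to network A
#'   with probability `pairs_A / (pairs_A + pairs_B)` under the null); the
#'   accompanying statistic `t` is the two-proportion z score. Under null
#'   simulations this test holds its nominal size.
#' * `"degree"`: Welch two-sample t-test on the per-node interkingdom degree
#'   distributions — the literal "t-test" reading. Degrees within a network
#'   are positively dependent (each edge raises two of them), so this variant
#'   is anti-conservative under the null; it is kept for fidelity and flagged
#'   as such. Degenerate zero-variance cases map to `t = 0, p = 1` when the
#'   means agree and `t = Inf, p = 0` when they do not (Welch df undefined,
#'   reported as `NA`).
#'
#' @param netA,netB `interkingdom_network` objects with >= 2 nodes each.
#' @param unit `"edge_rate"` or `"degree"`.
#' @return list: `t`, `p`, `df` (degree unit only), `connectedness_diff`
#'   (A minus B), `meanA`, `meanB` (mean node degrees), `unit`.
#' @export
compare_connectedness <- function(netA, netB, unit = c("edge_rate", "degree")) {
  stopifnot(inherits(netA, "interkingdom_network"),
            inherits(netB, "interkingdom_network"))
  unit <- match.arg(unit)
  dA <- netA$nodes$degree
  dB <- netB$nodes$degree
  if (length(dA) < 2 || length(dB) < 2) {
    stop("both networks need at least 2 nodes", call. = FALSE)
  }
  if (unit == "edge_rate") {
    eA <- nrow(netA$edges); eB <- nrow(netB$edges)
    pa <- netA$n_pairs; pb <- netB$n_pairs
    tot <- eA + eB
    if (tot == 0) {
      out <- list(t = 0, p = 1, df = NA_real_)
    } else {
      pr <- pa / (pa + pb)
      p_lo <- stats::pbinom(eA - 1, tot, pr) + 0.5 * stats::dbinom(eA, tot, pr)
      p_hi <- 1 - stats::pbinom(eA, tot, pr) + 0.5 * stats::dbinom(eA, tot, pr)
      pool <- tot / (pa + pb)
      z <- (eA / pa - eB / pb) /
        sqrt(max(pool * (1 - pool) * (1 / pa + 1 / pb), .Machine$double.eps))
      out <- list(t = z, p = min(1, 2 * min(p_lo, p_hi)), df = NA_real_)
    }
  } else if (stats::var(dA) == 0 && stats::var(dB) == 0) {
    equal <- mean(dA) == mean(dB)
    t_stat <- if (equal) 0 else Inf * sign(mean(dA) - mean(dB))
    out <- list(t = t_stat, p = if (equal) 1 else 0, df = NA_real_)
  } else {
    ht <- stats::t.test(dA, dB, var.equal = FALSE)
    out <- list(t = unname(ht$statistic), p = ht$p.value,
                df = unname(ht$parameter))
  }
  c(out, list(connectedness_diff = netA$connectedness - netB$connectedness,
              meanA = mean(dA), meanB = mean(dB), unit = unit))
}

#' Force-directed network layout (Fruchterman-Reingold)
#'
#' Standard iteration in the unit square: repulsion `k^2/d` between all node
#' pairs, attraction `d^2/k` along edges, displacement capped by a linearly
#' cooling temperature, fixed iteration count; deterministic given the seed.
#'
#' @param net an `interkingdom_network`.
#' @param seed RNG seed for the initial placement.
#' @param iterations number of cooling steps.
#' @return numeric matrix (nodes x 2) with node names as row names.
#' @export
layout_network <- function(net, seed = 1, iterations = 100) {
  stopifnot(inherits(net, "interkingdom_network"))
  v <- net$nodes$taxon
  n <- length(v)
  if (!n) stop("empty node roster", call. = FALSE)
  pos <- with_seed(seed, matrix(stats::runif(2 * n), ncol = 2))
  rownames(pos) <- v
  if (n == 1L) return(pos)
  k <- sqrt(1 / n)
  ei <- match(net$edges$bact, v)
  ej <- match(net$edges$fung, v)
  temp0 <- 0.1
  for (it in seq_len(iterations)) {
    temp <- temp0 * (1 - (it - 1) / iterations)
    disp <- matrix(0, n, 2)
    for (i in seq_len(n)) {
      delta <- sweep(-pos, 2, -pos[i, ])      # pos[i,] - pos
      d <- pmax(sqrt(rowSums(delta^2)), 1e-9)
      f <- k^2 / d
      f[i] <- 0
      disp[i, ] <- colSums(delta / d * f)
    }
    if (length(ei)) {
      for (e in seq_along(ei)) {
        delta <- pos[ei[e], ] - pos[ej[e], ]
        d <- max(sqrt(sum(delta^2)), 1e-9)
        f <- d^2 / k
        disp[ei[e], ] <- disp[ei[e], ] - delta / d * f
        disp[ej[e], ] <- disp[ej[e], ] + delta / d * f
      }
    }
    dl <- pmax(sqrt(rowSums(disp^2)), 1e-9)
    step <- pmin(dl, temp)
    pos <- pos + disp / dl * step
  }
  stopifnot(all(is.finite(pos)))
  pos
}

#' Export network edges as TSV
#'
#' @param net an `interkingdom_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network_edges <- function(net, path) {
  stopifnot(inherits(net, "interkingdom_network"))
  write_tsv(net$edges, path)
}

#' Export a network as GraphML
#'
#' Nodes carry `kingdom`, edges carry `rho`, `p` and `sign` attributes.
#'
#' @param net an `interkingdom_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(net, path) {
  stopifnot(inherits(net, "interkingdom_network"))
  g <- igraph::graph_from_data_frame(
    d = net$edges[, c("bact", "fung", "rho", "p", "sign"), drop = FALSE],
    directed = FALSE,
    vertices = net$nodes[, c("taxon", "kingdom"), drop = FALSE])
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
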