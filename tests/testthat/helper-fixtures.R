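# Shared fixtures, all built in code.

# small deterministic taxa table: 3 taxa x 4 samples
tiny_table <- function(kingdom = "bacteria") {
  m <- matrix(c(0, 5, 2, 0, 1, 1,
                3, 2, 0, 4, 1, 0), nrow = 3,
              dimnames = list(c("t1", "t2", "t3"),
                              c("S1", "S2", "S3", "S4")))
  taxa_table(m, kingdom = kingdom, scale = "counts")
}

tiny_meta <- function(n_dyads = 4) {
  types <- c("milk", "feces_1mo")
  dyad <- rep(seq_len(n_dyads), each = 2)
  type <- rep(types, n_dyads)
  data.frame(
    sample_id = sprintf("D%02d_%s", dyad, type),
    subject_id = ifelse(type == "milk", sprintf("M%02d", dyad),
                        sprintf("I%02d", dyad)),
    dyad_id = sprintf("D%02d", dyad),
    sample_type = type,
    birth_mode = rep(c("vaginal", "cesarean"), length.out = 2 * n_dyads),
    prenatal_abx = FALSE, perinatal_abx = FALSE,
    maternal_postpartum_abx = FALSE, infant_postnatal_abx = FALSE,
    stringsAsFactors = FALSE
  )
}

# distance_matrix from a plain symmetric matrix
as_distmat <- function(m, ids = rownames(m), metric = "aitchison") {
  dimnames(m) <- list(ids, ids)
  structure(list(sample_ids = ids, metric = metric, values = m),
            class = "distance_matrix")
}

# independent one-factor pseudo-F from a distance matrix (group-sum formula,
# the classic one-way decomposition; used as the PERMANOVA oracle)
oracle_pseudo_f <- function(D, labels) {
  n <- nrow(D)
  a <- length(unique(labels))
  ss_total <- sum(D[upper.tri(D)]^2) / n
  ss_within <- 0
  for (g in unique(labels)) {
    idx <- which(labels == g)
    sub <- D[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(sub[upper.tri(sub)]^2) / length(idx)
  }
  ss_between <- ss_total - ss_within
  (ss_between / (a - 1)) / (ss_within / (n - a))
}

# all distinct orderings of 1..n, independent of dyadnet's internal generator
oracle_permutations <- function(n) {
  grid <- do.call(expand.grid, rep(list(seq_len(n)), n))
  keep <- apply(grid, 1, function(r) length(unique(r)) == n)
  lapply(which(keep), function(i) as.integer(grid[i, ]))
}
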