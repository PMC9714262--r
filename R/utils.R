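# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state so that
#' seeded package functions never perturb the global random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministic per-stage seed derived from one top-level seed; stays < 2^31.
derive_seed <- function(seed, stage_index) {
  as.integer((as.numeric(seed) * 1103L + 12289L * stage_index) %% 2147483647)
}

# TSV writer with fixed settings so reruns are byte-identical.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random derangement (permutation with no fixed point) by rejection sampling.
# Expected number of attempts is ~e, independent of n (n >= 2).
random_derangement <- function(n) {
  if (n < 2L) stop("a derangement requires at least 2 elements", call. = FALSE)
  repeat {
    p <- sample.int(n)
    if (all(p != seq_len(n))) return(p)
  }
}

# All permutations of seq_len(n) as a list; used for exact enumeration (n <= 7).
all_permutations <- function(n) {
  stopifnot(n >= 1L, n <= 8L)
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) {
    for (pos in seq_len(n)) {
      k <- k + 1L
      out[[k]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}
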