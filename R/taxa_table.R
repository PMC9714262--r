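# Data model: taxa-by-sample count tables and sample metadata.

#' Construct a taxa table
#'
#' The in-memory form of a processed amplicon table for one kingdom:
#' taxa in rows (taxonomy labels; genus level for bacteria, species level for
#' fungi), samples in columns, non-negative counts or relative abundances.
#'
#' @param counts numeric matrix, taxa x samples, with row and column names.
#' @param kingdom `"bacteria"` or `"fungi"`.
#' @param scale `"counts"` (integer or derived reads) or `"relative"`
#'   (every sample column sums to 1).
#' @return an object of class `taxa_table` with fields `kingdom`, `taxa_ids`,
#'   `sample_ids`, `counts`, `scale`.
#' @export
taxa_table <- function(counts, kingdom = c("bacteria", "fungi"),
                       scale = c("counts", "relative")) {
  kingdom <- match.arg(kingdom)
  scale <- match.arg(scale)
  counts <- as.matrix(counts)
  if (!is.numeric(counts)) stop("counts must be numeric", call. = FALSE)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must carry taxa row names and sample column names", call. = FALSE)
  }
  if (nrow(counts) < 1L) stop("need at least 1 taxon", call. = FALSE)
  if (ncol(counts) < 2L) stop("need at least 2 samples", call. = FALSE)
  dup_t <- unique(rownames(counts)[duplicated(rownames(counts))])
  if (length(dup_t)) {
    stop("duplicate taxa ids: ", paste(dup_t, collapse = ", "), call. = FALSE)
  }
  dup_s <- unique(colnames(counts)[duplicated(colnames(counts))])
  if (length(dup_s)) {
    stop("duplicate sample ids: ", paste(dup_s, collapse = ", "), call. = FALSE)
  }
  if (anyNA(counts)) stop("counts contain missing values", call. = FALSE)
  neg <- which(counts < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stop(sprintf("negative value at taxon '%s', sample '%s'",
                 rownames(counts)[neg[1, 1]], colnames(counts)[neg[1, 2]]),
         call. = FALSE)
  }
  if (scale == "relative") {
    cs <- colSums(counts)
    bad <- which(abs(cs - 1) > 1e-9)
    if (length(bad)) {
      stop("relative-scale columns must sum to 1; offending sample(s): ",
           paste(colnames(counts)[bad], collapse = ", "), call. = FALSE)
    }
  }
  structure(
    list(kingdom = kingdom,
         taxa_ids = rownames(counts),
         sample_ids = colnames(counts),
         counts = counts,
         scale = scale),
    class = "taxa_table"
  )
}

#' @export
print.taxa_table <- function(x, ...) {
  cat(sprintf("<taxa_table> %s: %d taxa x %d samples (%s scale)\n",
              x$kingdom, length(x$taxa_ids), length(x$sample_ids), x$scale))
  invisible(x)
}

#' @export
dim.taxa_table <- function(x) dim(x$counts)

#' Read a taxa-by-sample count table from TSV
#'
#' First column holds taxon labels, remaining columns one sample each, with a
#' header row of sample ids. Values may be integer reads or decimals.
#'
#' @param path file path.
#' @param kingdom `"bacteria"` or `"fungi"`.
#' @param drop_zero_samples drop all-zero sample columns with a warning
#'   (default TRUE) instead of erroring later in `to_relative()`.
#' @return a [taxa_table()] with `scale = "counts"`, input ordering preserved.
#' @export
read_taxa_table <- function(path, kingdom = c("bacteria", "fungi"),
                            drop_zero_samples = TRUE) {
  kingdom <- match.arg(kingdom)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) != 1L) {
    stop("ragged rows in ", path, ": field counts ",
         paste(unique(nf), collapse = ", "), call. = FALSE)
  }
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("need a taxon column plus at least 2 samples", call. = FALSE)
  sample_ids <- colnames(df)[-1]
  dup_s <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup_s)) {
    stop("duplicate sample ids in header: ", paste(dup_s, collapse = ", "),
         call. = FALSE)
  }
  taxa <- as.character(df[[1]])
  dup_t <- unique(taxa[duplicated(taxa)])
  if (length(dup_t)) {
    stop("duplicate taxa ids: ", paste(dup_t, collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric count values in ", path, call. = FALSE)
  rownames(m) <- taxa
  if (drop_zero_samples) {
    zero <- colSums(m) == 0
    if (any(zero)) {
      warning("dropping all-zero sample(s): ",
              paste(colnames(m)[zero], collapse = ", "), call. = FALSE)
      m <- m[, !zero, drop = FALSE]
    }
  }
  taxa_table(m, kingdom = kingdom, scale = "counts")
}

#' Write a taxa table to TSV
#'
#' Inverse of [read_taxa_table()]; the round trip is bit-stable for integer
#' counts.
#'
#' @param table a [taxa_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_taxa_table <- function(table, path) {
  stopifnot(inherits(table, "taxa_table"))
  df <- data.frame(taxon = table$taxa_ids, table$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("taxon", table$sample_ids)
  write_tsv(df, path)
}

#' Import a taxa table from a BIOM file
#'
#' Thin wrapper over the `biomformat` package (optional dependency).
#'
#' @inheritParams read_taxa_table
#' @return a [taxa_table()] with `scale = "counts"`.
#' @export
read_taxa_table_biom <- function(path, kingdom = c("bacteria", "fungi")) {
  kingdom <- match.arg(kingdom)
  if (!requireNamespace("biomformat", quietly = TRUE)) {
    stop("BIOM import requires the 'biomformat' package", call. = FALSE)
  }
  b <- biomformat::read_biom(path)
  m <- as(biomformat::biom_data(b), "matrix")
  taxa_table(m, kingdom = kingdom, scale = "counts")
}

#' Convert counts to relative abundances
#'
#' @param table a [taxa_table()] with `scale = "counts"`.
#' @return a [taxa_table()] with `scale = "relative"`; each sample column
#'   divided by its total.
#' @export
to_relative <- function(table) {
  stopifnot(inherits(table, "taxa_table"))
  if (table$scale != "counts") stop("table is already on the relative scale", call. = FALSE)
  cs <- colSums(table$counts)
  zero <- which(cs == 0)
  if (length(zero)) {
    stop("all-zero sample(s): ", paste(table$sample_ids[zero], collapse = ", "),
         "; drop them before normalizing", call. = FALSE)
  }
  taxa_table(sweep(table$counts, 2, cs, "/"), kingdom = table$kingdom,
             scale = "relative")
}

#' Restrict paired kingdom tables to their shared samples
#'
#' Network analyses only admit samples with both bacterial and fungal data and
#' metadata; everything else is dropped and the per-reason counts reported.
#'
#' @param bact,fung [taxa_table()] objects for the two kingdoms.
#' @param meta sample metadata data frame (see [read_sample_metadata()]).
#' @return list with elements `bacteria`, `fungi` (identical sample ordering),
#'   `metadata` (matching rows), and `dropped` (named counts per reason).
#' @export
align_paired <- function(bact, fung, meta) {
  stopifnot(inherits(bact, "taxa_table"), inherits(fung, "taxa_table"))
  shared <- intersect(bact$sample_ids, fung$sample_ids)
  kept <- shared[shared %in% meta$sample_id]
  if (!length(kept)) stop("no samples shared by both kingdoms and metadata", call. = FALSE)
  dropped <- c(
    missing_fungal = sum(!(bact$sample_ids %in% fung$sample_ids)),
    missing_bacterial = sum(!(fung$sample_ids %in% bact$sample_ids)),
    missing_metadata = sum(!(shared %in% meta$sample_id))
  )
  if (sum(dropped) > 0) {
    message(sprintf(
      "align_paired: kept %d samples; dropped %d without fungal data, %d without bacterial data, %d without metadata",
      length(kept), dropped[["missing_fungal"]], dropped[["missing_bacterial"]],
      dropped[["missing_metadata"]]))
  }
  b <- taxa_table(bact$counts[, kept, drop = FALSE], bact$kingdom, bact$scale)
  f <- taxa_table(fung$counts[, kept, drop = FALSE], fung$kingdom, fung$scale)
  stopifnot(identical(b$sample_ids, f$sample_ids))
  list(bacteria = b, fungi = f,
       metadata = meta[match(kept, meta$sample_id), , drop = FALSE],
       dropped = dropped)
}

SAMPLE_TYPES <- c("milk", "feces_1mo", "feces_6mo")
BIRTH_MODES <- c("vaginal", "cesarean")
ABX_FLAGS <- c("prenatal_abx", "perinatal_abx",
               "maternal_postpartum_abx", "infant_postnatal_abx")
META_REQUIRED <- c("sample_id", "subject_id", "dyad_id", "sample_type",
                   "birth_mode", ABX_FLAGS)

parse_flag <- function(x, column) {
  v <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(v))
  out[v %in% c("1", "true", "yes")] <- TRUE
  out[v %in% c("0", "false", "no")] <- FALSE
  bad <- which(is.na(out) & !is.na(v) & v != "na" & v != "")
  if (length(bad)) {
    stop(sprintf("column '%s': unparseable boolean value '%s'", column, v[bad[1]]),
         call. = FALSE)
  }
  out
}

#' Read sample metadata from TSV
#'
#' Mandatory columns: `sample_id`, `subject_id`, `dyad_id`, `sample_type`
#' (`milk`, `feces_1mo`, `feces_6mo`), `birth_mode` (`vaginal`, `cesarean`),
#' and four antibiotic exposure flags (`prenatal_abx`, `perinatal_abx`,
#' `maternal_postpartum_abx`, `infant_postnatal_abx`). Flags accept
#' 0/1, true/false, yes/no, case-insensitively. Extra columns pass through as
#' free covariates.
#'
#' @param path file path.
#' @return a data frame, one row per sample.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  validate_metadata(df)
}

#' Validate a sample metadata data frame
#'
#' @param df data frame with the columns described in [read_sample_metadata()].
#' @return the validated data frame with parsed flag columns.
#' @export
validate_metadata <- function(df) {
  missing_cols <- setdiff(META_REQUIRED, colnames(df))
  if (length(missing_cols)) {
    stop("metadata missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup)) {
    stop("duplicate sample_id in metadata: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  bad_type <- setdiff(unique(df$sample_type), SAMPLE_TYPES)
  if (length(bad_type)) {
    stop("invalid sample_type value(s): ", paste(bad_type, collapse = ", "),
         call. = FALSE)
  }
  bad_mode <- setdiff(unique(df$birth_mode), BIRTH_MODES)
  if (length(bad_mode)) {
    stop("invalid birth_mode value(s): ", paste(bad_mode, collapse = ", "),
         call. = FALSE)
  }
  for (fl in ABX_FLAGS) df[[fl]] <- parse_flag(df[[fl]], fl)
  df
}
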