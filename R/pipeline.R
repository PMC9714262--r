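# Pipeline orchestration: one config drives load -> diversity -> ordination ->
# PERMANOVA -> dyad test -> Procrustes -> networks -> differential abundance.

RUN_CONFIG_SCHEMA <- "1"

run_config_defaults <- function() {
  list(
    schema_version = RUN_CONFIG_SCHEMA,
    bact_table = NULL,
    fung_table = NULL,
    metadata = NULL,
    tree = NULL,
    output_dir = NULL,
    seed = 1,
    pseudocount = 1,
    beta_metric = "aitchison",
    alpha = 0.05,
    min_prevalence = 0.30,
    n_perm = 999,
    procrustes_n_perm = 999,
    dyad_repetitions = 100,
    permanova_terms = c("birth_mode", "perinatal_abx"),
    subgroups = c("birth_mode", "perinatal_abx", "maternal_postpartum_abx"),
    diffabund_variable = "birth_mode",
    exclude_taxa = character(0),
    node_mode = "all",
    relative_within = "full"
  )
}

#' Build a validated pipeline run configuration
#'
#' Every stage's seed derives deterministically from the single top-level
#' `seed` (no wall-clock seeding), so stages can be rerun in isolation and a
#' rerun of the whole pipeline is byte-identical. Unknown keys are rejected.
#'
#' @param ... named configuration values; see `dyadnet:::run_config_defaults()`
#'   for the full key list and defaults. `bact_table`, `fung_table` and
#'   `metadata` (input paths) are mandatory.
#' @return a list of class `run_config`.
#' @export
run_config <- function(...) {
  user <- list(...)
  defaults <- run_config_defaults()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, user)
  if (!identical(as.character(cfg$schema_version), RUN_CONFIG_SCHEMA)) {
    stop("unsupported config schema_version: ", cfg$schema_version, call. = FALSE)
  }
  for (key in c("bact_table", "fung_table", "metadata")) {
    if (is.null(cfg[[key]])) stop("config requires '", key, "'", call. = FALSE)
  }
  stopifnot(cfg$alpha > 0, cfg$alpha < 1,
            cfg$min_prevalence > 0, cfg$min_prevalence <= 1,
            cfg$pseudocount > 0, cfg$n_perm >= 1, cfg$dyad_repetitions >= 1)
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file path.
#' @return a validated `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  # JSON nulls / empty objects come back as zero-length values: drop them so
  # defaults apply, except for keys that are legitimately empty vectors
  keep_empty <- c("exclude_taxa", "subgroups")
  raw <- raw[vapply(names(raw), function(k) {
    k %in% keep_empty || length(raw[[k]]) > 0
  }, logical(1))]
  if ("exclude_taxa" %in% names(raw)) {
    raw$exclude_taxa <- as.character(unlist(raw$exclude_taxa))
  }
  if ("subgroups" %in% names(raw)) {
    raw$subgroups <- as.character(unlist(raw$subgroups))
  }
  do.call(run_config, raw)
}

#' Write a pipeline configuration to JSON
#'
#' @param config a `run_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

subset_taxa_table <- function(table, sample_ids) {
  taxa_table(table$counts[, sample_ids, drop = FALSE], table$kingdom, table$scale)
}

#' Run the full analysis pipeline
#'
#' Executes all stages in dependency order and writes TSV results plus a run
#' manifest to the output directory. A failing subgroup analysis is recorded
#' in the manifest and does not abort independent stages.
#'
#' @param config a `run_config` or path to a config JSON.
#' @param out_dir output directory (default: `config$output_dir`).
#' @return invisibly, the manifest data frame, with attribute `n_errors`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  out_dir <- out_dir %||% config$output_dir
  if (is.null(out_dir)) stop("no output directory given", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  cfg_path <- file.path(out_dir, "run_config.json")
  write_run_config(config, cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))

  manifest <- list()
  note_stage <- function(stage, file, status, note = "") {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = stage, file = file, status = status, note = note,
      stringsAsFactors = FALSE)
  }
  run_stage <- function(stage, file, fun) {
    tryCatch({
      fun()
      note_stage(stage, file, "ok")
    }, error = function(e) {
      note_stage(stage, file, "error", conditionMessage(e))
    })
  }

  # ---- load + align -------------------------------------------------------
  bact <- read_taxa_table(config$bact_table, "bacteria")
  fung <- read_taxa_table(config$fung_table, "fungi")
  meta <- read_sample_metadata(config$metadata)
  if (length(config$exclude_taxa)) {
    bact <- taxa_table(bact$counts[!(bact$taxa_ids %in% config$exclude_taxa), ,
                                   drop = FALSE], "bacteria")
    fung <- taxa_table(fung$counts[!(fung$taxa_ids %in% config$exclude_taxa), ,
                                   drop = FALSE], "fungi")
  }
  aligned <- align_paired(bact, fung, meta)
  bact <- aligned$bacteria; fung <- aligned$fungi; meta <- aligned$metadata
  message(sprintf("run_pipeline: analyzing %d paired samples (dropped: %s)",
                  length(bact$sample_ids),
                  paste(names(aligned$dropped), aligned$dropped,
                        sep = "=", collapse = ", ")))
  kingdoms <- list(bacteria = bact, fungi = fung)
  seeds <- stats::setNames(
    vapply(1:6, function(i) derive_seed(config$seed, i), integer(1)),
    c("permanova", "dyad", "procrustes", "network", "layout", "spare"))

  # ---- alpha diversity ----------------------------------------------------
  run_stage("alpha_diversity", "alpha_diversity.tsv", function() {
    rows <- do.call(rbind, lapply(names(kingdoms), function(kg) {
      tb <- kingdoms[[kg]]
      data.frame(sample_id = tb$sample_ids, kingdom = kg,
                 shannon = alpha_diversity(tb, "shannon"),
                 simpson = alpha_diversity(tb, "simpson"),
                 stringsAsFactors = FALSE)
    }))
    write_tsv(rows, file.path(out_dir, "alpha_diversity.tsv"))
  })

  # ---- beta diversity + ordination ---------------------------------------
  tree <- if (!is.null(config$tree)) ape::read.tree(config$tree) else NULL
  dists <- list()
  ords <- list()
  for (kg in names(kingdoms)) {
    d <- beta_diversity(kingdoms[[kg]], config$beta_metric,
                        pseudocount = config$pseudocount, tree = tree)
    dists[[kg]] <- d
    run_stage(paste0("beta_", kg), paste0("distance_", kg, ".tsv"), function() {
      write_distance_matrix(d, file.path(out_dir, paste0("distance_", kg, ".tsv")))
    })
    ords[[kg]] <- pcoa(d)
    run_stage(paste0("pcoa_", kg), paste0("pcoa_", kg, ".tsv"), function() {
      co <- ords[[kg]]$coordinates
      write_tsv(data.frame(sample_id = rownames(co), co, check.names = FALSE),
                file.path(out_dir, paste0("pcoa_", kg, ".tsv")))
    })
  }

  # ---- PERMANOVA per sample type and kingdom ------------------------------
  run_stage("permanova", "permanova.tsv", function() {
    rows <- list()
    for (kg in names(kingdoms)) {
      for (st in unique(meta$sample_type)) {
        sub_ids <- meta$sample_id[meta$sample_type == st]
        res <- tryCatch({
          dsub <- dists[[kg]]$values[sub_ids, sub_ids, drop = FALSE]
          r <- permanova(new_distance_matrix(dsub, sub_ids, dists[[kg]]$metric),
                         meta, config$permanova_terms,
                         n_perm = config$n_perm, seed = seeds[["permanova"]])
          df <- as.data.frame(r)
          df$kingdom <- kg; df$sample_type <- st; df$status <- "ok"
          df
        }, error = function(e) {
          data.frame(term = NA, df = NA, SS = NA, F = NA, p = NA,
                     kingdom = kg, sample_type = st,
                     status = paste("skipped:", conditionMessage(e)),
                     stringsAsFactors = FALSE)
        })
        rows[[length(rows) + 1L]] <- res
      }
    }
    write_tsv(do.call(rbind, rows), file.path(out_dir, "permanova.tsv"))
  })

  # ---- dyad similarity ----------------------------------------------------
  run_stage("dyad_test", "dyad_test.tsv", function() {
    rows <- list()
    for (kg in names(kingdoms)) {
      for (ft in intersect(c("feces_1mo", "feces_6mo"), meta$sample_type)) {
        res <- tryCatch({
          r <- dyad_distance_test(dists[[kg]], meta, ft,
                                  n_repetitions = config$dyad_repetitions,
                                  seed = seeds[["dyad"]])
          data.frame(kingdom = kg, fecal_type = ft, n_dyads = r$n_dyads,
                     perm_p = r$perm_p, median_p = r$median_p,
                     fraction_significant = r$fraction_significant,
                     pooled_p = r$pooled_p, status = "ok",
                     stringsAsFactors = FALSE)
        }, error = function(e) {
          data.frame(kingdom = kg, fecal_type = ft, n_dyads = NA,
                     perm_p = NA, median_p = NA, fraction_significant = NA,
                     pooled_p = NA,
                     status = paste("skipped:", conditionMessage(e)),
                     stringsAsFactors = FALSE)
        })
        rows[[length(rows) + 1L]] <- res
      }
    }
    write_tsv(do.call(rbind, rows), file.path(out_dir, "dyad_test.tsv"))
  })

  # ---- Procrustes per sample type ----------------------------------------
  run_stage("procrustes", "procrustes.tsv", function() {
    rows <- list()
    for (st in unique(meta$sample_type)) {
      sub_ids <- meta$sample_id[meta$sample_type == st]
      res <- tryCatch({
        oa <- pcoa(new_distance_matrix(
          dists$bacteria$values[sub_ids, sub_ids, drop = FALSE], sub_ids,
          dists$bacteria$metric))
        ob <- pcoa(new_distance_matrix(
          dists$fungi$values[sub_ids, sub_ids, drop = FALSE], sub_ids,
          dists$fungi$metric))
        r <- procrustes_test(oa, ob, n_perm = config$procrustes_n_perm,
                             seed = seeds[["procrustes"]])
        data.frame(sample_type = st, m2 = r$m2, t = r$t, p = r$p,
                   n_axes = r$n_axes, n_samples = r$n_samples, status = "ok",
                   stringsAsFactors = FALSE)
      }, error = function(e) {
        data.frame(sample_type = st, m2 = NA, t = NA, p = NA, n_axes = NA,
                   n_samples = NA, status = paste("skipped:", conditionMessage(e)),
                   stringsAsFactors = FALSE)
      })
      rows[[length(rows) + 1L]] <- res
    }
    write_tsv(do.call(rbind, rows), file.path(out_dir, "procrustes.tsv"))
  })

  # ---- interkingdom networks ---------------------------------------------
  run_stage("networks", "connectedness_summary.tsv", function() {
    summary_rows <- list()
    compare_rows <- list()
    build_one <- function(ids, label) {
      if (length(ids) < 4) stop("fewer than 4 samples in ", label)
      net <- build_network(subset_taxa_table(bact, ids),
                           subset_taxa_table(fung, ids),
                           alpha = config$alpha,
                           min_prevalence = config$min_prevalence,
                           node_mode = config$node_mode,
                           relative_within = config$relative_within)
      write_network_edges(net, file.path(out_dir,
                                         paste0("network_edges_", label, ".tsv")))
      net
    }
    for (st in unique(meta$sample_type)) {
      st_ids <- meta$sample_id[meta$sample_type == st]
      net_all <- tryCatch(build_one(st_ids, st), error = function(e) e)
      if (inherits(net_all, "error")) {
        summary_rows[[length(summary_rows) + 1L]] <- data.frame(
          sample_type = st, subgroup = "all", level = "all", n_samples = length(st_ids),
          n_nodes = NA, n_edges = NA, connectedness = NA,
          status = paste("skipped:", conditionMessage(net_all)),
          stringsAsFactors = FALSE)
        next
      }
      summary_rows[[length(summary_rows) + 1L]] <- data.frame(
        sample_type = st, subgroup = "all", level = "all",
        n_samples = net_all$n_samples, n_nodes = nrow(net_all$nodes),
        n_edges = nrow(net_all$edges), connectedness = net_all$connectedness,
        status = "ok", stringsAsFactors = FALSE)
      for (sg in config$subgroups) {
        lv <- meta[[sg]][match(st_ids, meta$sample_id)]
        nets <- list()
        for (level in sort(unique(as.character(lv[!is.na(lv)])))) {
          ids <- st_ids[!is.na(lv) & as.character(lv) == level]
          label <- paste(st, sg, level, sep = "_")
          net <- tryCatch(build_one(ids, label), error = function(e) e)
          if (inherits(net, "error")) {
            summary_rows[[length(summary_rows) + 1L]] <- data.frame(
              sample_type = st, subgroup = sg, level = level,
              n_samples = length(ids), n_nodes = NA, n_edges = NA,
              connectedness = NA,
              status = paste("skipped:", conditionMessage(net)),
              stringsAsFactors = FALSE)
          } else {
            nets[[level]] <- net
            summary_rows[[length(summary_rows) + 1L]] <- data.frame(
              sample_type = st, subgroup = sg, level = level,
              n_samples = net$n_samples, n_nodes = nrow(net$nodes),
              n_edges = nrow(net$edges), connectedness = net$connectedness,
              status = "ok", stringsAsFactors = FALSE)
          }
        }
        if (length(nets) == 2) {
          cmp <- tryCatch(compare_connectedness(nets[[1]], nets[[2]]),
                          error = function(e) NULL)
          if (!is.null(cmp)) {
            compare_rows[[length(compare_rows) + 1L]] <- data.frame(
              sample_type = st, subgroup = sg,
              levelA = names(nets)[1], levelB = names(nets)[2],
              t = cmp$t, p = cmp$p,
              connectedness_diff = cmp$connectedness_diff,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    write_tsv(do.call(rbind, summary_rows),
              file.path(out_dir, "connectedness_summary.tsv"))
    if (length(compare_rows)) {
      write_tsv(do.call(rbind, compare_rows),
                file.path(out_dir, "network_comparisons.tsv"))
    }
  })

  # ---- differential abundance --------------------------------------------
  run_stage("diffabund", "diffabund.tsv", function() {
    rows <- list()
    for (kg in names(kingdoms)) {
      for (st in unique(meta$sample_type)) {
        ids <- meta$sample_id[meta$sample_type == st]
        res <- tryCatch({
          df <- diff_abundance(subset_taxa_table(kingdoms[[kg]], ids), meta,
                               config$diffabund_variable)
          df$kingdom <- kg; df$sample_type <- st; df$status <- "ok"
          df
        }, error = function(e) NULL)
        if (!is.null(res)) rows[[length(rows) + 1L]] <- res
      }
    }
    if (!length(rows)) stop("no differential-abundance contrast was testable")
    write_tsv(do.call(rbind, rows), file.path(out_dir, "diffabund.tsv"))
  })

  manifest <- do.call(rbind, manifest)
  manifest$config_hash <- cfg_hash
  manifest$seed <- config$seed
  write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  n_errors <- sum(manifest$status == "error")
  if (n_errors) {
    warning(n_errors, " pipeline stage(s) errored; see manifest.tsv", call. = FALSE)
  }
  attr(manifest, "n_errors") <- n_errors
  invisible(manifest)
}

#' Write a small synthetic demo cohort and a matching run config
#'
#' Generates a <= 60-dyad cohort with planted interkingdom edges and a birth
#' mode effect, writes count tables, metadata and a `run_config` JSON to
#' `dir`, sized so that [run_pipeline()] completes in well under 5 minutes on
#' one CPU.
#'
#' @param dir output directory.
#' @param seed top-level seed.
#' @param n_dyads cohort size (default 20).
#' @return path to the written config JSON.
#' @export
make_demo <- function(dir, seed = 1, n_dyads = 20) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  planted <- data.frame(bact = c(1, 2, 3), fung = c(1, 2, 3),
                        rho = c(0.8, 0.8, -0.8))
  cfg <- cohort_config(
    n_dyads = n_dyads, n_bact = 15, n_fung = 10,
    planted_edges = planted, dyad_effect_sd = 0.5,
    covariate_effects = list(
      covariate_effect("birth_mode",
                       taxa_log_fc = c(bact004 = 1.0, fung004 = -1.0))),
    seed = derive_seed(seed, 101))
  cohort <- generate_cohort(cfg)
  bact_path <- file.path(dir, "bacteria_counts.tsv")
  fung_path <- file.path(dir, "fungi_counts.tsv")
  meta_path <- file.path(dir, "metadata.tsv")
  write_taxa_table(cohort$bacteria, bact_path)
  write_taxa_table(cohort$fungi, fung_path)
  meta <- cohort$metadata
  for (fl in ABX_FLAGS) meta[[fl]] <- as.integer(meta[[fl]])
  write_tsv(meta, meta_path)
  run_cfg <- run_config(
    bact_table = bact_path, fung_table = fung_path, metadata = meta_path,
    output_dir = file.path(dir, "results"), seed = seed,
    n_perm = 199, procrustes_n_perm = 199, dyad_repetitions = 50,
    permanova_terms = "birth_mode",
    subgroups = "birth_mode")
  cfg_path <- file.path(dir, "demo_config.json")
  write_run_config(run_cfg, cfg_path)
  cfg_path
}
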