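#' Run the whole analysis pipeline from one configuration
#'
#' Executes the fixed stage order
#' simulate/load -> prepare (singleton removal, rarefaction at 95% of the
#' minimum depth) -> diversity -> assembly -> classify -> discriminate,
#' writing each stage's outputs to its own sub-directory of `out_dir` and a
#' reproducibility manifest (`manifest.json`) recording the configuration
#' snapshot, the master seed, the per-stage derived seeds, file digests,
#' package version and per-stage wall-clock. A failing stage leaves earlier
#' outputs in place and is named in the manifest.
#'
#' The configuration is a YAML file (or an equivalent named list) with one
#' block per stage. Exactly one of `input:` (paths `feature_table`,
#' `taxonomy`, `metadata`) or `simulate:` (fields of [simulation_config()]
#' plus optional `n_tail`, `theta`, `inject: {individuals, per_individual,
#' rel_abundance}`) must be present. Optional blocks `prepare:`
#' (`fraction`), `assembly:` (`n_null`), `classify:` (`top_k`, `ntree`,
#' `train_fraction`, `individual_aware`), `discriminate:`
#' (`rank_threshold`, `habitat`) override stage defaults.
#'
#' @param config Path to a YAML configuration file, or a named list.
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed; overrides the config's `seed` field.
#' @return The manifest, invisibly, as a named list.
#' @export
run_all <- function(config, out_dir, seed = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  known <- c("input", "simulate", "prepare", "diversity", "assembly",
             "classify", "discriminate", "seed")
  bad <- setdiff(names(cfg), known)
  if (length(bad) > 0) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  has_input <- !is.null(cfg$input)
  has_sim <- !is.null(cfg$simulate)
  if (has_input && has_sim) {
    stop("config has both an input block and a simulate block; ",
         "the data source is ambiguous", call. = FALSE)
  }
  if (!has_input && !has_sim) {
    stop("config needs either an input block or a simulate block", call. = FALSE)
  }
  if (has_input) {
    for (f in c("feature_table", "taxonomy", "metadata")) {
      if (is.null(cfg$input[[f]]) || !file.exists(cfg$input[[f]])) {
        stop("missing input file for '", f, "'", call. = FALSE)
      }
    }
  }
  seed <- as.integer(seed %||% cfg$seed %||% 1L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  stages <- c("simulate", "prepare", "diversity", "assembly", "classify",
              "discriminate")
  manifest <- list(
    config = cfg, master_seed = seed,
    stage_seeds = stats::setNames(
      lapply(stages, function(s) substream_seed(seed, s)), stages),
    package_version = as.character(utils::packageVersion("oralsite")),
    stages = list(), outputs = list(), failed_stage = NULL)

  env <- new.env()
  for (stage in stages) {
    t0 <- Sys.time()
    ok <- tryCatch({
      do.call(paste0("stage_", stage),
              list(cfg = cfg, env = env, out = file.path(out_dir, stage),
                   seed = substream_seed(seed, stage)))
      TRUE
    }, error = function(e) {
      warning("stage '", stage, "' failed: ", conditionMessage(e),
              call. = FALSE)
      FALSE
    })
    manifest$stages[[stage]] <- list(
      status = if (ok) "ok" else "failed",
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    if (!ok) {
      manifest$failed_stage <- stage
      break
    }
  }

  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest$outputs <- as.list(tools::md5sum(files))
  names(manifest$outputs) <- sub(paste0("^", out_dir, "/?"), "",
                                 names(manifest$outputs))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}

stage_simulate <- function(cfg, env, out, seed) {
  dir.create(out, showWarnings = FALSE)
  if (!is.null(cfg$input)) {
    env$table <- read_feature_table(cfg$input$feature_table)
    env$taxonomy <- read_taxonomy(cfg$input$taxonomy)
    env$metadata <- read_metadata(cfg$input$metadata)
  } else {
    sc <- cfg$simulate
    prof <- default_profiles(n_tail = sc$n_tail %||% 300L,
                             theta = sc$theta %||% 5)
    config <- simulation_config(
      n_individuals = sc$n_individuals %||% 50L,
      depth_range = unlist(sc$depth_range %||% c(50201L, 199533L)),
      seed = seed)
    sim <- generate_paired_study(config, prof$saliva, prof$mucosa)
    env$table <- sim$table
    env$taxonomy <- sim$taxonomy
    env$metadata <- sim$metadata
    if (!is.null(sc$inject)) {
      inj <- inject_unique_species(
        env$table, env$metadata,
        individuals = sc$inject$individuals %||% NULL,
        per_individual = sc$inject$per_individual %||% 1L,
        rel_abundance = sc$inject$rel_abundance %||% 1e-4,
        seed = seed)
      env$table <- inj$table
      env$taxonomy <- dplyr::bind_rows(env$taxonomy, inj$taxonomy_extra)
      jsonlite::write_json(inj$truth, file.path(out, "planted_truth.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  write_feature_table(env$table, file.path(out, "feature_table.tsv"))
  write_taxonomy(env$taxonomy, file.path(out, "taxonomy.tsv"))
  write_metadata(env$metadata, file.path(out, "metadata.tsv"))
}

stage_prepare <- function(cfg, env, out, seed) {
  dir.create(out, showWarnings = FALSE)
  tab <- remove_singletons(env$table)
  depth <- rarefaction_depth(tab, fraction = cfg$prepare$fraction %||% 0.95)
  env$rarefied <- rarefy(tab, depth, seed = seed)
  env$metadata <- env$metadata[env$metadata$sample_id %in%
                                 rownames(env$rarefied), ]
  env$depth <- depth
  jsonlite::write_json(list(depth = depth,
                            n_samples = nrow(env$rarefied),
                            n_features = ncol(env$rarefied)),
                       file.path(out, "prepare.json"), auto_unbox = TRUE)
  write_feature_table(env$rarefied, file.path(out, "table_rarefied.tsv"))
}

stage_diversity <- function(cfg, env, out, seed) {
  dir.create(out, showWarnings = FALSE)
  alpha <- alpha_diversity(env$rarefied)
  readr::write_tsv(alpha, file.path(out, "alpha_diversity.tsv"))

  sh <- stats::setNames(alpha$shannon, alpha$sample_id)
  tests <- compare_groups(sh, env$metadata)
  readr::write_tsv(tests, file.path(out, "shannon_habitat_test.tsv"))
  if ("age" %in% names(env$metadata) && !all(is.na(env$metadata$age))) {
    readr::write_tsv(spearman_age(sh, env$metadata),
                     file.path(out, "shannon_age_spearman.tsv"))
  }

  rel <- to_relative(env$rarefied)
  dm <- bray_curtis(rel)
  utils::write.table(dm, file.path(out, "bray_curtis.tsv"), sep = "\t",
                     quote = FALSE, col.names = NA)
  ord <- nmds_ordination(dm, seed = seed)
  readr::write_tsv(dplyr::mutate(ord$points, stress = ord$stress),
                   file.path(out, "nmds.tsv"))

  for (rank in c("phylum", "genus")) {
    coll <- collapse_taxa(env$rarefied, env$taxonomy, rank)
    da <- differential_abundance(to_relative(coll), env$metadata)
    readr::write_tsv(da, file.path(out, paste0("differential_", rank, ".tsv")))
  }
}

stage_assembly <- function(cfg, env, out, seed) {
  dir.create(out, showWarnings = FALSE)
  groups <- split(env$metadata$sample_id, env$metadata$habitat)
  groups$pooled <- env$metadata$sample_id
  fits <- lapply(names(groups), function(g) {
    fit <- fit_ncm(env$rarefied[groups[[g]], , drop = FALSE])
    readr::write_tsv(tidy(fit), file.path(out, paste0("ncm_", g, ".tsv")))
    cbind(group = g, glance(fit))
  })
  readr::write_tsv(dplyr::bind_rows(fits), file.path(out, "ncm_summary.tsv"))

  nm <- null_model(env$rarefied, env$metadata,
                   n_null = cfg$assembly$n_null %||% 999, seed = seed)
  readr::write_tsv(glance(nm), file.path(out, "null_model.tsv"))
  jsonlite::write_json(glance(nm), file.path(out, "null_model.json"),
                       auto_unbox = TRUE, digits = NA)
}

stage_classify <- function(cfg, env, out, seed) {
  dir.create(out, showWarnings = FALSE)
  cc <- cfg$classify
  rep <- classify_habitat(env$rarefied, env$metadata,
                          train_fraction = cc$train_fraction %||% 0.7,
                          top_k = cc$top_k %||% 30,
                          ntree = cc$ntree %||% 500,
                          individual_aware = isTRUE(cc$individual_aware),
                          seed = seed)
  readr::write_tsv(tidy(rep), file.path(out, "importance_topk.tsv"))
  readr::write_tsv(rep$confusion, file.path(out, "confusion.tsv"))
  jsonlite::write_json(as.list(glance(rep)), file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA)
}

stage_discriminate <- function(cfg, env, out, seed) {
  dir.create(out, showWarnings = FALSE)
  dc <- cfg$discriminate
  rep <- discriminate_individuals(env$rarefied, env$taxonomy, env$metadata,
                                  rank_threshold = dc$rank_threshold %||% 100,
                                  habitat = dc$habitat %||% "saliva")
  readr::write_tsv(tidy(rep), file.path(out, "unique_species.tsv"))
  readr::write_tsv(tibble::tibble(core_taxon = rep$core),
                   file.path(out, "core_taxa.tsv"))
  if (!is.null(rep$code)) {
    utils::write.table(rep$code, file.path(out, "microbial_code.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
  }
  jsonlite::write_json(as.list(glance(rep)), file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA)
}
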