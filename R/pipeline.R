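# End-to-end orchestration: curate -> fingerprints -> cluster/AD -> train ->
# screen -> report, from a single YAML-able configuration with one global
# seed fanned out deterministically to every stochastic stage.

#' Default pipeline configuration
#'
#' @param output_dir where stage artifacts are written.
#' @param seed global seed; per-stage seeds are derived from it by salting
#'   with the stage name, so stages can be re-run in isolation.
#' @return nested configuration list (YAML-serializable).
#' @export
default_run_config <- function(output_dir = tempfile("qsarscreen_run_"),
                               seed = 1L) {
  list(
    seed = as.integer(seed),
    output_dir = output_dir,
    synthetic = list(enabled = TRUE, n_total = 3000L, active_fraction = 0.014,
                     label_noise = 0.01),
    input = list(training_table = NULL, format = NULL),
    descriptors = list(families = "morgan", morgan_bits = 1024L,
                       morgan_radius = 2L),
    split = list(test_fraction = 0.03),
    clustering = list(sim_cutoff = 0.35, ad_threshold = 0.195,
                      n_target_clusters = 4L),
    model = list(family = "rf", n_trees = 500L),
    screening = list(enabled = TRUE, library = NULL, n_library = 200L,
                     n_hits_planted = 2L, n_unrelated = 30L,
                     p_threshold = 0.64, ad_threshold = 0.195,
                     docking_table = NULL)
  )
}

stage_seed <- function(global_seed, stage) {
  as.integer((as.numeric(global_seed) * 7919 + .hash_string(stage, 2147483629)) %%
               2147483647)
}

#' Validate a pipeline configuration
#'
#' @param config configuration list (see [default_run_config]) or a path to a
#'   YAML file.
#' @return character vector of issues (empty when runnable); each issue names
#'   the offending field.
#' @export
validate_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  issues <- character(0)
  add <- function(msg) issues <<- c(issues, msg)
  if (is.null(config$seed) || is.na(suppressWarnings(as.integer(config$seed))) ||
      config$seed < 0) add("seed: must be a non-negative integer")
  known <- c("maccs", "morgan", "pathfp", "d2d", "autocorr3d", "morse", "rdf",
             "whim", "voxel")
  fams <- config$descriptors$families
  if (is.null(fams) || !all(fams %in% known)) {
    add(paste0("descriptors.families: unknown family (",
               paste(setdiff(fams, known), collapse = ", "), ")"))
  }
  adt <- config$clustering$ad_threshold
  if (!is.null(adt) && (adt <= 0 || adt >= 1)) {
    add("clustering.ad_threshold: must be in (0,1)")
  }
  pt <- config$screening$p_threshold
  if (!is.null(pt) && (pt < 0 || pt > 1)) {
    add("screening.p_threshold: must be in [0,1]")
  }
  sat <- config$screening$ad_threshold
  if (!is.null(sat) && (sat <= 0 || sat >= 1)) {
    add("screening.ad_threshold: must be in (0,1)")
  }
  tf <- config$split$test_fraction
  if (!is.null(tf) && (tf <= 0 || tf >= 1)) {
    add("split.test_fraction: must be in (0,1)")
  }
  if (!isTRUE(config$synthetic$enabled)) {
    tt <- config$input$training_table
    if (is.null(tt)) add("input.training_table: required when synthetic data is disabled")
    else if (!file.exists(tt)) add("input.training_table: file not found")
  }
  if (isTRUE(config$screening$enabled) && !is.null(config$screening$library) &&
      !file.exists(config$screening$library)) {
    add("screening.library: file not found")
  }
  dt <- config$screening$docking_table
  if (!is.null(dt) && !file.exists(dt)) add("screening.docking_table: file not found")
  if (!config$model$family %in% c("rf", "svm", "mlp")) {
    add("model.family: must be rf, svm or mlp")
  }
  issues
}

pipeline_log <- function(con, stage, event, ...) {
  line <- sprintf("[%s] %s: %s", stage, event, sprintf(...))
  message(line)
  if (!is.null(con)) writeLines(line, con)
}

#' Run the full screening pipeline
#'
#' Executes curation, fingerprinting, clustering with applicability-domain
#' pruning, model training with out-of-bag validation, library screening and
#' report writing, leaving all artifacts plus a machine-readable provenance
#' manifest under `config$output_dir`.  Re-running with an identical
#' configuration reproduces the random-forest out-of-bag confusion matrix
#' exactly.
#'
#' @param config configuration list or YAML path (see [default_run_config]).
#' @return the output directory, invisibly; the manifest lives at
#'   `<output_dir>/manifest.json`.
#' @export
run_pipeline <- function(config = default_run_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  issues <- validate_run_config(config)
  if (length(issues) > 0L) {
    stop("invalid configuration:\n  ", paste(issues, collapse = "\n  "))
  }
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file(file.path(config$output_dir, "run.log"), open = "wt")
  on.exit(close(logfile))
  manifest <- list(config = config, stages = list(),
                   package_version = as.character(utils::packageVersion("qsarscreen")))
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s (artifacts kept in %s)",
                   stage, conditionMessage(e), config$output_dir), call. = FALSE)
    })
  }

  # -- curate
  records <- run_stage("curate", {
    if (isTRUE(config$synthetic$enabled)) {
      ds <- generate_dataset(synthetic_spec(
        n_total = config$synthetic$n_total,
        active_fraction = config$synthetic$active_fraction,
        label_noise = config$synthetic$label_noise,
        seed = stage_seed(config$seed, "synthetic")))
      utils::write.csv(ds$records, file.path(config$output_dir, "raw.csv"),
                       row.names = FALSE)
      ds$records
    } else {
      parsed <- parse_molecule_table(config$input$training_table,
                                     config$input$format)
      utils::write.csv(parsed$rejects, file.path(config$output_dir, "rejects.csv"),
                       row.names = FALSE)
      parsed$records
    }
  })
  records <- run_stage("standardize", standardize_records(records))
  dd <- run_stage("deduplicate", deduplicate_records(records))
  records <- rbind(dd$records, resolve_conflicts(dd$conflicts, "drop"))
  utils::write.csv(records, file.path(config$output_dir, "curated.csv"),
                   row.names = FALSE)
  pipeline_log(logfile, "curate", "done", "%d curated records (%d conflicts dropped)",
               nrow(records), length(dd$conflicts))
  manifest$stages$curate <- list(n_records = nrow(records),
                                 n_conflicts = length(dd$conflicts),
                                 artifact = "curated.csv")

  # -- split
  split <- run_stage("split", split_dataset(
    records, test_fraction = config$split$test_fraction,
    seed = stage_seed(config$seed, "split")))
  jsonlite::write_json(list(train = split$train, test1 = split$test1,
                            test2 = split$test2, seed = split$seed),
                       file.path(config$output_dir, "split.json"))
  train <- records[records$id %in% split$train, , drop = FALSE]
  test1 <- records[records$id %in% split$test1, , drop = FALSE]
  manifest$stages$split <- list(n_train = nrow(train), n_test1 = nrow(test1),
                                artifact = "split.json")

  # -- descriptors
  feats <- run_stage("featurize", assemble_descriptor_matrix(
    records, families = config$descriptors$families,
    morgan_bits = config$descriptors$morgan_bits,
    morgan_radius = config$descriptors$morgan_radius))
  fps <- run_stage("featurize", fp_morgan(records$smiles,
                                          n_bits = config$descriptors$morgan_bits,
                                          radius = config$descriptors$morgan_radius,
                                          ids = records$id))
  pipeline_log(logfile, "featurize", "done", "%d x %d descriptor matrix",
               nrow(feats), ncol(feats))
  manifest$stages$featurize <- list(n_columns = ncol(feats),
                                    families = config$descriptors$families)

  # -- cluster + AD
  cm <- run_stage("cluster", {
    m <- cluster_dataset(fps[train$id, , drop = FALSE],
                         smiles = stats::setNames(train$smiles, train$id),
                         n_target_clusters = config$clustering$n_target_clusters,
                         sim_cutoff = config$clustering$sim_cutoff,
                         ad_threshold = config$clustering$ad_threshold)
    prune_to_x(m, fps[train$id, , drop = FALSE],
               threshold = config$clustering$ad_threshold,
               smiles = stats::setNames(train$smiles, train$id))
  })
  write_cluster_model(cm, file.path(config$output_dir, "cluster_model.json"))
  manifest$stages$cluster <- list(sizes = as.list(table(cm$labels)),
                                  artifact = "cluster_model.json")

  # -- train + validate
  model <- run_stage("train", qsar_train(
    feats[train$id, , drop = FALSE], train$label,
    family = config$model$family,
    seed = stage_seed(config$seed, "train")))
  metrics <- list()
  if (config$model$family == "rf") metrics$oob <- as.data.frame(oob_metrics(model))
  test_pred <- predict(model, feats[test1$id, , drop = FALSE], type = "class")
  metrics$test1 <- as.data.frame(confusion_metrics(test1$label, test_pred))
  mtab <- do.call(rbind, metrics)
  utils::write.csv(cbind(set = names(metrics), mtab),
                   file.path(config$output_dir, "metrics.csv"), row.names = FALSE)
  pipeline_log(logfile, "train", "done", "%s model; test1 MCC=%.3f",
               config$model$family, metrics$test1$mcc)
  manifest$stages$train <- c(list(family = config$model$family,
                                  artifact = "metrics.csv"),
                             list(metrics = metrics))

  # -- screen
  if (isTRUE(config$screening$enabled)) {
    run_stage("screen", {
      if (is.null(config$screening$library)) {
        lib <- generate_screen_library(
          n_total = config$screening$n_library,
          n_hits_planted = config$screening$n_hits_planted,
          n_unrelated = config$screening$n_unrelated,
          seed = stage_seed(config$seed, "library"))$records
      } else {
        lib <- parse_molecule_table(config$screening$library)$records
      }
      lib_feats <- assemble_descriptor_matrix(
        lib, families = config$descriptors$families,
        morgan_bits = config$descriptors$morgan_bits,
        morgan_radius = config$descriptors$morgan_radius)
      lib_fps <- fp_morgan(lib$smiles, n_bits = config$descriptors$morgan_bits,
                           radius = config$descriptors$morgan_radius,
                           ids = lib$id)
      dock <- if (!is.null(config$screening$docking_table)) {
        ingest_docking_scores(config$screening$docking_table)
      } else NULL
      hits <- screen_library(model, lib_feats, lib_fps, cm,
                             config = screening_config(
                               p_threshold = config$screening$p_threshold,
                               ad_threshold = config$screening$ad_threshold),
                             docking = dock,
                             smiles = stats::setNames(lib$smiles, lib$id))
      write_screening_report(hits, file.path(config$output_dir, "screening"))
      pipeline_log(logfile, "screen", "done", "%d/%d passed",
                   sum(hits$passed), nrow(hits))
      manifest$stages$screen <- list(n_library = nrow(hits),
                                     n_passed = sum(hits$passed),
                                     artifact = "screening/screening_hits.csv")
    })
  }

  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(config$output_dir)
}
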