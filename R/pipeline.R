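#' Default pipeline configuration
#'
#' One list drives the four stages (separability -> classification -> CASA
#' -> SDM) plus synthetic-data generation; any subset of stages can be
#' enabled. Seeds are per stage so changing one stage's seed leaves earlier
#' stages bit-identical.
#'
#' @param out_dir output directory for stage artifacts and the manifest.
#' @param seed master seed (stage seeds derive from it unless overridden).
#' @param stages character vector of stages to run, in pipeline order.
#' @param truth_args arguments passed to [synth_truth()].
#' @param n_per_class ground-sample counts per class (defaults follow the
#'   survey design: cropland 43, forest 53, urban 45, water 28, target 39).
#' @param min_distance minimum sample spacing, metres.
#' @param n_trees,target_class classifier settings.
#' @param sdm_args arguments for [generate_sdm_inputs()].
#' @param stage_seeds optional named list overriding the derived seed of a
#'   stage (`samples`, `rf`, `sdm`, `sdm_reps`); changing one stage's seed
#'   leaves earlier stages bit-identical.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = tempfile("run"), seed = 1,
                            stages = c("synth", "separability", "classify",
                                       "casa", "sdm"),
                            truth_args = list(),
                            n_per_class = c(urban = 45, waterbody = 28,
                                            cropland = 43,
                                            other_forests = 53,
                                            e_ulmoides = 39),
                            min_distance = 20,
                            n_trees = 500,
                            target_class = "e_ulmoides",
                            sdm_args = list(n_occurrences = 120,
                                            n_background = 2000),
                            stage_seeds = list()) {
  structure(list(out_dir = out_dir, seed = seed, stages = stages,
                 truth_args = truth_args, n_per_class = n_per_class,
                 min_distance = min_distance, n_trees = n_trees,
                 target_class = target_class, sdm_args = sdm_args,
                 stage_seeds = stage_seeds),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#' @param config a `pipeline_config`.
#' @param path YAML path.
#' @return the path (write) / the config (read).
#' @export
write_pipeline_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$n_per_class <- as.list(cfg$n_per_class)   # keep names in YAML
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$n_per_class)) cfg$n_per_class <- unlist(cfg$n_per_class)
  do.call(pipeline_config, cfg[intersect(names(cfg),
                                         names(formals(pipeline_config)))])
}

stage_log <- function(log, stage, t0, files) {
  c(log, list(list(stage = stage,
                   seconds = round(as.numeric(Sys.time()) - t0, 3),
                   artifacts = files)))
}

#' Run the pipeline end-to-end from one configuration
#'
#' Executes the enabled stages in order on synthetic inputs, writing every
#' stage artifact under `config$out_dir` and returning (and writing) a
#' manifest with file hashes, seeds and the winning choices. Re-running an
#' unchanged configuration reproduces identical artifact hashes.
#'
#' @param config a [pipeline_config()].
#' @return the manifest, invisibly; written as `manifest.json`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  truth <- do.call(synth_truth, c(list(seed = config$seed),
                                  config$truth_args))
  manifest <- list(seed = config$seed, stages = config$stages,
                   results = list())
  seed_for <- function(tag) {
    if (!is.null(config$stage_seeds[[tag]])) config$stage_seeds[[tag]]
    else sub_seed(config$seed, tag)
  }
  files <- character(0)
  log <- list()

  put_csv <- function(df, name) {
    p <- file.path(config$out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    files <<- c(files, p)
    p
  }

  scenes <- NULL; samples <- NULL
  if ("synth" %in% config$stages) {
    t0 <- as.numeric(Sys.time())
    scenes <- generate_scenes(truth)
    samples <- sample_points(truth$labels, config$n_per_class,
                             config$min_distance,
                             seed = seed_for("samples"))
    put_csv(samples, "samples.csv")
    log <- stage_log(log, "synth", t0, "samples.csv")
  }

  best_date <- utils::tail(truth$dates, 1)
  if ("separability" %in% config$stages) {
    t0 <- as.numeric(Sys.time())
    rep <- separability_report(scenes, samples,
                               band_combinations("combinations"),
                               target_class = config$target_class)
    put_csv(rep, "separability.csv")
    best_date <- as.character(select_optimal_window(rep))
    manifest$results$best_date <- best_date
    log <- stage_log(log, "separability", t0, "separability.csv")
  }

  winner_fit <- NULL; winner_combo <- NULL; class_map <- NULL
  if ("classify" %in% config$stages) {
    t0 <- as.numeric(Sys.time())
    cmp <- evaluate_combinations(
      scenes[[best_date]], samples, band_combinations("models"),
      classifier_config(n_trees = config$n_trees,
                        seed = seed_for("rf")),
      target_class = config$target_class)
    put_csv(cmp$table, "model_comparison.csv")
    winner_combo <- band_combinations("models")[[cmp$winner]]
    winner_fit <- cmp$fits[[cmp$winner]]
    class_map <- classify_raster(winner_fit, scenes[[best_date]],
                                 winner_combo)
    manifest$results$winning_model <- cmp$winner
    manifest$results$winning_oa <- cmp$table$oa[cmp$table$model == cmp$winner]
    log <- stage_log(log, "classify", t0, "model_comparison.csv")
  }

  if ("casa" %in% config$stages) {
    t0 <- as.numeric(Sys.time())
    climate <- generate_climate(truth)
    ndvi <- generate_ndvi_series(truth)
    veg <- if (!is.null(class_map)) class_map else truth$labels
    casa <- casa_annual(ndvi, climate, veg)
    grading <- classify_npp(casa$annual)
    target_code <- match(config$target_class, attr(veg, "classes"))
    mask <- veg$values == target_code
    carbon <- total_carbon(casa$annual, mask)
    put_csv(data.frame(grade = seq_along(grading$labels),
                       label = grading$labels,
                       upper_break = c(grading$breaks, NA)),
            "npp_grades.csv")
    manifest$results$total_carbon_t <- carbon
    manifest$results$npp_breaks <- grading$breaks
    log <- stage_log(log, "casa", t0, "npp_grades.csv")
  }

  if ("sdm" %in% config$stages) {
    t0 <- as.numeric(Sys.time())
    inputs <- do.call(generate_sdm_inputs,
                      c(list(truth = truth,
                             seed = seed_for("sdm")),
                        config$sdm_args))
    pres <- grid_extract(inputs$bioclim, inputs$presence$x, inputs$presence$y)
    bg <- grid_extract(inputs$bioclim, inputs$background$x,
                       inputs$background$y)
    reps <- maxent_replicates(pres, bg,
                              seed = seed_for("sdm_reps"))
    fit <- maxent_fit(pres, bg)
    prob <- maxent_predict_logistic(fit, inputs$bioclim)
    zoning <- classify_suitability(prob, "fixed_breaks")
    areas <- area_by_class(zoning$grades, resolution_km = truth$res / 1000)
    imp <- variable_importance(fit, pres, bg, "percent_contribution")
    put_csv(data.frame(replicate = seq_along(reps$auc), auc = reps$auc),
            "sdm_auc.csv")
    put_csv(imp, "sdm_contribution.csv")
    put_csv(areas, "sdm_areas.csv")
    manifest$results$mean_auc <- reps$mean_auc
    manifest$results$top_variable <-
      imp$variable[which.max(imp$percent_contribution)]
    log <- stage_log(log, "sdm", t0,
                     c("sdm_auc.csv", "sdm_contribution.csv",
                       "sdm_areas.csv"))
  }

  manifest$log <- log
  manifest$artifacts <- lapply(files, function(p) {
    list(file = basename(p), md5 = unname(tools::md5sum(p)))
  })
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
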