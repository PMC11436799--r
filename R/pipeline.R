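# End-to-end orchestration: generate or load a survey, fit the yield model,
# decompose gaps, attribute and cluster, map hotspots, score scenarios, and
# write every stage's output plus a reproducibility manifest.

#' Pipeline configuration
#'
#' Collects paths, seed, and stage parameters. Either `generator` is given
#' (a [generator_config()] or argument list, and the landscape is generated
#' in memory) or `survey_csv` points at a survey table on disk. The single
#' `seed` fans out to per-stage seeds by fixed offsets (+1 model fit, +2
#' attribution background, +3 generator when it has no seed of its own), so
#' a stage rerun in isolation reproduces its in-pipeline result.
#'
#' @param out_dir output directory for stage CSVs and the manifest.
#' @param generator optional [generator_config()] or list of its arguments.
#' @param survey_csv,district_areas_csv input CSVs when not generating.
#' @param seed master seed.
#' @param num_trees,min_node_size,bg_size,decile,band_km,alpha stage
#'   parameters (see the stage functions).
#' @param scenarios integer vector of scenario ids to evaluate.
#' @param prices price list passed to [scenario_spec()].
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            generator = NULL,
                            survey_csv = NULL,
                            district_areas_csv = NULL,
                            seed = 1L,
                            num_trees = 500,
                            min_node_size = 50,
                            bg_size = 100,
                            decile = 0.10,
                            band_km = 10,
                            alpha = 0.05,
                            scenarios = 1:4,
                            prices = list()) {
  structure(list(out_dir = out_dir, generator = generator,
                 survey_csv = survey_csv,
                 district_areas_csv = district_areas_csv,
                 seed = as.integer(seed), num_trees = num_trees,
                 min_node_size = min_node_size, bg_size = bg_size,
                 decile = decile, band_km = band_km, alpha = alpha,
                 scenarios = scenarios, prices = prices),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Flat YAML keys mirroring [pipeline_config()] arguments; a `generator`
#' mapping is passed to [generator_config()].
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

stage_write <- function(df, dir, name, manifest) {
  path <- file.path(dir, name)
  write.csv(as.data.frame(df), path, row.names = FALSE)
  c(manifest, setNames(name, sub("[.]csv$", "", name)))
}

#' Run the full yield-gap pipeline
#'
#' Stages, in order: data (generate or read + validate), attainable yield,
#' model fit, permutation importance + sequential ICE decomposition,
#' Shapley attribution + co-limitation clusters, Gi* hotspots for the
#' irrigation and N attributions, and the configured scenarios. Each stage
#' writes a deterministically named CSV under `out_dir`; preconditions
#' (e.g. district areas present when scenarios are enabled) are checked
#' before any model is fitted, and a stage failure aborts with the stage
#' name. Rerunning with the same config and seed reproduces all outputs
#' bitwise.
#'
#' @param config a [pipeline_config()].
#' @return the run manifest (named list: seed, config hash, package
#'   version, stage outputs), also written as `manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "configuration"
  fail <- function(e) abort(paste0("pipeline stage '", stage, "' failed: ",
                                   conditionMessage(e)))
  withCallingHandlers({
    # -- preconditions, before any expensive work
    if (is.null(config$generator) && is.null(config$survey_csv)) {
      abort("config needs either a generator or a survey_csv")
    }
    if (length(config$scenarios) > 0 && is.null(config$generator) &&
        is.null(config$district_areas_csv)) {
      abort("scenario stage enabled but no district_areas_csv given")
    }

    manifest_files <- character()
    schema <- survey_schema()

    stage <- "data"
    if (!is.null(config$generator)) {
      gcfg <- config$generator
      if (!inherits(gcfg, "generator_config")) {
        gcfg <- as.list(gcfg)
        if (is.null(gcfg$seed)) gcfg$seed <- config$seed + 3L
        gcfg <- do.call(generator_config, gcfg)
      }
      land <- generate_survey(gcfg)
      survey <- land$survey
      areas <- land$district_areas
      manifest_files <- stage_write(land$ground_truth, config$out_dir,
                                    "ground_truth.csv", manifest_files)
    } else {
      survey <- read_survey(config$survey_csv, schema)
      areas <- if (!is.null(config$district_areas_csv)) {
        read_district_areas(config$district_areas_csv)
      } else NULL
    }
    manifest_files <- stage_write(survey, config$out_dir, "survey.csv",
                                  manifest_files)

    stage <- "attainable_yield"
    gs <- attainable_yield(survey, config$decile)
    manifest_files <- stage_write(gs$gaps, config$out_dir, "yield_gaps.csv",
                                  manifest_files)

    stage <- "yield_model"
    fm <- encode_features(survey, schema)
    model <- fit_yield_model(fm, survey$yield_obs,
                             num_trees = config$num_trees,
                             min_node_size = config$min_node_size,
                             seed = config$seed + 1L)

    stage <- "decomposition"
    imp <- permutation_importance(model, fm, survey$yield_obs,
                                  seed = config$seed + 1L,
                                  features = schema$management)
    manifest_files <- stage_write(imp, config$out_dir, "importance.csv",
                                  manifest_files)
    dec <- decompose_sequential(model, fm, ranking = imp, schema = schema,
                                table = survey)
    manifest_files <- stage_write(dec, config$out_dir, "decomposition.csv",
                                  manifest_files)

    stage <- "shap"
    shap <- shap_values(model, fm, bg_size = config$bg_size,
                        seed = config$seed + 2L)
    shap_df <- as.data.frame(shap$phi)
    shap_df <- cbind(field_id = as.character(survey$field_id), shap_df)
    manifest_files <- stage_write(shap_df, config$out_dir,
                                  "shap_values.csv", manifest_files)
    clusters <- assign_clusters(shap, districts = survey$district)
    cl_df <- tibble(field_id = as.character(survey$field_id),
                    district = survey$district,
                    label = as.character(clusters$labels),
                    phi_irrigation = clusters$phi_irrigation,
                    phi_n = clusters$phi_n)
    manifest_files <- stage_write(cl_df, config$out_dir, "clusters.csv",
                                  manifest_files)

    stage <- "hotspot"
    hot <- bind_rows(lapply(c("n_rate", "irrigation_count"), function(v) {
      h <- classify_hotspots(
        gi_star(survey$lat, survey$lon, shap$phi[, v], config$band_km),
        alpha = config$alpha)
      cbind(field_id = as.character(survey$field_id), variable = v,
            as.data.frame(h))
    }))
    manifest_files <- stage_write(hot, config$out_dir, "hotspots.csv",
                                  manifest_files)

    stage <- "scenarios"
    for (id in config$scenarios) {
      spec <- scenario_spec(id, prices = config$prices)
      ap <- apply_scenario(survey, spec, clusters)
      res <- evaluate_scenario(model, survey, ap$modified, areas, spec,
                               mask = ap$mask)
      out <- bind_rows(res$district,
                       mutate(res$total, district = "TOTAL",
                              .before = 1))
      out$nue <- res$nue
      manifest_files <- stage_write(out, config$out_dir,
                                    sprintf("scenario_%d.csv", id),
                                    manifest_files)
    }

    stage <- "manifest"
    # hash the scientific configuration, not where the outputs happen to go
    cfg_for_hash <- unclass(config)
    cfg_for_hash$out_dir <- NULL
    manifest <- list(package = "paddygap",
                     version = as.character(utils::packageVersion("paddygap")),
                     seed = config$seed,
                     config_hash = rlang::hash(cfg_for_hash),
                     model_r2 = model$r2,
                     outputs = as.list(manifest_files))
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    manifest
  }, error = fail)
}
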