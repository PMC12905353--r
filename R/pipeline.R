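#' Pipeline run configuration
#'
#' Collects every knob of an end-to-end run into one serialisable object:
#' the RNG seed, grid shape, ground-truth parameters of the synthetic data,
#' the ignition-threshold percentile, the scenario shift table and the
#' experiment selection. A persisted configuration re-runs to identical
#' outputs.
#'
#' @param seed Integer master seed for all stochastic stages.
#' @param nlon,nlat,resolution,lat_min Grid shape (see [fire_grid()]).
#' @param spatial_scale Predictor autocorrelation length, cells.
#' @param truth A [ground_truth()].
#' @param threshold_percentile Percentile of the zero-cell fitted
#'   distribution defining the ignition threshold.
#' @param curve_percentiles Percentiles evaluated in the skill curve.
#' @param shifts Scenario shift table (per-RCP list; see
#'   [default_scenario_shifts()]).
#' @param experiments Experiment labels to run (subset of
#'   realistic/climate_only/co2_only/climate_co2/human_only; may be empty).
#' @param out_dir Output directory (`NULL` = no files written).
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 1, nlon = 40, nlat = 20, resolution = 0.5,
                       lat_min = -nlat * resolution / 2, spatial_scale = 4,
                       truth = default_ground_truth(),
                       threshold_percentile = 0.5,
                       curve_percentiles = c(0.1, 0.25, 0.5, 0.75, 0.9),
                       shifts = list(
                         "RCP2.6" = default_scenario_shifts("RCP2.6"),
                         "RCP6.0" = default_scenario_shifts("RCP6.0")),
                       experiments = experiment_labels(),
                       out_dir = NULL) {
  bad <- setdiff(experiments, experiment_labels())
  if (length(bad)) stop("unknown experiment label(s): ",
                        paste(bad, collapse = ", "))
  if (threshold_percentile <= 0 || threshold_percentile >= 1)
    stop("threshold_percentile must lie in (0, 1)")
  structure(list(seed = as.integer(seed), nlon = nlon, nlat = nlat,
                 resolution = resolution, lat_min = lat_min,
                 spatial_scale = spatial_scale, truth = truth,
                 threshold_percentile = threshold_percentile,
                 curve_percentiles = curve_percentiles, shifts = shifts,
                 experiments = experiments, out_dir = out_dir),
            class = "run_config")
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full fire-regime pipeline
#'
#' Executes, in order: simulate (synthetic dataset with known truth), fit
#' (the three GLMs), threshold (ignition threshold + skill curve), project
#' (scenario bundle and factorial experiment matrix), predict (gated fire
#' properties per experiment), attribute (per-cell driver decomposition of
#' the realistic experiments) and report (summary tables; written as CSV
#' when the configuration names an output directory, along with a JSON
#' manifest of file hashes). A stage failure propagates with the stage name;
#' outputs of completed stages are left intact.
#'
#' @param config A [run_config()].
#' @return List of class `pipeline_run`: `config`, `dataset`, `models`,
#'   `threshold` (report + curve), `bundle`, `experiments`, `predictions`
#'   (per-experiment summaries), `attribution` (per RCP), `tables` (the
#'   report data.frames) and `manifest`.
#' @export
#' @examples
#' \donttest{
#' run <- run_pipeline(run_config(seed = 1, nlon = 24, nlat = 12))
#' run$tables$tss
#' }
run_pipeline <- function(config = run_config()) {
  if (!inherits(config, "run_config")) config <- do.call(run_config, config)

  dataset <- pipeline_stage("simulate", {
    grid <- fire_grid(config$nlon, config$nlat, config$resolution,
                      lat_min = config$lat_min)
    generate_dataset(grid, config$truth, seed = config$seed,
                     spatial_scale = config$spatial_scale)
  })

  models <- pipeline_stage("fit", list(
    BA = fit_fire_glm(dataset$predictors, dataset$fire$BA, "BA"),
    FS = fit_fire_glm(dataset$predictors, dataset$fire$FS, "FS"),
    FI = fit_fire_glm(dataset$predictors, dataset$fire$FI, "FI")
  ))

  threshold <- pipeline_stage("threshold", {
    fitted_BA <- predict(models$BA)
    list(report = derive_threshold(fitted_BA, dataset$fire$BA,
                                   config$threshold_percentile),
         curve = tss_curve(fitted_BA, dataset$fire$BA,
                           config$curve_percentiles),
         fitted_BA = fitted_BA)
  })

  bundle <- pipeline_stage("project", {
    generate_scenario(dataset$predictors, shifts = config$shifts,
                      seed = config$seed + 1000L)
  })
  experiments <- pipeline_stage("project", {
    keep <- build_experiment_matrix(bundle)
    keep[vapply(keep, function(e) e$label %in% config$experiments, TRUE)]
  })

  predictions <- pipeline_stage("predict", {
    thr <- threshold$report$threshold
    lapply(experiments, function(e) {
      BA <- predict(models$BA, e$predictors)
      FS <- predict(models$FS, e$predictors)
      FI <- predict(models$FI, e$predictors)
      gate <- apply_threshold(BA, FS, FI, thr)
      list(label = e$label, rcp = e$rcp, gcm = e$gcm,
           BA = BA, FS = gate$FS, FI = gate$FI,
           unburnt_pct = gate$unburnt_pct)
    })
  })

  attribution <- pipeline_stage("attribute", {
    out <- list()
    for (r in bundle$rcps) {
      real <- Filter(function(e) e$label == "realistic" && e$rcp == r,
                     experiments)
      if (!length(real)) next
      Xmean <- Reduce(`+`, lapply(real, `[[`, "predictors")) / length(real)
      out[[r]] <- predictor_contributions(models$BA, bundle$baseline, Xmean)
    }
    out
  })

  tables <- pipeline_stage("report", {
    pipeline_tables(dataset, models, threshold, bundle, experiments,
                    predictions, attribution)
  })

  run <- structure(list(config = config, dataset = dataset, models = models,
                        threshold = threshold, bundle = bundle,
                        experiments = experiments, predictions = predictions,
                        attribution = attribution, tables = tables,
                        manifest = NULL),
                   class = "pipeline_run")
  if (!is.null(config$out_dir)) run <- pipeline_report(run, config$out_dir)
  run
}

# assemble the report tables (threshold skill; biome burnt area; FS/FI
# sensitivity to the threshold percentile; per-experiment summary)
pipeline_tables <- function(dataset, models, threshold, bundle, experiments,
                            predictions, attribution) {
  tss_tab <- threshold$curve

  # mean realistic BA per RCP (across GCM members)
  ba_rcp <- list()
  for (r in bundle$rcps) {
    idx <- vapply(predictions, function(p)
      p$label == "realistic" && p$rcp == r, TRUE)
    if (any(idx))
      ba_rcp[[r]] <- Reduce(`+`, lapply(predictions[idx], `[[`, "BA")) /
        sum(idx)
  }
  ba_modern <- inverse_link(models$BA, predict(models$BA, type = "link"))
  biome_tab <- biome_aggregate(ba_modern, dataset$biome, dataset$grid)
  names(biome_tab)[-1] <- paste0("modern_", c("km2", "pct"))
  for (r in names(ba_rcp)) {
    agg <- biome_aggregate(ba_rcp[[r]], dataset$biome, dataset$grid)
    key <- if (r == "RCP2.6") "high_mitigation" else "low_mitigation"
    biome_tab[[paste0(key, "_km2")]] <- agg$burnt_area_km2
    biome_tab[[paste0(key, "_pct")]] <- agg$global_pct
  }

  # threshold-sensitivity table (25th/50th/75th percentile thresholds)
  sens_rows <- list()
  for (p in c(0.25, 0.5, 0.75)) {
    thr <- derive_threshold(threshold$fitted_BA, dataset$fire$BA,
                            p)$threshold
    scen <- c(list(Modern = list(BA = ba_modern,
                                 FS = predict(models$FS),
                                 FI = predict(models$FI))),
              lapply(ba_rcp, function(ba) NULL))
    for (r in names(ba_rcp)) {
      idx <- vapply(predictions, function(x)
        x$label == "realistic" && x$rcp == r, TRUE)
      scen[[r]] <- list(
        BA = ba_rcp[[r]],
        FS = Reduce(`+`, lapply(predictions[idx], `[[`, "FS")) / sum(idx),
        FI = Reduce(`+`, lapply(predictions[idx], `[[`, "FI")) / sum(idx))
    }
    for (s in names(scen)) {
      g <- apply_threshold(scen[[s]]$BA, scen[[s]]$FS, scen[[s]]$FI, thr)
      burn <- !g$gated
      sens_rows[[length(sens_rows) + 1L]] <- data.frame(
        percentile = p, scenario = s,
        fire_size = if (any(burn)) mean(g$FS[burn]) else 0,
        fire_intensity = if (any(burn)) mean(g$FI[burn]) else 0,
        unburnt_pct = g$unburnt_pct)
    }
  }
  sensitivity_tab <- do.call(rbind, sens_rows)

  exp_tab <- if (length(predictions)) {
    do.call(rbind, lapply(predictions, function(p) data.frame(
      label = p$label, rcp = p$rcp, gcm = p$gcm,
      mean_BA = mean(p$BA), mean_FS = mean(p$FS), mean_FI = mean(p$FI),
      unburnt_pct = p$unburnt_pct)))
  } else {
    data.frame(label = character(), rcp = character(), gcm = character(),
               mean_BA = numeric(), mean_FS = numeric(), mean_FI = numeric(),
               unburnt_pct = numeric())
  }

  driver_tab <- if (length(attribution)) {
    do.call(rbind, lapply(names(attribution), function(r) {
      freq <- dominant_driver_map(attribution[[r]])$frequency
      rbind(cbind(rcp = r, sign = "positive", freq$positive),
            cbind(rcp = r, sign = "negative", freq$negative))
    }))
  } else NULL

  list(tss = tss_tab, biome = biome_tab, sensitivity = sensitivity_tab,
       experiments = exp_tab, drivers = driver_tab)
}

#' Write the pipeline report
#'
#' Emits the run's tables as CSV (threshold-skill table in the reference
#' column order; biome burnt-area table; threshold-sensitivity table;
#' per-experiment summary; dominant-driver frequencies), the fitted models
#' as JSON, and a JSON manifest recording the configuration, output files
#' and their MD5 hashes. Deterministic stages reproduce identical hashes
#' under the same configuration.
#'
#' @param run A [run_pipeline()] result.
#' @param out_dir Output directory (created if needed).
#' @return The run, with `manifest` filled in, invisibly.
#' @export
pipeline_report <- function(run, out_dir) {
  if (is.null(run$tables)) stop("missing stage outputs: report tables")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    tss = file.path(out_dir, "threshold_skill.csv"),
    biome = file.path(out_dir, "biome_burnt_area.csv"),
    sensitivity = file.path(out_dir, "threshold_sensitivity.csv"),
    experiments = file.path(out_dir, "experiment_summary.csv"),
    predictors = file.path(out_dir, "baseline_predictors.csv")
  )
  write_tss_csv(run$tables$tss, paths["tss"])
  utils::write.csv(run$tables$biome, paths["biome"], row.names = FALSE)
  utils::write.csv(run$tables$sensitivity, paths["sensitivity"],
                   row.names = FALSE)
  utils::write.csv(run$tables$experiments, paths["experiments"],
                   row.names = FALSE)
  write_field_csv(run$dataset$predictors, run$dataset$grid,
                  paths["predictors"])
  if (!is.null(run$tables$drivers)) {
    paths["drivers"] <- file.path(out_dir, "dominant_drivers.csv")
    utils::write.csv(run$tables$drivers, paths["drivers"], row.names = FALSE)
  }
  for (m in names(run$models)) {
    paths[paste0("model_", m)] <- file.path(out_dir,
                                            paste0("model_", m, ".json"))
    write_fire_glm(run$models[[m]], paths[[paste0("model_", m)]])
  }
  manifest <- list(
    seed = run$config$seed,
    n_cells = nrow(run$dataset$predictors),
    n_experiments = length(run$experiments),
    threshold = run$threshold$report$threshold,
    files = as.list(stats::setNames(unname(tools::md5sum(paths)),
                                    basename(paths)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  run$manifest <- manifest
  invisible(run)
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("pipeline_run: %d cells, %d experiments, threshold %.4g\n",
              nrow(x$dataset$predictors), length(x$experiments),
              x$threshold$report$threshold))
  invisible(x)
}
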