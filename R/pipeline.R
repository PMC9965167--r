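#' Default pipeline run configuration
#'
#' A single nested list drives the whole pipeline; every stage can be
#' toggled and every knob that the analysis depends on is named here so
#' deviations are explicit. The defaults give a small demonstration trial
#' (60 plots, 60 bands) that runs end-to-end on one CPU in a few minutes.
#'
#' @param ... overrides merged over the defaults (nested lists merge
#'   recursively)
#' @return a run-configuration list
#' @export
default_run_config <- function(...) {
  cfg <- list(
    seed = 1,
    out_dir = "maizefuse_run",
    simulate = list(n_plots = 60, plots_per_block = 6, n_bands = 60,
                    n_block_cols = 1, effect_scale = 1),
    prep = list(margin = 5, use_truth_mask = FALSE),
    ndsi = list(enabled = TRUE,
                traits = c("dry_grain_yield", "total_plant_n")),
    features = list(enabled = TRUE),
    train_ml = list(enabled = TRUE, regressor = "rfr",
                    traits = c("dry_grain_yield", "total_plant_n"),
                    feature_set = "hyper_dsm"),
    train_dl = list(enabled = TRUE,
                    tasks = c("dry_grain_yield", "total_plant_n"),
                    modalities = c("hyperspectral", "lidar_height",
                                   "lidar_intensity"),
                    n_crops = 5, max_epochs = 8, bins = 6),
    evaluate = list(enabled = TRUE, moran_k = 8, n_permutations = 999)
  )
  modifyList(cfg, list(...))
}

#' Run the full pipeline
#'
#' Executes simulate -> prep -> {ndsi, features} -> {shallow ML, deep
#' learning} -> evaluate in dependency order, writing CSV/GeoJSON artifacts
#' and a JSON manifest (seeds, stage timings, md5 hashes of every artifact)
#' into the output directory.
#'
#' @param config a configuration list from [default_run_config()] or the
#'   path to a YAML file with the same structure
#' @return the manifest, invisibly
#' @export
run_pipeline <- function(config = default_run_config()) {
  if (is.character(config)) config <- modifyList(default_run_config(),
                                                 yaml::read_yaml(config))
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("maizefuse")),
                   seed = cfg$seed, stages = list(), artifacts = character())
  add_artifact <- function(path) {
    manifest$artifacts <<- c(manifest$artifacts, path)
  }
  timed <- function(name, expr) {
    t0 <- proc.time()[3]
    res <- tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed", error = conditionMessage(e))
      write_manifest(manifest, cfg$out_dir)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
    manifest$stages[[name]] <<- list(status = "ok",
                                     seconds = round(proc.time()[3] - t0, 2))
    res
  }
  p <- function(f) file.path(cfg$out_dir, f)

  scene <- timed("simulate", {
    sc <- simulate_field(n_plots = cfg$simulate$n_plots,
                         plots_per_block = cfg$simulate$plots_per_block,
                         n_bands = cfg$simulate$n_bands,
                         n_block_cols = cfg$simulate$n_block_cols,
                         seed = cfg$seed,
                         effect_spec = default_effect_spec(cfg$simulate$effect_scale))
    write_plots_geojson(sc$plots, p("plots.geojson"))
    write.csv(as.data.frame(sc$phenotypes)[, c("plot_id", "treatment",
                                               trait_names())],
              p("phenotypes.csv"), row.names = FALSE)
    add_artifact(p("plots.geojson")); add_artifact(p("phenotypes.csv"))
    sc
  })

  prep <- timed("prep", {
    pr <- prep_plots(scene, margin = cfg$prep$margin, seed = cfg$seed,
                     use_truth_mask = cfg$prep$use_truth_mask)
    bm <- data.frame(plot_id = pr$design$plot_id, pr$band_stack$M,
                     check.names = FALSE)
    write.csv(bm, p("band_means.csv"), row.names = FALSE)
    add_artifact(p("band_means.csv"))
    pr
  })

  if (isTRUE(cfg$ndsi$enabled)) timed("ndsi", {
    bs <- band_stack(prep$band_stack$M, prep$band_stack$wavelengths)
    tr <- as.data.frame(prep$phenotypes)[, cfg$ndsi$traits, drop = FALSE]
    best <- ndsi_screen_traits(bs, tr)
    write.csv(best, p("ndsi_best_pairs.csv"), row.names = FALSE)
    add_artifact(p("ndsi_best_pairs.csv"))
  })

  feats <- NULL
  if (isTRUE(cfg$features$enabled)) feats <- timed("features", {
    fx <- plot_features(prep)
    write.csv(data.frame(plot_id = rownames(fx), fx, check.names = FALSE),
              p("features.csv"), row.names = FALSE)
    jsonlite::write_json(feature_registry(), p("feature_registry.json"),
                         auto_unbox = TRUE)
    add_artifact(p("features.csv")); add_artifact(p("feature_registry.json"))
    fx
  })

  preds <- list()
  if (isTRUE(cfg$train_ml$enabled) && !is.null(feats)) timed("train_ml", {
    sets <- modality_feature_sets(colnames(feats))
    X <- feats[, sets[[cfg$train_ml$feature_set]], drop = FALSE]
    sp <- stratified_split(as.character(prep$design$treatment), seed = cfg$seed)
    keep <- apply(X[sp$train, , drop = FALSE], 2, sd) > 0
    sc <- standardize(X[, keep, drop = FALSE], fit_rows = sp$train)
    rows <- list()
    for (tn in cfg$train_ml$traits) {
      y <- as.data.frame(prep$phenotypes)[[tn]]
      fit <- fit_with_search(sc$scaled[sp$train, , drop = FALSE], y[sp$train],
                             regressor = cfg$train_ml$regressor, seed = cfg$seed)
      yh <- predict(fit, sc$scaled)
      preds[[paste0("ml_", tn)]] <- yh
      m <- regression_metrics(y[sp$test], yh[sp$test])
      rows[[tn]] <- data.frame(trait = tn, regressor = cfg$train_ml$regressor,
                               r2 = m$r2, rmse = m$rmse, mae = m$mae)
    }
    write.csv(do.call(rbind, rows), p("ml_metrics.csv"), row.names = FALSE)
    add_artifact(p("ml_metrics.csv"))
  })

  if (isTRUE(cfg$train_dl$enabled)) timed("train_dl", {
    tc <- default_train_config(seed = cfg$seed,
                               n_crops = cfg$train_dl$n_crops,
                               max_epochs = cfg$train_dl$max_epochs,
                               bins = cfg$train_dl$bins)
    fit <- train_fusion_net(prep, tasks = cfg$train_dl$tasks,
                            modalities = cfg$train_dl$modalities, config = tc)
    write.csv(fit$history, p("dl_history.csv"), row.names = FALSE)
    ev <- evaluate_fusion_net(fit, prep, "test")
    write.csv(ev, p("dl_metrics.csv"), row.names = FALSE)
    yh <- predict_fusion_net(fit, prep)
    for (tn in fit$tasks) preds[[paste0("dl_", tn)]] <- yh[, tn]
    add_artifact(p("dl_history.csv")); add_artifact(p("dl_metrics.csv"))
  })

  if (isTRUE(cfg$evaluate$enabled) && length(preds)) timed("evaluate", {
    cen <- plot_centroids(prep$design)
    rows <- list()
    for (nm in names(preds)) {
      tn <- sub("^(ml|dl)_", "", nm)
      y <- as.data.frame(prep$phenotypes)[[tn]]
      mp <- prediction_map(data.frame(plot_id = prep$design$plot_id,
                                      measured = y, predicted = preds[[nm]]),
                           prep$design)
      write_prediction_map(mp, p(paste0("map_", nm, ".geojson")))
      add_artifact(p(paste0("map_", nm, ".geojson")))
      mi <- morans_i(mp$residual, cen, k = cfg$evaluate$moran_k,
                     n_permutations = cfg$evaluate$n_permutations,
                     seed = cfg$seed)
      rows[[nm]] <- data.frame(model = nm, moran_i = mi$i,
                               expected = mi$expected, p_value = mi$p_value,
                               significant = mi$significant)
    }
    write.csv(do.call(rbind, rows), p("moran.csv"), row.names = FALSE)
    add_artifact(p("moran.csv"))
  })

  write_manifest(manifest, cfg$out_dir)
  invisible(manifest)
}

write_manifest <- function(manifest, out_dir) {
  files <- manifest$artifacts
  manifest$hashes <- as.list(tools::md5sum(files[file.exists(files)]))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
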