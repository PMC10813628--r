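#' End-to-end pipeline on a synthetic seascape
#'
#' Runs every stage in order — simulate, classify sediment, hard-bottom
#' rules, station labelling, per-realm model fitting, grid prediction, map
#' composition, area summaries — and writes all layers, tables and a
#' machine-readable run manifest to an output directory. Outputs are
#' write-once per run directory: an existing non-empty directory is
#' rejected.
#'
#' @param config a [seascape_config()].
#' @param out_dir output directory (created; must not already contain a
#'   manifest).
#' @param rule a [community_rule()].
#' @param model_seed seed for the model stage (split/tuning/forests).
#' @param ntree_grid,mtry_grid hyperparameter grids passed to
#'   [model_config()].
#' @param label_mode label sampling mode of [generate_stations()].
#' @return (invisibly) a list with all in-memory stage results; files are
#'   written under `out_dir`.
#' @export
run_pipeline <- function(config = seascape_config(), out_dir,
                         rule = default_community_rule(),
                         model_seed = config$seed,
                         ntree_grid = c(250, 500), mtry_grid = NULL,
                         label_mode = "argmax") {
  if (dir.exists(out_dir) && file.exists(file.path(out_dir,
                                                   "manifest.json"))) {
    stop("output directory already holds a run (outputs are write-once)",
         call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "benthoscape",
                   version = as.character(utils::packageVersion("benthoscape")),
                   seed = config$seed, model_seed = model_seed,
                   cell_size = config$cell_size, stages = list())
  stage <- function(name, value) {
    manifest$stages[[name]] <<- value
  }

  # 1. simulate
  sim <- simulate_seascape(config, rule, label_mode)
  geom <- sim$geom
  stage("simulate", list(cells = geom$nrow * geom$ncol,
                         stations = nrow(sim$stations),
                         boulders = nrow(sim$boulders)))

  # 2. sediment -> EUNIS substrate per cell
  substrate <- matrix(bsh_to_eunis(as.vector(sim$sediment)),
                      geom$nrow, geom$ncol)
  write_class_grid(sim$sediment, file.path(out_dir, "sediment_bsh.asc"),
                   geom)
  stage("classify_sediment", list(classes = length(unique(as.vector(
    sim$sediment)))))

  # 3. hard bottom
  counts <- grid_boulder_counts(sim$boulders, geom)
  bclass <- classify_boulder_density(counts)
  hard <- hard_substrate_mask(bclass, sim$sediment, geom)
  write_ascii_grid(counts, file.path(out_dir, "boulder_counts.asc"), geom)
  write_ascii_grid(bclass, file.path(out_dir, "boulder_class.asc"), geom)
  stage("hardbottom", list(boulders = nrow(sim$boulders),
                           hard_cells = sum(hard)))

  # 4. station labelling
  labels <- assign_hub_labels(sim$stations, sim$records)
  stn <- cbind(sim$stations[c("station_id", "x", "y", "method", "row",
                              "col")],
               labels[c("raw_label", "harmonized_label", "excluded",
                        "reason")])
  utils::write.csv(stn, file.path(out_dir, "stations_labelled.csv"),
                   row.names = FALSE)
  stage("assign_hub", list(stations = nrow(stn),
                           excluded = sum(stn$excluded)))

  # 5. fit + predict per realm
  keep <- !stn$excluded
  fits <- list()
  preds <- list()
  for (realm in c("endo", "epi")) {
    rows <- keep & stn$method == (if (realm == "endo") "grab" else "video")
    if (!any(rows)) next
    feats <- build_feature_matrix(stn[rows, ], stn$harmonized_label[rows],
                                  sim$env, sim$sediment, realm,
                                  hard = hard)
    tab <- table(droplevels(feats$y))
    if (length(tab) < 2 || min(tab) < 2) next  # realm not modellable
    cfg <- model_config(realm = realm, ntree_grid = ntree_grid,
                        mtry_grid = mtry_grid, seed = model_seed)
    fit <- fit_biotope_model(feats, cfg)
    fits[[realm]] <- fit
    preds[[realm]] <- predict_grid(fit, sim$env, sim$sediment, realm,
                                   hard = hard)
    jsonlite::write_json(
      list(realm = realm, accuracy = fit$accuracy, ci = fit$ci,
           kappa = fit$kappa, auc = fit$auc, oob_error = fit$oob_error,
           hyperparameters = fit$hyperparameters,
           importance = as.list(fit$importance)),
      file.path(out_dir, paste0("fit_", realm, ".json")),
      auto_unbox = TRUE, digits = NA)
    utils::write.csv(as.data.frame.matrix(fit$confusion),
                     file.path(out_dir, paste0("confusion_", realm,
                                               ".csv")))
    stage(paste0("fit_", realm),
          list(train = length(fit$split$train),
               test = length(fit$split$test),
               accuracy = fit$accuracy))
  }

  # 6. compose layers
  photic <- sim$env$photic
  bht <- compose_bht(photic, substrate)
  bht <- eliminate_small_patches(bht, geom$cell_size)
  endo_tok <- if (!is.null(preds$endo)) preds$endo$token else
    matrix(NA_character_, geom$nrow, geom$ncol)
  epi_tok <- if (!is.null(preds$epi)) preds$epi$token else
    matrix(NA_character_, geom$nrow, geom$ncol)
  token <- intersect_endo_epi(hard, endo_tok, epi_tok)
  hub <- build_hub_layer(photic, substrate, token, geom$cell_size)
  oht <- build_oht_layer(geom, hub$hub)
  write_class_grid(bht, file.path(out_dir, "bht.asc"), geom)
  write_class_grid(hub$hub, file.path(out_dir, "hub.asc"), geom)
  utils::write.csv(area_summary(bht, geom$cell_size),
                   file.path(out_dir, "bht_areas.csv"), row.names = FALSE)
  utils::write.csv(hub$areas, file.path(out_dir, "hub_areas.csv"),
                   row.names = FALSE)
  utils::write.csv(oht$areas, file.path(out_dir, "oht_areas.csv"),
                   row.names = FALSE)
  stage("compose", list(bht_classes = length(unique(stats::na.omit(
    as.vector(bht)))), hub_classes = nrow(hub$areas)))

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(sim = sim, substrate = substrate, counts = counts,
                 boulder_class = bclass, hard = hard, stations = stn,
                 fits = fits, predictions = preds, bht = bht, hub = hub,
                 oht = oht, manifest = manifest))
}
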