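#' Build and validate a run configuration
#'
#' Assembles the pipeline configuration with the protocol defaults:
#' 1970–2012 study window, pseudo-absence multiplier 4, resolution scan
#' over 1/5/10/20/30/50 cells-equivalent block sizes, 5-fold
#' cross-validation, out-of-region minimum of 25 occurrence points, and
#' the reduced BRT tuning grid.
#'
#' @param ... overrides of the defaults (see the source for field names).
#' @return Validated config list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    n_rows = 64, n_cols = 64, autocorr_range = 10, cellsize = 1000,
    n_expert = 300, n_citizen = 300, n_regions = 6,
    window = c(1970, 2012),
    multiplier = 4,
    resolutions_cells = c(1, 5, 10, 20, 30, 50),
    thinning_mode = "random",
    strategies = c("random", "weighted"),
    datasets = c("expert", "citizen", "combined"),
    algorithms = c("glm", "brt", "maxent"),
    selection_dataset = "expert",
    candidate_climatic = list(c1 = "cov1", c2 = "cov2", c12 = c("cov1", "cov2")),
    candidate_nonclimatic = list(n1 = "cov3", n2 = "cov4",
                                 n12 = c("cov3", "cov4")),
    cv_folds = 5,
    region_min_count = 25,
    max_replicates_used = 3,
    brt_grid = brt_grid_default(),
    maxent_reg_grid = seq(0.2, 5, by = 0.2),
    ensemble_dataset = "combined", ensemble_strategy = "random",
    seed = 1
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  cfg[names(over)] <- over
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

validate_config <- function(cfg) {
  if (cfg$multiplier <= 0) stop("config invalid: multiplier must be > 0",
                                call. = FALSE)
  if (cfg$cv_folds < 2) stop("config invalid: cv_folds must be >= 2",
                             call. = FALSE)
  if (cfg$region_min_count < 1) {
    stop("config invalid: region_min_count must be >= 1", call. = FALSE)
  }
  if (!all(cfg$datasets %in% c("expert", "citizen", "combined"))) {
    stop("config invalid: unknown dataset label", call. = FALSE)
  }
  if (!all(cfg$algorithms %in% c("glm", "brt", "maxent"))) {
    stop("config invalid: unknown algorithm", call. = FALSE)
  }
  invisible(cfg)
}

#' Read a run configuration from YAML
#' @param path YAML file whose keys are [run_config()] fields.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' Run the full pipeline on a synthetic study system
#'
#' Chains every stage — landscape simulation, occurrence preparation,
#' spatial-structure analysis and thinning, pseudo-absence generation,
#' model fitting with two-phase AICc covariate selection, cross-validation
#' and out-of-region evaluation, covariate importance, and Kappa-weighted
#' ensemble projection — writing each stage's artifacts under `outdir`
#' with a manifest recording the seed and a config hash. Stages whose
#' primary output already exists are skipped when `resume = TRUE`, so
#' deleting one artifact re-executes only the stages from that point.
#'
#' @param config a [run_config()].
#' @param outdir output directory (created if needed).
#' @param resume skip stages whose outputs exist.
#' @return Invisibly, a list with the evaluation summary, selection,
#'   importance table, ensemble, and paths of all written artifacts.
#' @export
run_pipeline <- function(config = run_config(), outdir, resume = TRUE) {
  validate_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  path <- function(...) file.path(outdir, paste0(...))
  stage_done <- function(f) resume && file.exists(path(f))
  log_stage <- function(s) message("[pipeline] stage: ", s)

  manifest <- list(seed = seed, config_hash = rlang::hash(unclass(config)),
                   config = unclass(config),
                   stages = character())
  # ---- stage: simulate -------------------------------------------------
  world <- simulate_study(
    n_rows = config$n_rows, n_cols = config$n_cols,
    n_expert = config$n_expert, n_citizen = config$n_citizen,
    n_regions = config$n_regions, autocorr_range = config$autocorr_range,
    seed = child_seed(seed, "simulate"))
  if (!stage_done("truth.asc")) {
    log_stage("simulate")
    for (nm in names(world$stack$layers)) {
      write_raster(world$stack$layers[[nm]], path(nm, ".asc"))
    }
    write_raster(world$species$truth, path("truth.asc"))
    write_raster(world$regions, path("regions.asc"))
    write_occurrences(world$expert, path("occurrences_expert.csv"))
    write_occurrences(world$citizen, path("occurrences_citizen.csv"))
    jsonlite::write_json(
      list(intercept = world$species$intercept,
           curves = world$species$curves),
      path("truth_params.json"), auto_unbox = TRUE, digits = NA)
  }
  grid <- world$stack$layers[[1]]

  # ---- stage: prep -----------------------------------------------------
  log_stage("prep")
  prep_one <- function(occ) suppressMessages(
    prepare_occurrences(occ, grid, window = config$window))
  occ <- list(expert = prep_one(world$expert),
              citizen = prep_one(world$citizen))
  occ$combined <- merge_datasets(occ$expert, occ$citizen, grid)
  occ <- occ[config$datasets]
  if (!stage_done("prepared_expert.csv")) {
    for (d in names(occ)) write_occurrences(occ[[d]], path("prepared_", d, ".csv"))
  }

  # ---- stage: spatial --------------------------------------------------
  log_stage("spatial")
  effort <- lapply(occ, function(o) density_surface(o, grid))
  scan <- select_resolution(
    occ[[config$selection_dataset]], grid,
    resolutions = config$resolutions_cells * grid$cellsize,
    seed = child_seed(seed, "scan"))
  thin_res <- if (is.na(scan$selected))
    max(config$resolutions_cells) * grid$cellsize else scan$selected
  if (!stage_done("resolution_scan.csv")) {
    utils::write.csv(scan$table, path("resolution_scan.csv"),
                     row.names = FALSE)
    for (d in names(effort)) write_raster(effort[[d]], path("density_", d, ".asc"))
  }

  # ---- stage: pabs + training tables ----------------------------------
  log_stage("pabs")
  tables <- list()
  for (d in names(occ)) {
    for (s in config$strategies) {
      pa <- if (s == "random") {
        generate_random(occ[[d]], grid, multiplier = config$multiplier,
                        seed = child_seed(seed, paste0("pa-", d, "-", s)))
      } else {
        generate_weighted(occ[[d]], effort[[d]], grid,
                          multiplier = config$multiplier,
                          seed = child_seed(seed, paste0("pa-", d, "-", s)))
      }
      key <- paste0(d, ".", s)
      occ_rep <- thin_replicates(occ[[d]], grid, thin_res,
                                 mode = config$thinning_mode,
                                 seed = child_seed(seed, paste0("thin-o-", key)))
      pa_rep <- thin_replicates(
        occurrence_set(pa$x, pa$y), grid, thin_res,
        mode = config$thinning_mode,
        seed = child_seed(seed, paste0("thin-a-", key)))
      keep <- seq_len(min(config$max_replicates_used,
                          max(occ_rep$n_replicates, pa_rep$n_replicates)))
      occ_rep$replicates <- occ_rep$replicates[
        pmin(keep, occ_rep$n_replicates)]
      pa_rep$replicates <- pa_rep$replicates[pmin(keep, pa_rep$n_replicates)]
      tables[[key]] <- build_training_table(occ_rep, pa_rep, world$stack)
      if (!stage_done(paste0("pabs_", d, "_", s, ".csv"))) {
        utils::write.csv(as.data.frame(pa), path("pabs_", d, "_", s, ".csv"),
                         row.names = FALSE)
      }
    }
  }

  # ---- stage: select ---------------------------------------------------
  log_stage("select")
  sel_table <- tables[[paste0(config$selection_dataset, ".random")]]
  selection <- two_phase_select(sel_table, config$candidate_climatic,
                                config$candidate_nonclimatic,
                                algorithm = "glm")
  best_covs <- selection$best
  if (!stage_done("selection.csv")) {
    utils::write.csv(selection$phase2, path("selection.csv"),
                     row.names = FALSE)
  }

  # ---- stage: fit ------------------------------------------------------
  log_stage("fit")
  fit_full <- function(alg, tab) {
    switch(alg,
           glm = fit_glm(tab, best_covs),
           brt = tune_fit_brt(tab, best_covs, grid = config$brt_grid,
                              seed = child_seed(seed, "brt")),
           maxent = tune_fit_maxent(tab, best_covs,
                                    reg_grid = config$maxent_reg_grid,
                                    seed = child_seed(seed, "mx")))
  }
  refitter <- function(alg, model) {
    switch(alg,
           glm = function(t) fit_glm(t, best_covs),
           brt = function(t) fit_brt(
             t, best_covs, trees = model$tuning$selected$trees,
             rate = model$tuning$selected$rate,
             complexity = model$tuning$selected$complexity,
             seed = child_seed(seed, "brt-re")),
           maxent = function(t) tune_fit_maxent(
             t, best_covs,
             reg_grid = model$tuning$selected$multiplier,
             seed = child_seed(seed, "mx-re")))
  }
  models <- list()
  for (key in names(tables)) {
    for (alg in config$algorithms) {
      mkey <- paste0(key, ".", alg)
      models[[mkey]] <- fit_full(alg, tables[[key]])
      if (!stage_done(paste0("model_", gsub("\\.", "_", mkey), ".json"))) {
        write_model_json(models[[mkey]],
                         path("model_", gsub("\\.", "_", mkey), ".json"))
      }
    }
  }

  # ---- stage: evaluate -------------------------------------------------
  log_stage("evaluate")
  records <- list()
  region_status <- list()
  for (key in names(tables)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    for (alg in config$algorithms) {
      mkey <- paste0(key, ".", alg)
      f <- refitter(alg, models[[mkey]])
      records[[paste0("cv.", mkey)]] <- cross_validate(
        tables[[key]], f, folds = config$cv_folds,
        seed = child_seed(seed, paste0("cv-", mkey)),
        algorithm = alg, dataset = parts[1], strategy = parts[2])
      oor <- tryCatch(
        out_of_region(tables[[key]], world$regions, f,
                      min_count = config$region_min_count,
                      algorithm = alg, dataset = parts[1],
                      strategy = parts[2]),
        error = function(e) NULL)
      if (!is.null(oor)) {
        records[[paste0("oor.", mkey)]] <- oor$records
        region_status[[mkey]] <- oor$regions
      }
    }
  }
  records <- dplyr::bind_rows(records)
  summary_tab <- aggregate_evaluations(
    records, by = c("protocol", "dataset", "strategy", "algorithm"))
  if (!stage_done("evaluation_records.csv")) {
    utils::write.csv(as.data.frame(records), path("evaluation_records.csv"),
                     row.names = FALSE)
    jsonlite::write_json(summary_tab, path("evaluation_summary.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }

  # ---- stage: importance ----------------------------------------------
  log_stage("importance")
  imp <- purrr::imap_dfr(models, function(m, mkey) {
    dplyr::mutate(covariate_importance(m), model = mkey, .before = 1)
  })
  if (!stage_done("importance.csv")) {
    utils::write.csv(as.data.frame(imp), path("importance.csv"),
                     row.names = FALSE)
  }

  # ---- stage: ensemble -------------------------------------------------
  log_stage("ensemble")
  ens_key <- paste0(config$ensemble_dataset, ".", config$ensemble_strategy)
  member_models <- list(); member_kappas <- c(); member_labels <- c()
  cvrec <- records[records$protocol == "cv" &
                     records$dataset == config$ensemble_dataset &
                     records$strategy == config$ensemble_strategy, ]
  for (alg in config$algorithms) {
    mkey <- paste0(ens_key, ".", alg)
    if (is.null(models[[mkey]])) next
    member_models[[length(member_models) + 1]] <- models[[mkey]]
    member_kappas <- c(member_kappas,
                       mean(cvrec$kappa[cvrec$algorithm == alg]))
    member_labels <- c(member_labels, alg)
  }
  ens <- build_ensemble(member_models, member_kappas, member_labels)
  ens_map <- project_ensemble(ens, world$stack)
  if (!stage_done("ensemble.asc")) {
    write_raster(ens_map, path("ensemble.asc"))
    jsonlite::write_json(ens$table, path("ensemble_members.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }

  manifest$stages <- c("simulate", "prep", "spatial", "pabs", "select",
                       "fit", "evaluate", "importance", "ensemble")
  manifest$selected_resolution <- thin_res
  manifest$best_covariates <- best_covs
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(list(world = world, tables = tables, selection = selection,
                 models = models, records = records, summary = summary_tab,
                 importance = imp, ensemble = ens, ensemble_map = ens_map,
                 scan = scan, outdir = outdir))
}
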