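#' Run the full closure-and-accessibility pipeline
#'
#' Executes the end-to-end analysis: simulate (or load) a two-year region,
#' operationalize the cohort, fit the full logistic closure model, select
#' the final model by backward stepwise AIC, smooth the closure probability
#' over live births, compute baseline and scenario accessibility surfaces,
#' and write every artifact plus a JSON run log. The run log records the
#' seed, a hash of the configuration, and the record count after every
#' filter stage, so the whole exclusion funnel is machine-checkable.
#'
#' @param config a [pipeline_config()] (or the path of a YAML config file).
#' @param out_dir artifact directory (created if needed).
#' @return Invisibly, the run log as a list. Artifacts written: cohort and
#'   regression-cohort CSVs, exclusion log CSV, full and final regression
#'   tables, elimination trace, LOWESS curves, network CSV/GeoJSON, one
#'   surface CSV/GeoJSON and one coverage CSV per scenario, `run_log.json`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  log <- list(seed = config$seed,
              config_hash = config_hash(config),
              started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
              stages = list())
  stage_counts <- list()
  current_stage <- "init"
  on.exit({
    log$stages <- stage_counts
    log$failed_stage <- if (!identical(current_stage, "done")) current_stage
    jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  })

  current_stage <- "simulate"
  if (!is.null(config$paths)) {
    p <- config$paths
    baseline_raw <- read_registry(p$registry_baseline)
    followup_raw <- read_registry(p$registry_followup)
    areas <- utils::read.csv(p$areas, stringsAsFactors = FALSE)
    network <- if (!is.null(p$network_nodes)) {
      read_network_csv(p$network_nodes, p$network_edges)
    }
  } else {
    rc <- region_config(n_sites = config$n_sites, n_nodes = config$n_nodes,
                        seed = config$seed)
    sim <- simulate_region(rc, true_model(),
                           target_rate = config$target_closure_rate)
    baseline_raw <- sim$baseline
    followup_raw <- sim$followup
    areas <- sim$areas
    network <- sim$network
    write_network_csv(network, file.path(out_dir, "network_nodes.csv"),
                      file.path(out_dir, "network_edges.csv"))
    write_network_geojson(network, file.path(out_dir, "network.geojson"))
    write_registry(baseline_raw, file.path(out_dir, "registry_baseline.csv"))
    write_registry(followup_raw, file.path(out_dir, "registry_followup.csv"))
  }
  stage_counts$baseline_records <- nrow(baseline_raw)
  stage_counts$followup_records <- nrow(followup_raw)

  current_stage <- "operationalize"
  baseline_obs <- identify_obstetric_sites(baseline_raw)
  followup_obs <- identify_obstetric_sites(followup_raw)
  stage_counts$baseline_obstetric_sites <- nrow(baseline_obs)
  stage_counts$followup_obstetric_sites <- nrow(followup_obs)
  cohort <- build_closure_cohort(baseline_obs, followup_obs,
                                 followup_full = followup_raw,
                                 network = network, areas = areas)
  stage_counts$cohort_rows <- nrow(cohort)
  stage_counts$closures <- sum(cohort$closed_by_followup)
  reg_cohort <- apply_exclusions(cohort)
  excl <- attr(reg_cohort, "exclusion_log")
  stage_counts$regression_rows <- nrow(reg_cohort)
  utils::write.csv(cohort, file.path(out_dir, "cohort.csv"), row.names = FALSE)
  utils::write.csv(reg_cohort, file.path(out_dir, "regression_cohort.csv"),
                   row.names = FALSE)
  utils::write.csv(excl, file.path(out_dir, "exclusion_log.csv"), row.names = FALSE)

  current_stage <- "fit"
  spec <- regression_spec()
  screened <- screen_multicollinearity(reg_cohort, spec)
  full_fit <- screened$fit
  write_regression_csv(full_fit, file.path(out_dir, "regression_full.csv"),
                       file.path(out_dir, "regression_full_stats.csv"))

  current_stage <- "select"
  sel <- backward_stepwise_aic(reg_cohort, full_fit$spec)
  write_regression_csv(sel$fit, file.path(out_dir, "regression_final.csv"),
                       file.path(out_dir, "regression_final_stats.csv"))
  utils::write.csv(sel$trace, file.path(out_dir, "stepwise_trace.csv"),
                   row.names = FALSE)
  stage_counts$stepwise_retained <- length(sel$retained)

  current_stage <- "smooth"
  curves <- lowess_curve(reg_cohort)
  utils::write.csv(curves, file.path(out_dir, "lowess_curves.csv"),
                   row.names = FALSE)

  current_stage <- "access"
  fac_all <- facility_set(data.frame(
    site_id = followup_obs$site_id,
    node_id = followup_obs$node_id,
    live_births = count_live_births(followup_obs$procedures),
    has_pediatrics = has_department(followup_obs$departments,
                                    PEDIATRICS_DEPARTMENT_CODE)
  ), network)
  pts <- sample_points(c(xmin = min(network$nodes$x), xmax = max(network$nodes$x),
                         ymin = min(network$nodes$y), ymax = max(network$nodes$y)),
                       config$sampler_n, seed = config$seed, network = network)
  base_surface <- access_surface(network, fac_all, points = pts,
                                 thresholds = config$time_thresholds)
  stage_counts$surface_points <- nrow(base_surface)

  current_stage <- "scenarios"
  for (sc in config$scenarios) {
    sp <- scenario_spec(sc$name,
                        require_pediatrics = isTRUE(sc$require_pediatrics),
                        min_live_births = sc$min_live_births)
    fac <- apply_scenario(fac_all, sp)
    surf <- access_surface(network, fac, points = pts,
                           thresholds = config$time_thresholds)
    # facility subsets can only lengthen travel times
    stopifnot(all(surf$min_time >= base_surface$min_time - 1e-9))
    rep_ <- coverage_report(surf, reference = base_surface)
    utils::write.csv(as.data.frame(surf),
                     file.path(out_dir, paste0("surface_", sp$name, ".csv")),
                     row.names = FALSE)
    write_surface_geojson(surf, file.path(out_dir, paste0("surface_", sp$name, ".geojson")))
    utils::write.csv(as.data.frame(rep_),
                     file.path(out_dir, paste0("coverage_", sp$name, ".csv")),
                     row.names = FALSE)
    stage_counts[[paste0("scenario_", sp$name, "_facilities")]] <- nrow(fac)
  }

  current_stage <- "done"
  log$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  log$stages <- stage_counts
  invisible(log)
}

# Stable hash of the configuration: md5 of its canonical serialization.
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(unclass(config)), tmp)
  unname(tools::md5sum(tmp))
}
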