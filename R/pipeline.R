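CONFIG_DEFAULTS <- list(
  mode = "direct_z",          # direct_z | timeseries
  n_male = 203, n_female = 291,
  age_low = 22, age_high = 36,
  n_regions = 116, n_timepoints = 1200,
  n_sex_edges = 0, n_age_edges = 0, n_int_edges = 0,
  effect_size_sex = 0.5, effect_size_age = 0.05, effect_size_int = 0.02,
  noise_sd = 1,
  block_r = 0.3, base_r = 0.05,
  alpha = 0.05, alpha_remove = 0.05,
  correction = "bonferroni",  # bonferroni | bh_fdr
  density_grid = "0.05:0.95:0.05",
  n_nulls = 30, swaps_per_edge = 10,
  center_age = FALSE, abs_threshold = FALSE,
  t_variant = "student",      # student | welch
  seed = 1,
  out_dir = "fcnets-run")

#' Validate and normalize a pipeline configuration
#'
#' Accepts a named list or the path of a flat `key = value` text file,
#' applies the standard defaults (alpha 0.05, density grid 0.05:0.95:0.05,
#' 30 nulls, 10 swaps per edge, 203/291 cohort aged 22-36, 116 regions,
#' 1200 timepoints) and validates ranges. Unknown keys and out-of-range
#' values raise itemized errors.
#'
#' @param config Named list (possibly empty) or path to a key=value file.
#' @return A normalized `RunConfig` list.
#' @export
validateConfig <- function(config = list()) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) {
      stop("config file does not exist: ", config, call. = FALSE)
    }
    lines <- readLines(config)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    kv <- strsplit(lines, "=", fixed = TRUE)
    config <- stats::setNames(
      lapply(kv, function(x) utils::type.convert(trimws(x[2]),
                                                 as.is = TRUE)),
      vapply(kv, function(x) trimws(x[1]), character(1)))
  }
  unknown <- setdiff(names(config), names(CONFIG_DEFAULTS))
  errors <- character()
  if (length(unknown)) {
    errors <- c(errors, paste("unknown key(s):",
                              paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(CONFIG_DEFAULTS,
                           config[intersect(names(config),
                                            names(CONFIG_DEFAULTS))])
  if (!cfg$mode %in% c("direct_z", "timeseries")) {
    errors <- c(errors, "mode must be direct_z or timeseries")
  }
  if (!cfg$correction %in% c("bonferroni", "bh_fdr")) {
    errors <- c(errors, "correction must be bonferroni or bh_fdr")
  }
  if (!cfg$t_variant %in% c("student", "welch")) {
    errors <- c(errors, "t_variant must be student or welch")
  }
  if (!(cfg$alpha > 0 && cfg$alpha < 1)) {
    errors <- c(errors, "alpha must lie in (0, 1)")
  }
  if (!(cfg$alpha_remove > 0 && cfg$alpha_remove < 1)) {
    errors <- c(errors, "alpha_remove must lie in (0, 1)")
  }
  grid <- tryCatch(parseDensityGrid(cfg$density_grid),
                   error = function(e) {
                     errors <<- c(errors, conditionMessage(e))
                     NULL
                   })
  if (cfg$n_male + cfg$n_female < 3) {
    errors <- c(errors, "cohort must contain at least 3 subjects")
  }
  if (cfg$n_regions < 3) errors <- c(errors, "n_regions must be >= 3")
  if (cfg$mode == "timeseries" &&
      cfg$n_timepoints < cfg$n_regions + 2) {
    errors <- c(errors, "n_timepoints must be >= n_regions + 2")
  }
  if (cfg$n_nulls < 0 || cfg$swaps_per_edge < 1) {
    errors <- c(errors, "n_nulls must be >= 0 and swaps_per_edge >= 1")
  }
  if (length(errors)) {
    stop("invalid configuration:\n  ",
         paste(errors, collapse = "\n  "), call. = FALSE)
  }
  cfg$density_grid_levels <- grid
  class(cfg) <- c("RunConfig", "list")
  cfg
}

writeStage <- function(obj, path) {
  if (is.data.frame(obj)) {
    utils::write.csv(obj, path, row.names = FALSE)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
  }
  path
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> (fc) -> regress -> graph -> compare on a synthetic
#' cohort under one configuration, writing every stage output plus a
#' manifest of MD5 content hashes into a fresh, append-only run directory
#' (`run-001`, `run-002`, ... under `out_dir`). Identical configuration and
#' seed reproduce identical manifest hashes.
#'
#' @param config A `RunConfig` from [validateConfig()] (or a raw list/path,
#'   validated on the way in).
#' @param stopAfter Last stage to execute: `"simulate"`, `"regress"`,
#'   `"graph"` or `"compare"` (default, the full pipeline).
#' @return Invisibly, a list with `runDir`, `manifest` (data.frame file/md5)
#'   and the in-memory stage results.
#' @export
runPipeline <- function(config = list(),
                        stopAfter = c("compare", "graph", "regress",
                                      "simulate")) {
  stopAfter <- match.arg(stopAfter)
  stages <- c("simulate", "regress", "graph", "compare")
  run <- stages[seq_len(match(stopAfter, stages))]
  report <- strat <- grid <- nodalCmp <- globalCmp <- motion <- NULL
  if (!inherits(config, "RunConfig")) config <- validateConfig(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  existing <- list.files(config$out_dir, pattern = "^run-\\d+$")
  runDir <- file.path(config$out_dir,
                      sprintf("run-%03d", length(existing) + 1L))
  dir.create(runDir)
  files <- character()
  logline <- function(stage, msg) {
    message(sprintf("[%s] %s", stage, msg))
  }

  # --- simulate -------------------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  scheme <- makeScheme(config$n_regions)
  cohort <- makeCohort(config$n_male, config$n_female, config$age_low,
                       config$age_high, seed = deriveSeed(config$seed, 1L))
  nE <- config$n_regions * (config$n_regions - 1) / 2
  effects <- makeEffectMap(
    nE, config$n_sex_edges, config$n_age_edges, config$n_int_edges,
    effectSizes = c(sex = config$effect_size_sex,
                    age = config$effect_size_age,
                    int = config$effect_size_int),
    noiseSd = config$noise_sd, seed = deriveSeed(config$seed, 2L))
  if (config$mode == "direct_z") {
    fce <- simulateDirectZ(cohort, effects, seed = deriveSeed(config$seed, 3L))
  } else {
    ts <- simulateTimeSeries(cohort, scheme, blockR = config$block_r,
                             baseR = config$base_r,
                             nTimepoints = config$n_timepoints,
                             seed = deriveSeed(config$seed, 3L))
    fcs <- lapply(ts, function(m) reorderFC(computeFC(m), scheme))
    fce <- buildGroupTable(fcs, cohort, scheme)
  }
  files <- c(files, writeStage(cohort, file.path(runDir, "cohort.csv")))
  writeEffectMap(effects, file.path(runDir, "effect_map.csv"))
  files <- c(files, file.path(runDir, "effect_map.csv"))
  writeGroupFC(fce, file.path(runDir, "group_fc.csv"),
               indexPath = file.path(runDir, "edge_index.csv"))
  files <- c(files, file.path(runDir, "group_fc.csv"),
             file.path(runDir, "edge_index.csv"))
  logline("simulate", sprintf("%d subjects x %d edges (%.1fs)",
                              nrow(cohort), nE,
                              proc.time()[["elapsed"]] - t0))

  # --- regress --------------------------------------------------------
  if ("regress" %in% run) {
  t0 <- proc.time()[["elapsed"]]
  report <- runMassUnivariate(fce, alpha = config$alpha,
                              alphaRemove = config$alpha_remove,
                              correction = config$correction,
                              centerAge = config$center_age)
  files <- c(files, writeStage(report$results,
                               file.path(runDir, "edge_regression.csv")))
  summaryJson <- list(
    n_edges = report$counts$n_edges,
    threshold = report$threshold$threshold,
    threshold_label = report$threshold$label,
    n_significant_models = report$counts$n_significant_models,
    models_significant = as.list(report$counts$models_significant),
    sex_male_gt_female = report$counts$sex_male_gt_female,
    sex_female_gt_male = report$counts$sex_female_gt_male,
    age_negative = report$counts$age_negative,
    int_significant = report$counts$int_significant)
  files <- c(files, writeStage(summaryJson,
                               file.path(runDir, "regression_summary.json")))
  strat <- stratifiedAgeSlopes(fce, alpha = config$alpha)
  files <- c(files, writeStage(strat$results,
                               file.path(runDir, "age_slopes_by_sex.csv")))
  logline("regress", sprintf("%d significant models (%.1fs)",
                             report$counts$n_significant_models,
                             proc.time()[["elapsed"]] - t0))
  }

  # --- graph ----------------------------------------------------------
  if ("graph" %in% run) {
  t0 <- proc.time()[["elapsed"]]
  grid <- runDensityGrid(fce, grid = config$density_grid_levels,
                         nNulls = config$n_nulls,
                         swapsPerEdge = config$swaps_per_edge,
                         seed = deriveSeed(config$seed, 4L),
                         absolute = config$abs_threshold)
  files <- c(files, writeStage(grid$nodal,
                               file.path(runDir, "graph_nodal.csv")))
  files <- c(files, writeStage(grid$global,
                               file.path(runDir, "graph_global.csv")))
  logline("graph", sprintf("%d densities x %d subjects (%.1fs)",
                           length(config$density_grid_levels), nrow(cohort),
                           proc.time()[["elapsed"]] - t0))
  }

  # --- compare --------------------------------------------------------
  if ("compare" %in% run) {
  t0 <- proc.time()[["elapsed"]]
  nodalCmp <- nodalMetricComparison(grid$nodal, cohort,
                                    metric = "clustering",
                                    alpha = config$alpha,
                                    variant = config$t_variant)
  files <- c(files, writeStage(nodalCmp$perNodeDensity,
                               file.path(runDir, "nodal_comparison.csv")))
  files <- c(files, writeStage(nodalCmp$stack,
                               file.path(runDir, "nodal_stack.csv")))
  globalMetrics <- intersect(c("largest_component", "C_norm", "L_norm",
                               "sigma"), colnames(grid$global))
  globalCmp <- do.call(rbind, lapply(globalMetrics, function(m) {
    cbind(metric = m, globalMetricComparison(grid$global, cohort, m,
                                             variant = config$t_variant))
  }))
  files <- c(files, writeStage(globalCmp,
                               file.path(runDir, "global_comparison.csv")))
  motion <- motionChecks(cohort, variant = config$t_variant)
  if (!is.null(motion)) {
    files <- c(files, writeStage(
      list(fd_sex_t = motion$sex_t$t, fd_sex_p = motion$sex_t$p,
           fd_age_r = motion$age_cor$r, fd_age_p = motion$age_cor$p),
      file.path(runDir, "motion_checks.json")))
  }
  logline("compare", sprintf("done (%.1fs)", proc.time()[["elapsed"]] - t0))
  }

  # --- manifest -------------------------------------------------------
  manifest <- data.frame(file = basename(files),
                         md5 = as.character(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  cfgOut <- config
  class(cfgOut) <- "list"
  jsonlite::write_json(list(config = cfgOut, manifest = manifest),
                       file.path(runDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(runDir = runDir, manifest = manifest, fce = fce,
                 report = report, stratified = strat, grid = grid,
                 nodalComparison = nodalCmp, globalComparison = globalCmp,
                 motion = motion))
}
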