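#' Interpolate per-sample health risk onto the analysis grid
#'
#' The default mode (`"sum_first"`) interpolates the already-summed total
#' carcinogenic risk. The alternative (`"per_pollutant"`) interpolates each
#' pollutant's carcinogenic-risk column separately and sums the resulting
#' rasters; the two generally differ because IDW and summation do not
#' commute across different per-pollutant weight supports.
#'
#' @param health Health results data frame (from [assess_samples()]),
#'   holding `x`, `y`, `tcr` and `cr_<id>` columns.
#' @param spec A [grid_spec()].
#' @param config A `soilrisk_config` (IDW parameters come from it).
#' @param mask Optional nodata mask matrix.
#' @param mode `"sum_first"` (default) or `"per_pollutant"`.
#' @return `soil_raster` of interpolated TCR.
#' @export
map_health_risk <- function(health, spec, config, mask = NULL,
                            mode = c("sum_first", "per_pollutant")) {
  mode <- match.arg(mode)
  p <- config$idw
  pts <- cbind(health$x, health$y)
  if (mode == "sum_first") {
    idw_grid(pts, health$tcr, spec, power = p$power, k = p$k,
             snap_eps = p$snap_eps, mask = mask)
  } else {
    cr_cols <- grep("^cr_", names(health), value = TRUE)
    total <- NULL
    for (cn in cr_cols) {
      r <- idw_grid(pts, health[[cn]], spec, power = p$power, k = p$k,
                    snap_eps = p$snap_eps, mask = mask)
      total <- if (is.null(total)) r$values else total + r$values
    }
    soil_raster(spec, total)
  }
}

#' Summary report of a pipeline run
#'
#' @param health Health results data frame.
#' @param cri CRI results data frame.
#' @param integrated `soil_raster` of integrated class ranks.
#' @param config A `soilrisk_config`.
#' @return A list (JSON-ready) with TCR/THI ranges, the LOO cross-validation
#'   RMSE of the interpolated TCR field, the CRI class distribution, and
#'   per-class integrated areas.
#' @export
risk_report <- function(health, cri, integrated, config) {
  p <- config$idw
  area <- class_area_summary(integrated)
  lv <- as.character(classify_cri(cri$cri, config$thresholds))
  list(
    n_samples = nrow(health),
    tcr = list(min = min(health$tcr), max = max(health$tcr)),
    thi = list(min = min(health$thi), max = max(health$thi)),
    tcr_loo_rmse = loo_rmse(cbind(health$x, health$y), health$tcr,
                            power = p$power, k = p$k, snap_eps = p$snap_eps),
    n_factories = nrow(cri),
    cri = list(min = min(cri$cri), max = max(cri$cri), mean = mean(cri$cri)),
    factories_by_level = as.list(stats::setNames(
      vapply(risk_levels(), function(l) sum(lv == l), 0L), risk_levels())),
    integrated_cells = as.list(stats::setNames(area$cells, area$level)),
    integrated_area_m2 = as.list(stats::setNames(area$area_m2, area$level)))
}

pipeline_stages <- c("simulate", "health", "factory", "map", "integrate", "report")

#' Run the assessment pipeline
#'
#' Executes (a suffix-closed subset of) the stages
#' `simulate -> health -> factory -> map -> integrate -> report`, reading
#' each stage's inputs from `out_dir` so a run can resume from precomputed
#' CSVs. All randomness flows from the single seed; re-running with
#' identical config and seed reproduces byte-identical CSV/ASC outputs.
#'
#' Outputs in `out_dir`: `samples.csv`, `factories.csv`, `landuse.asc`,
#' `truth.json` (simulate); `health.csv` (health); `cri.csv` (factory);
#' `tcr.asc`, `tcr_class.asc` (map); `integrated.asc`, `cri_surface.asc`
#' (integrate); `summary.json` and `run.log` (report).
#'
#' @param config A `soilrisk_config` (or a path to one).
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed; defaults to the config's.
#' @param stages Character vector of stages to run, in pipeline order.
#' @param tcr_mode Interpolation mode for [map_health_risk()].
#' @return The summary list, invisibly (or `NULL` if `report` not run).
#' @export
run_pipeline <- function(config, out_dir, seed = NULL,
                         stages = pipeline_stages,
                         tcr_mode = "sum_first") {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "soilrisk_config"))
  if (is.null(seed)) seed <- if (!is.null(config$seed)) config$seed else 1L
  seed <- as.integer(seed)
  bad <- setdiff(stages, pipeline_stages)
  if (length(bad)) {
    stop("unknown stage: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  stages <- pipeline_stages[pipeline_stages %in% stages]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(out_dir, f)
  need <- function(f, stage) {
    if (!file.exists(pth(f))) {
      stop("stage '", stage, "' needs ", f, " in ", out_dir,
           " (run earlier stages first)", call. = FALSE)
    }
    pth(f)
  }
  log_lines <- c(
    paste0("soilrisk pipeline seed=", seed),
    paste0("stages: ", paste(stages, collapse = " ")))
  timer <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    force(expr)
    log_lines <<- c(log_lines, sprintf("stage %s: %.2f s", stage,
                                       proc.time()[["elapsed"]] - t0))
  }
  spec <- scene_grid_spec(config)
  mask <- reservoir_mask(config, spec)
  summary_out <- NULL

  if ("simulate" %in% stages) timer("simulate", {
    scene <- generate_scene(config, seed)
    write_samples(scene$samples, pth("samples.csv"))
    write_factories(scene$factories, pth("factories.csv"))
    write_raster(scene$landuse, pth("landuse.asc"))
    jsonlite::write_json(scene$truth, pth("truth.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  })
  if ("health" %in% stages) timer("health", {
    samples <- read_samples(need("samples.csv", "health"), config$pollutants)
    landuse <- read_raster(need("landuse.asc", "health"))
    health <- assess_samples(samples, config, landuse)
    write_table_csv(health, pth("health.csv"))
  })
  if ("factory" %in% stages) timer("factory", {
    factories <- read_factories(need("factories.csv", "factory"))
    cri <- assess_factories(factories, config)
    write_table_csv(cri, pth("cri.csv"))
  })
  if ("map" %in% stages) timer("map", {
    health <- utils::read.csv(need("health.csv", "map"))
    tcr <- map_health_risk(health, spec, config, mask = mask, mode = tcr_mode)
    write_raster(tcr, pth("tcr.asc"))
    write_raster(classify_raster(tcr, config$thresholds$tcr_breaks),
                 pth("tcr_class.asc"))
  })
  if ("integrate" %in% stages) timer("integrate", {
    tcr_class <- read_raster(need("tcr_class.asc", "integrate"))
    landuse <- read_raster(need("landuse.asc", "integrate"))
    cri <- utils::read.csv(need("cri.csv", "integrate"))
    integrated <- overlay(tcr_class, landuse, config$matrix)
    surface <- factory_surface(cri, spec, power = config$idw$power,
                               k = config$idw$k,
                               snap_eps = config$idw$snap_eps, mask = mask)
    if (isTRUE(config$factory_escalation)) {
      integrated <- escalate_by_factory_risk(integrated, surface,
                                             config$thresholds$cri_breaks)
    }
    write_raster(integrated, pth("integrated.asc"))
    write_raster(surface, pth("cri_surface.asc"))
  })
  if ("report" %in% stages) timer("report", {
    health <- utils::read.csv(need("health.csv", "report"))
    cri <- utils::read.csv(need("cri.csv", "report"))
    integrated <- read_raster(need("integrated.asc", "report"))
    summary_out <- risk_report(health, cri, integrated, config)
    inputs <- c("samples.csv", "factories.csv", "landuse.asc", "health.csv",
                "cri.csv", "tcr.asc", "tcr_class.asc", "integrated.asc")
    inputs <- inputs[file.exists(file.path(out_dir, inputs))]
    digests <- as.list(tools::md5sum(file.path(out_dir, inputs)))
    names(digests) <- inputs
    summary_out$provenance <- list(seed = seed, input_digests = digests)
    jsonlite::write_json(summary_out, pth("summary.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  })
  writeLines(log_lines, pth("run.log"))
  invisible(summary_out)
}
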