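#' Path to the shipped default configuration
#'
#' @return Path to the package's `default_config.yaml`.
#' @export
default_config_path <- function() {
  system.file("extdata", "default_config.yaml", package = "soilrisk", mustWork = TRUE)
}

#' Load and validate a pipeline configuration
#'
#' @param path Path to a YAML (or JSON) configuration file; defaults to the
#'   configuration shipped with the package.
#' @return A validated `soilrisk_config` object.
#' @export
load_config <- function(path = default_config_path()) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                        simplifyMatrix = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  validate_config(raw)
}

#' Serialize a configuration back to YAML
#'
#' @param config A `soilrisk_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "soilrisk_config"))
  x <- unclass(config)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

cfg_fail <- function(...) stop(paste0(...), call. = FALSE)

check_number <- function(x, key, min = -Inf, max = Inf, strict_min = FALSE,
                         strict_max = FALSE) {
  if (is.null(x) || length(x) != 1L || !is.numeric(x) || !is.finite(x)) {
    cfg_fail("config key '", key, "' must be a single finite number")
  }
  if ((strict_min && x <= min) || (!strict_min && x < min) ||
      (strict_max && x >= max) || (!strict_max && x > max)) {
    cfg_fail("config key '", key, "' out of range (value ", x, ")")
  }
  as.numeric(x)
}

check_breaks <- function(b, key, n = NULL, lower = -Inf, upper = Inf) {
  b <- as.numeric(unlist(b))
  if (!is.null(n) && length(b) != n) {
    cfg_fail("config key '", key, "' must have ", n, " entries")
  }
  if (any(!is.finite(b))) cfg_fail("config key '", key, "' must be finite")
  if (is.unsorted(b, strictly = TRUE)) {
    cfg_fail("non-increasing breaks in config key '", key, "'")
  }
  if (any(b <= lower) || any(b >= upper)) {
    cfg_fail("config key '", key, "' outside (", lower, ", ", upper, ")")
  }
  b
}

check_known_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra)) {
    cfg_fail("unknown config key", if (length(extra) > 1) "s", " in ", where,
             ": ", paste(extra, collapse = ", "))
  }
}

check_rect <- function(r, key) {
  r <- as.numeric(unlist(r))
  if (length(r) != 4L || any(!is.finite(r)) || r[1] >= r[3] || r[2] >= r[4]) {
    cfg_fail("config key '", key, "' must be a rectangle [xmin, ymin, xmax, ymax]")
  }
  r
}

validate_pollutant <- function(p, id) {
  check_known_keys(p, c("group", "sf", "rfd", "abs"), paste0("pollutants.", id))
  if (is.null(p$group) || !(p$group %in% c("heavy_metal", "organic"))) {
    cfg_fail("pollutants.", id, ".group must be 'heavy_metal' or 'organic'")
  }
  pathways <- c("ingestion", "dermal", "inhalation")
  for (fld in c("sf", "rfd")) {
    if (!is.null(p[[fld]])) {
      check_known_keys(p[[fld]], pathways, paste0("pollutants.", id, ".", fld))
      for (pw in names(p[[fld]])) {
        check_number(p[[fld]][[pw]], paste0("pollutants.", id, ".", fld, ".", pw),
                     min = 0, strict_min = TRUE)
      }
    }
  }
  if (length(p$sf) + length(p$rfd) == 0L) {
    cfg_fail("pollutants.", id, " needs at least one of sf/rfd")
  }
  if (!is.null(p$abs)) {
    check_number(p$abs, paste0("pollutants.", id, ".abs"),
                 min = 0, strict_min = TRUE, max = 1)
  }
  p
}

scenario_fields <- c("BW", "EF", "ED", "IngR", "SA", "AF", "ABS", "InhR",
                     "PEF", "AT_ca", "AT_nc", "CF")

validate_scenario <- function(s, lu) {
  check_known_keys(s, scenario_fields, paste0("scenarios.", lu))
  for (fld in scenario_fields) {
    s[[fld]] <- check_number(s[[fld]], paste0("scenarios.", lu, ".", fld),
                             min = 0, strict_min = TRUE)
  }
  if (s$ABS > 1) cfg_fail("scenarios.", lu, ".ABS must be in (0, 1]")
  if (s$AT_ca < s$AT_nc) {
    cfg_fail("scenarios.", lu, ": AT_ca must be >= AT_nc")
  }
  s
}

validate_rule <- function(rule, id) {
  where <- paste0("factory.indicators.", id, ".rule")
  if (is.null(rule$kind) || !(rule$kind %in% c("bins", "categorical", "boolean"))) {
    cfg_fail(where, ".kind must be one of bins, categorical, boolean")
  }
  chk_score <- function(s, k) check_number(s, paste0(where, ".", k), min = 0, max = 3)
  if (rule$kind == "bins") {
    check_known_keys(rule, c("kind", "breaks", "scores"), where)
    rule$breaks <- check_breaks(rule$breaks, paste0(where, ".breaks"))
    rule$scores <- as.numeric(unlist(rule$scores))
    if (length(rule$scores) != length(rule$breaks) + 1L) {
      cfg_fail(where, ": scores must have one more entry than breaks")
    }
    for (s in rule$scores) chk_score(s, "scores")
  } else if (rule$kind == "categorical") {
    check_known_keys(rule, c("kind", "mapping"), where)
    if (length(rule$mapping) == 0L) cfg_fail(where, ".mapping is empty")
    for (lab in names(rule$mapping)) chk_score(rule$mapping[[lab]], lab)
  } else {
    check_known_keys(rule, c("kind", "score_true", "score_false"), where)
    chk_score(rule$score_true, "score_true")
    chk_score(rule$score_false, "score_false")
  }
  rule
}

validate_factory <- function(f) {
  check_known_keys(f, c("weight_mode", "missing_policy", "criterion_weights",
                        "indicators"), "factory")
  if (!(f$weight_mode %in% c("normalized", "raw"))) {
    cfg_fail("factory.weight_mode must be 'normalized' or 'raw'")
  }
  if (!(f$missing_policy %in% c("error", "worst", "renormalize"))) {
    cfg_fail("factory.missing_policy must be one of error, worst, renormalize")
  }
  crits <- c("sudden", "cumulative", "supervision")
  if (!setequal(names(f$criterion_weights), crits)) {
    cfg_fail("factory.criterion_weights must name exactly ",
             paste(crits, collapse = ", "))
  }
  for (cr in crits) {
    check_number(f$criterion_weights[[cr]],
                 paste0("factory.criterion_weights.", cr), min = 0)
  }
  if (length(f$indicators) == 0L) cfg_fail("factory.indicators is empty")
  for (id in names(f$indicators)) {
    ind <- f$indicators[[id]]
    check_known_keys(ind, c("criterion", "weight", "rule"),
                     paste0("factory.indicators.", id))
    if (is.null(ind$criterion) || !(ind$criterion %in% crits)) {
      cfg_fail("factory.indicators.", id, ".criterion must be one of ",
               paste(crits, collapse = ", "))
    }
    check_number(ind$weight, paste0("factory.indicators.", id, ".weight"), min = 0)
    f$indicators[[id]]$rule <- validate_rule(ind$rule, id)
  }
  have <- unique(vapply(f$indicators, `[[`, "", "criterion"))
  missing_cr <- setdiff(crits, have)
  if (length(missing_cr)) {
    cfg_fail("factory: criterion without indicators: ",
             paste(missing_cr, collapse = ", "))
  }
  f
}

validate_matrix_spec <- function(m) {
  lv <- risk_levels()
  lu <- land_use_classes()
  if (!setequal(names(m), lv)) {
    cfg_fail("matrix rows must be exactly the four risk levels")
  }
  for (h in lv) {
    if (!setequal(names(m[[h]]), lu)) {
      cfg_fail("matrix row '", h, "' must have exactly the four land-use columns")
    }
    for (u in lu) {
      v <- m[[h]][[u]]
      if (is.null(v) || !(v %in% lv)) {
        cfg_fail("matrix entry (", h, ", ", u, ") is not a valid risk level")
      }
    }
  }
  m
}

validate_scene <- function(sc, pollutant_ids) {
  check_known_keys(sc, c("extent", "census_spacing", "infill_spacing", "jitter",
                         "hotspots", "reservoir", "landuse", "ph", "background",
                         "low_detection", "organic_detection", "plumes",
                         "factories"), "scene")
  sc$extent <- as.numeric(unlist(sc$extent))
  if (length(sc$extent) != 2L || any(!is.finite(sc$extent)) || any(sc$extent <= 0)) {
    cfg_fail("scene.extent must be two positive numbers (width, height)")
  }
  sc$census_spacing <- check_number(sc$census_spacing, "scene.census_spacing",
                                    min = 0, strict_min = TRUE)
  sc$infill_spacing <- check_number(sc$infill_spacing, "scene.infill_spacing",
                                    min = 0, strict_min = TRUE)
  sc$jitter <- check_number(sc$jitter, "scene.jitter", min = 0,
                            max = sc$census_spacing / 2)
  for (i in seq_along(sc$hotspots)) {
    hs <- sc$hotspots[[i]]
    check_known_keys(hs, c("name", "rect"), paste0("scene.hotspots[", i, "]"))
    r <- check_rect(hs$rect, paste0("scene.hotspots[", i, "].rect"))
    if (r[1] < 0 || r[2] < 0 || r[3] > sc$extent[1] || r[4] > sc$extent[2]) {
      cfg_fail("scene.hotspots[", i, "]: hotspot zone outside extent")
    }
    sc$hotspots[[i]]$rect <- r
  }
  if (!is.null(sc$reservoir)) {
    sc$reservoir <- check_rect(sc$reservoir, "scene.reservoir")
  }
  check_known_keys(sc$landuse, setdiff(land_use_classes(), "agriculture"),
                   "scene.landuse")
  for (lu in names(sc$landuse)) {
    sc$landuse[[lu]] <- lapply(seq_along(sc$landuse[[lu]]), function(i) {
      check_rect(sc$landuse[[lu]][[i]], paste0("scene.landuse.", lu, "[", i, "]"))
    })
  }
  check_number(sc$ph$mean, "scene.ph.mean", min = 0, max = 14)
  check_number(sc$ph$sd, "scene.ph.sd", min = 0)
  for (blk in c("background", "low_detection")) {
    for (id in names(sc[[blk]])) {
      if (!(id %in% pollutant_ids)) {
        cfg_fail("scene.", blk, ".", id, ": pollutant missing from registry")
      }
      check_number(sc[[blk]][[id]]$median, paste0("scene.", blk, ".", id, ".median"),
                   min = 0, strict_min = TRUE)
      check_number(sc[[blk]][[id]]$gsd, paste0("scene.", blk, ".", id, ".gsd"),
                   min = 1)
    }
  }
  sc$organic_detection <- check_number(sc$organic_detection,
                                       "scene.organic_detection", min = 0, max = 1)
  for (i in seq_along(sc$plumes)) {
    pl <- sc$plumes[[i]]
    check_known_keys(pl, c("pollutant", "center", "amplitude", "length_scale"),
                     paste0("scene.plumes[", i, "]"))
    if (!(pl$pollutant %in% pollutant_ids)) {
      cfg_fail("scene.plumes[", i, "]: pollutant '", pl$pollutant,
               "' missing from registry")
    }
    ctr <- as.numeric(unlist(pl$center))
    if (length(ctr) != 2L || any(!is.finite(ctr))) {
      cfg_fail("scene.plumes[", i, "].center must be (x, y)")
    }
    sc$plumes[[i]]$center <- ctr
    check_number(pl$amplitude, paste0("scene.plumes[", i, "].amplitude"), min = 0)
    check_number(pl$length_scale, paste0("scene.plumes[", i, "].length_scale"),
                 min = 0, strict_min = TRUE)
  }
  fc <- sc$factories
  check_known_keys(fc, c("count", "scatter_fraction", "tier_probs", "score_sd",
                         "industries"), "scene.factories")
  check_number(fc$count, "scene.factories.count", min = 0)
  check_number(fc$scatter_fraction, "scene.factories.scatter_fraction",
               min = 0, max = 1)
  if (!all(names(fc$tier_probs) %in% risk_levels())) {
    cfg_fail("scene.factories.tier_probs keys must be risk levels")
  }
  tp <- as.numeric(unlist(fc$tier_probs))
  if (any(tp < 0) || sum(tp) <= 0) {
    cfg_fail("scene.factories.tier_probs must be non-negative with positive sum")
  }
  check_number(fc$score_sd, "scene.factories.score_sd", min = 0)
  sc
}

#' Validate a raw configuration
#'
#' Checks the full configuration schema: unknown keys anywhere are errors,
#' break sequences must be strictly increasing, weights finite and
#' non-negative, every exposure scenario must belong to one of the four
#' land-use classes, and every pollutant referenced by the scene must exist
#' in the registry. Error messages name the offending key.
#'
#' @param raw A nested list as parsed from YAML/JSON.
#' @return A `soilrisk_config` object.
#' @export
validate_config <- function(raw) {
  top <- c("seed", "thresholds", "nondetect_policy", "lod", "pollutants",
           "scenarios", "default_scenario", "factory", "idw", "grid",
           "matrix", "factory_escalation", "scene")
  check_known_keys(raw, top, "top level")
  for (key in setdiff(top, c("seed", "lod", "factory_escalation"))) {
    if (is.null(raw[[key]])) cfg_fail("missing config key '", key, "'")
  }

  check_known_keys(raw$thresholds, c("tcr_breaks", "cri_breaks"), "thresholds")
  raw$thresholds$tcr_breaks <- check_breaks(raw$thresholds$tcr_breaks,
                                            "thresholds.tcr_breaks",
                                            n = 3, lower = 0)
  raw$thresholds$cri_breaks <- check_breaks(raw$thresholds$cri_breaks,
                                            "thresholds.cri_breaks",
                                            n = 3, lower = 0, upper = 3)

  if (!(raw$nondetect_policy %in% c("zero", "lod2"))) {
    cfg_fail("nondetect_policy must be 'zero' or 'lod2'")
  }

  if (length(raw$pollutants) == 0L) cfg_fail("pollutants registry is empty")
  for (id in names(raw$pollutants)) {
    raw$pollutants[[id]] <- validate_pollutant(raw$pollutants[[id]], id)
  }
  for (id in names(raw$lod)) {
    if (!(id %in% names(raw$pollutants))) {
      cfg_fail("lod.", id, ": pollutant missing from registry")
    }
    check_number(raw$lod[[id]], paste0("lod.", id), min = 0, strict_min = TRUE)
  }

  bad_lu <- setdiff(names(raw$scenarios), land_use_classes())
  if (length(bad_lu)) {
    cfg_fail("unknown land-use class in scenarios: ",
             paste(bad_lu, collapse = ", "))
  }
  for (lu in names(raw$scenarios)) {
    raw$scenarios[[lu]] <- validate_scenario(raw$scenarios[[lu]], lu)
  }
  if (!(raw$default_scenario %in% names(raw$scenarios))) {
    cfg_fail("default_scenario '", raw$default_scenario,
             "' has no scenario definition")
  }

  raw$factory <- validate_factory(raw$factory)

  check_known_keys(raw$idw, c("power", "k", "snap_eps"), "idw")
  raw$idw$power <- check_number(raw$idw$power, "idw.power", min = 0,
                                strict_min = TRUE)
  if (!identical(raw$idw$k, "all")) {
    k <- raw$idw$k
    if (!is.numeric(k) || length(k) != 1L || k < 1 || k != floor(k)) {
      cfg_fail("idw.k must be a positive integer or 'all'")
    }
    raw$idw$k <- as.integer(k)
  }
  raw$idw$snap_eps <- check_number(raw$idw$snap_eps, "idw.snap_eps", min = 0)

  check_known_keys(raw$grid, c("cell_size", "nodata"), "grid")
  raw$grid$cell_size <- check_number(raw$grid$cell_size, "grid.cell_size",
                                     min = 0, strict_min = TRUE)
  raw$grid$nodata <- check_number(raw$grid$nodata, "grid.nodata")

  raw$matrix <- validate_matrix_spec(raw$matrix)

  if (is.null(raw$factory_escalation)) raw$factory_escalation <- FALSE
  if (!is.logical(raw$factory_escalation) || length(raw$factory_escalation) != 1L) {
    cfg_fail("factory_escalation must be TRUE or FALSE")
  }

  raw$scene <- validate_scene(raw$scene, names(raw$pollutants))

  if (!is.null(raw$seed)) {
    raw$seed <- as.integer(check_number(raw$seed, "seed"))
  }

  structure(raw, class = "soilrisk_config")
}

#' @export
print.soilrisk_config <- function(x, ...) {
  cat("<soilrisk_config>\n")
  cat("  pollutants:", length(x$pollutants),
      " scenarios:", paste(names(x$scenarios), collapse = "/"), "\n")
  cat("  tcr breaks:", paste(format(x$thresholds$tcr_breaks), collapse = ", "), "\n")
  cat("  cri breaks:", paste(format(x$thresholds$cri_breaks), collapse = ", "), "\n")
  cat("  factory indicators:", length(x$factory$indicators),
      "( weight mode:", x$factory$weight_mode, ")\n")
  cat("  scene extent:", paste(x$scene$extent, collapse = " x "), "m;",
      length(x$scene$plumes), "plumes;", x$scene$factories$count, "factories\n")
  invisible(x)
}
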