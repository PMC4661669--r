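pathways <- c("ingestion", "dermal", "inhalation")

#' Chronic daily intake for one exposure pathway
#'
#' Standard three-pathway soil exposure dose model:
#' \itemize{
#'   \item ingestion: `C * IngR * EF * ED * CF / (BW * AT)`
#'   \item dermal: `C * SA * AF * ABS * EF * ED * CF / (BW * AT)`
#'   \item inhalation: `C * InhR * EF * ED / (PEF * BW * AT)`
#' }
#' with `AT = AT_ca` for the carcinogenic average and `AT_nc` otherwise.
#' The dose is linear in the concentration.
#'
#' @param C Soil concentration, mg/kg (vectorized).
#' @param pathway One of `"ingestion"`, `"dermal"`, `"inhalation"`.
#' @param scenario Exposure scenario (named list, see the shipped config).
#' @param carcinogenic Use the carcinogenic averaging time?
#' @param abs_frac Dermal absorption fraction; defaults to the scenario's
#'   `ABS`, overridden by per-pollutant registry values in [assess_sample()].
#' @return Dose in mg/(kg*d).
#' @export
chronic_daily_intake <- function(C, pathway, scenario, carcinogenic = TRUE,
                                 abs_frac = NULL) {
  if (length(pathway) != 1L || !(pathway %in% pathways)) {
    stop("unknown pathway label: ", paste(pathway, collapse = ", "), call. = FALSE)
  }
  if (any(C < 0, na.rm = TRUE)) stop("concentration must be >= 0", call. = FALSE)
  s <- scenario
  AT <- if (carcinogenic) s$AT_ca else s$AT_nc
  if (is.null(abs_frac)) abs_frac <- s$ABS
  switch(pathway,
    ingestion  = C * s$IngR * s$EF * s$ED * s$CF / (s$BW * AT),
    dermal     = C * s$SA * s$AF * abs_frac * s$EF * s$ED * s$CF / (s$BW * AT),
    inhalation = C * s$InhR * s$EF * s$ED / (s$PEF * s$BW * AT)
  )
}

#' Carcinogenic risk from a chronic dose
#'
#' @param dose Chronic daily intake, mg/(kg*d).
#' @param sf Slope factor, (mg/(kg*d))^-1.
#' @return Incremental lifetime cancer risk (unitless), `dose * sf`.
#' @export
carcinogenic_risk <- function(dose, sf) {
  stopifnot(all(dose >= 0), all(sf > 0))
  dose * sf
}

#' Hazard quotient from a chronic dose
#'
#' @param dose Chronic daily intake, mg/(kg*d).
#' @param rfd Reference dose, mg/(kg*d).
#' @return Hazard quotient (unitless), `dose / rfd`; 1 is the conventional
#'   acceptability boundary.
#' @export
hazard_quotient <- function(dose, rfd) {
  stopifnot(all(dose >= 0), all(rfd > 0))
  dose / rfd
}

#' Classify a total carcinogenic risk value
#'
#' @param tcr Total carcinogenic risk, >= 0 (vectorized; NA propagates).
#' @param thresholds Thresholds list holding `tcr_breaks` (three increasing
#'   positive breaks), or a numeric break vector.
#' @return Ordered risk-level factor.
#' @export
classify_health_risk <- function(tcr, thresholds) {
  breaks <- if (is.list(thresholds)) thresholds$tcr_breaks else thresholds
  if (any(tcr < 0, na.rm = TRUE)) stop("negative TCR", call. = FALSE)
  risk_level(classify_interval(tcr, breaks))
}

effective_conc <- function(conc, id, nondetect_policy, lod) {
  x <- conc[[id]]
  if (is.null(x) || is.na(x)) {
    if (nondetect_policy == "lod2" && !is.null(lod[[id]])) lod[[id]] / 2 else 0
  } else {
    x
  }
}

#' Assess one soil sample
#'
#' Sums carcinogenic risk (CR) over every pollutant and pathway with a slope
#' factor, and hazard quotients (HQ) over every pollutant and pathway with a
#' reference dose. Nondetects (absent/NA concentrations) contribute zero
#' dose under the default policy, or LOD/2 under `nondetect_policy =
#' "lod2"`.
#'
#' @param sample A list or one-row data frame with at least `id` and `conc`
#'   (named list pollutant -> mg/kg; NA = nondetect).
#' @param registry Pollutant registry (named list, see shipped config).
#' @param scenario Exposure scenario list.
#' @param thresholds Thresholds list with `tcr_breaks`.
#' @param nondetect_policy `"zero"` (default) or `"lod2"`.
#' @param lod Named list of detection limits (used by `"lod2"`).
#' @return A list with `id`, `tcr`, `thi`, `level`, per-pollutant `cr` and
#'   `hq`, and the per-pollutant-per-pathway `detail` data frame.
#' @export
assess_sample <- function(sample, registry, scenario, thresholds,
                          nondetect_policy = "zero", lod = list()) {
  conc <- sample$conc
  unknown <- setdiff(names(conc), names(registry))
  if (length(unknown)) {
    stop("pollutant missing from registry: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  ids <- names(conc)
  rows <- list()
  cr_by_pollutant <- stats::setNames(numeric(length(ids)), ids)
  hq_by_pollutant <- stats::setNames(numeric(length(ids)), ids)
  for (id in ids) {
    p <- registry[[id]]
    C <- effective_conc(conc, id, nondetect_policy, lod)
    abs_frac <- if (!is.null(p$abs)) p$abs else scenario$ABS
    for (pw in pathways) {
      sf <- p$sf[[pw]]
      rfd <- p$rfd[[pw]]
      cr <- if (!is.null(sf)) {
        carcinogenic_risk(
          chronic_daily_intake(C, pw, scenario, TRUE, abs_frac), sf)
      } else NA_real_
      hq <- if (!is.null(rfd)) {
        hazard_quotient(
          chronic_daily_intake(C, pw, scenario, FALSE, abs_frac), rfd)
      } else NA_real_
      if (!is.null(sf)) cr_by_pollutant[[id]] <- cr_by_pollutant[[id]] + cr
      if (!is.null(rfd)) hq_by_pollutant[[id]] <- hq_by_pollutant[[id]] + hq
      rows[[length(rows) + 1L]] <- data.frame(
        pollutant = id, pathway = pw, conc = C, cr = cr, hq = hq,
        stringsAsFactors = FALSE)
    }
  }
  detail <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pollutant = character(), pathway = character(),
               conc = numeric(), cr = numeric(), hq = numeric())
  tcr <- sum(cr_by_pollutant)
  thi <- sum(hq_by_pollutant)
  list(id = sample$id, tcr = tcr, thi = thi,
       level = classify_health_risk(tcr, thresholds),
       cr = cr_by_pollutant, hq = hq_by_pollutant, detail = detail)
}

#' Assess a table of soil samples
#'
#' Applies [assess_sample()] to each row of a samples data frame. The
#' exposure scenario for a sample is chosen from the land-use raster cell it
#' falls in; samples outside the raster, on nodata cells, or when no raster
#' is given, use the configured default scenario.
#'
#' @param samples Data frame with columns `id`, `x`, `y`, `point_type`,
#'   `pH`, then one column per pollutant id (NA = nondetect).
#' @param config A `soilrisk_config`.
#' @param landuse Optional land-use raster (`soil_raster` of class codes).
#' @return Data frame: `id`, `x`, `y`, `tcr`, `thi`, `level`, then
#'   per-pollutant carcinogenic-risk columns `cr_<id>`.
#' @export
assess_samples <- function(samples, config, landuse = NULL) {
  meta_cols <- c("id", "x", "y", "point_type", "pH")
  poll_cols <- setdiff(names(samples), meta_cols)
  unknown <- setdiff(poll_cols, names(config$pollutants))
  if (length(unknown)) {
    stop("pollutant missing from registry: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(samples)
  lu_codes <- if (!is.null(landuse)) {
    extract_cells(landuse, samples$x, samples$y)
  } else {
    rep(NA_real_, n)
  }
  scenario_name <- rep(config$default_scenario, n)
  ok <- !is.na(lu_codes) & lu_codes %in% 1:4
  scenario_name[ok] <- land_use_classes()[lu_codes[ok]]
  scenario_name[!(scenario_name %in% names(config$scenarios))] <-
    config$default_scenario

  # effective concentrations under the nondetect policy
  Ceff <- matrix(0, n, length(poll_cols), dimnames = list(NULL, poll_cols))
  for (id in poll_cols) {
    v <- samples[[id]]
    nd <- is.na(v)
    if (config$nondetect_policy == "lod2" && !is.null(config$lod[[id]])) {
      v[nd] <- config$lod[[id]] / 2
    } else {
      v[nd] <- 0
    }
    Ceff[, id] <- v
  }

  # CR and HQ are linear in concentration: per scenario and pollutant,
  # precompute unit-concentration coefficients summed over pathways
  crmat <- matrix(0, n, length(poll_cols),
                  dimnames = list(NULL, paste0("cr_", poll_cols)))
  thi <- numeric(n)
  for (sn in unique(scenario_name)) {
    rows <- scenario_name == sn
    s <- config$scenarios[[sn]]
    for (id in poll_cols) {
      p <- config$pollutants[[id]]
      abs_frac <- if (!is.null(p$abs)) p$abs else s$ABS
      ccr <- 0
      chq <- 0
      for (pw in pathways) {
        if (!is.null(p$sf[[pw]])) {
          ccr <- ccr + chronic_daily_intake(1, pw, s, TRUE, abs_frac) * p$sf[[pw]]
        }
        if (!is.null(p$rfd[[pw]])) {
          chq <- chq + chronic_daily_intake(1, pw, s, FALSE, abs_frac) / p$rfd[[pw]]
        }
      }
      crmat[rows, paste0("cr_", id)] <- Ceff[rows, id] * ccr
      thi[rows] <- thi[rows] + Ceff[rows, id] * chq
    }
  }
  tcr <- rowSums(crmat)
  out <- data.frame(id = samples$id, x = samples$x, y = samples$y,
                    scenario = scenario_name, tcr = tcr, thi = thi,
                    level = as.character(classify_health_risk(tcr, config$thresholds)),
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(crmat))
}
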