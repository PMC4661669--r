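matrix_rank_table <- function(m) {
  m <- validate_matrix_spec(m)
  lv <- risk_levels()
  lu <- land_use_classes()
  tab <- matrix(NA_integer_, 4, 4, dimnames = list(lv, lu))
  for (h in lv) for (u in lu) tab[h, u] <- risk_rank(m[[h]][[u]])
  tab
}

#' Integrated risk class for one (health level, land use) pair
#'
#' Pure lookup in the 4x4 integration matrix: the same health risk weighs
#' more heavily on residential and conservation land than on industrial
#' land.
#'
#' @param health Health-risk level (label or ordered factor).
#' @param land_use Land-use class label.
#' @param m Matrix spec: nested list `m[[health]][[land_use]] -> level` (the
#'   default ships in the package config).
#' @return Integrated risk level (ordered factor).
#' @export
integrated_class <- function(health, land_use, m) {
  tab <- matrix_rank_table(m)
  h <- as.character(risk_level(health))
  land_use <- as.character(land_use)
  bad <- !(land_use %in% land_use_classes())
  if (any(bad)) {
    stop("unknown land-use class: ", paste(unique(land_use[bad]), collapse = ", "),
         call. = FALSE)
  }
  risk_level(tab[cbind(h, land_use)])
}

#' Overlay a health-risk class raster with a land-use raster
#'
#' Cellwise matrix lookup. The two rasters must share one grid (dimensions,
#' origin and cell size equal to 1e-6 relative); a cell is nodata in the
#' result iff it is nodata in either input.
#'
#' @param health_classes `soil_raster` of health-risk class ranks (0..3).
#' @param land_use `soil_raster` of land-use codes (1-based index into
#'   [land_use_classes()]).
#' @param m Matrix spec (see [integrated_class()]).
#' @return `soil_raster` of integrated class ranks (0..3).
#' @export
overlay <- function(health_classes, land_use, m) {
  if (!same_grid(health_classes$spec, land_use$spec)) {
    stop("grid mismatch between health-risk and land-use rasters", call. = FALSE)
  }
  tab <- matrix_rank_table(m)
  h <- as.vector(health_classes$values)
  u <- as.vector(land_use$values)
  if (any(!is.na(h) & (h < 0 | h > 3 | h != floor(h)))) {
    stop("health class raster must hold ranks 0..3", call. = FALSE)
  }
  if (any(!is.na(u) & !(u %in% 1:4))) {
    stop("unknown land-use code in raster: ",
         paste(unique(u[!is.na(u) & !(u %in% 1:4)]), collapse = ", "),
         call. = FALSE)
  }
  out <- rep(NA_real_, length(h))
  ok <- !is.na(h) & !is.na(u)
  out[ok] <- tab[cbind(h[ok] + 1, u[ok])]
  soil_raster(health_classes$spec,
              matrix(out, health_classes$spec$n_rows,
                     health_classes$spec$n_cols))
}

#' Interpolated factory-CRI surface
#'
#' IDW surface of factory comprehensive-risk-index values on the shared
#' analysis grid. The surface is a companion layer to the integrated-risk
#' map: it is reported alongside the matrix classification, not substituted
#' into it.
#'
#' @param factories Data frame with `x`, `y`, `cri` (e.g. from
#'   [assess_factories()]).
#' @param spec A [grid_spec()].
#' @param power,k,snap_eps IDW parameters, as in [idw_predict()].
#' @param mask Optional nodata mask matrix.
#' @return `soil_raster` of interpolated CRI values.
#' @export
factory_surface <- function(factories, spec, power = 2, k = 12,
                            snap_eps = 1e-9, mask = NULL) {
  if (nrow(factories) == 0L) stop("empty factory set", call. = FALSE)
  idw_grid(cbind(factories$x, factories$y), factories$cri, spec,
           power = power, k = k, snap_eps = snap_eps, mask = mask)
}

#' Escalate integrated classes where the factory surface is extreme
#'
#' Optional extension (off by default in the pipeline): raises a cell's
#' integrated class by one level where the interpolated factory-CRI surface
#' exceeds the top CRI break. This goes beyond the pure matrix method and is
#' clearly marked as an extension.
#'
#' @param integrated `soil_raster` of integrated class ranks.
#' @param cri_surface `soil_raster` of CRI values on the same grid.
#' @param cri_breaks CRI breaks; the last one is the escalation threshold.
#' @return `soil_raster` of (possibly escalated) class ranks.
#' @export
escalate_by_factory_risk <- function(integrated, cri_surface,
                                     cri_breaks = c(1, 2, 2.5)) {
  if (!same_grid(integrated$spec, cri_surface$spec)) {
    stop("grid mismatch between integrated map and CRI surface", call. = FALSE)
  }
  thr <- cri_breaks[length(cri_breaks)]
  v <- integrated$values
  hot <- !is.na(cri_surface$values) & cri_surface$values > thr & !is.na(v)
  v[hot] <- pmin(v[hot] + 1, 3)
  soil_raster(integrated$spec, v)
}

#' Summarize a classified raster
#'
#' @param r `soil_raster` of class ranks (0..3).
#' @return Data frame with `level`, `cells`, and `area_m2`
#'   (cells x cell_size^2); nodata cells are excluded.
#' @export
class_area_summary <- function(r) {
  v <- as.vector(r$values)
  counts <- vapply(0:3, function(k) sum(v == k, na.rm = TRUE), 0L)
  data.frame(level = risk_levels(), cells = counts,
             area_m2 = counts * r$spec$cell_size^2)
}
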