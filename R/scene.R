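# run expr with a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

in_rect <- function(x, y, r) {
  x >= r[1] & x < r[3] & y >= r[2] & y < r[4]
}

#' Analysis grid for a scene
#'
#' @param config A `soilrisk_config`.
#' @return A [grid_spec()] covering the scene extent at the configured cell
#'   size, origin at (0, 0).
#' @export
scene_grid_spec <- function(config) {
  ext <- config$scene$extent
  cs <- config$grid$cell_size
  grid_spec(0, 0, cs, ceiling(ext[1] / cs), ceiling(ext[2] / cs),
            nodata = config$grid$nodata)
}

#' Reservoir nodata mask
#'
#' @param config A `soilrisk_config`.
#' @param spec A [grid_spec()].
#' @return Logical matrix, `TRUE` for cells whose center lies in the
#'   reservoir rectangle (or all-`FALSE` when no reservoir is configured).
#' @export
reservoir_mask <- function(config, spec) {
  m <- matrix(FALSE, spec$n_rows, spec$n_cols)
  res <- config$scene$reservoir
  if (!is.null(res)) {
    cc <- cell_centers(spec)
    m[cbind(cc$row, cc$col)] <- in_rect(cc$x, cc$y, res)
  }
  m
}

#' Generate the sampling design
#'
#' Census points follow systematic random grid sampling: one point per
#' `census_spacing` cell, uniformly jittered by up to `jitter` meters around
#' the cell center (jitter 0 gives the exact regular grid). Encrypted infill
#' points sit on `infill_spacing` grids inside the hotspot zones, jittered
#' proportionally. No point falls in the reservoir; coincident points are
#' dropped.
#'
#' @param config A `soilrisk_config`.
#' @param seed Integer seed.
#' @return Data frame `id`, `x`, `y`, `point_type` (concentrations unset).
#' @export
generate_sampling_design <- function(config, seed = config$seed) {
  sc <- config$scene
  grid_points <- function(rect, spacing, jitter, prefix) {
    xs <- seq(rect[1] + spacing / 2, rect[3] - spacing / 2 + 1e-9, by = spacing)
    ys <- seq(rect[2] + spacing / 2, rect[4] - spacing / 2 + 1e-9, by = spacing)
    if (!length(xs) || !length(ys)) {
      return(data.frame(x = numeric(), y = numeric()))
    }
    g <- expand.grid(x = xs, y = ys)
    if (jitter > 0) {
      g$x <- g$x + stats::runif(nrow(g), -jitter, jitter)
      g$y <- g$y + stats::runif(nrow(g), -jitter, jitter)
    }
    g
  }
  pts <- with_seed(seed, {
    census <- grid_points(c(0, 0, sc$extent[1], sc$extent[2]),
                          sc$census_spacing, sc$jitter, "C")
    census$point_type <- "census"
    infill_jitter <- sc$jitter * sc$infill_spacing / sc$census_spacing
    infill <- lapply(sc$hotspots, function(hs) {
      g <- grid_points(hs$rect, sc$infill_spacing, infill_jitter, "E")
      if (nrow(g)) g$point_type <- "encrypted"
      g
    })
    rbind(census, do.call(rbind, infill[vapply(infill, nrow, 0L) > 0]))
  })
  keep <- pts$x >= 0 & pts$x <= sc$extent[1] & pts$y >= 0 & pts$y <= sc$extent[2]
  if (!is.null(sc$reservoir)) {
    keep <- keep & !in_rect(pts$x, pts$y, sc$reservoir)
  }
  pts <- pts[keep, , drop = FALSE]
  # drop points coinciding with an earlier point (possible at jitter 0 where
  # infill grids intersect the census grid)
  if (nrow(pts) > 1L) {
    dup <- logical(nrow(pts))
    for (i in 2:nrow(pts)) {
      d2 <- (pts$x[seq_len(i - 1)] - pts$x[i])^2 + (pts$y[seq_len(i - 1)] - pts$y[i])^2
      dup[i] <- any(d2 < 0.25)
    }
    pts <- pts[!dup, , drop = FALSE]
  }
  pts$id <- sprintf("S%03d", seq_len(nrow(pts)))
  rownames(pts) <- NULL
  pts[, c("id", "x", "y", "point_type")]
}

plume_log_term <- function(x, y, plumes, pollutant) {
  out <- numeric(length(x))
  for (pl in plumes) {
    if (pl$pollutant == pollutant) {
      d2 <- (x - pl$center[1])^2 + (y - pl$center[2])^2
      out <- out + pl$amplitude * exp(-d2 / (2 * pl$length_scale^2))
    }
  }
  out
}

#' Generate concentrations for a sampling design
#'
#' Heavy metals are log-normal around their background medians with plume
#' terms added on the log scale, so every metal is strictly positive (100%
#' detection) and the background coefficient-of-variation structure
#' survives near plumes. Low-detection analytes (Hg and the organics) are
#' detected with probability `organic_detection`; nondetects are `NA`.
#'
#' @param points Data frame from [generate_sampling_design()] (any `x`/`y`
#'   table works).
#' @param config A `soilrisk_config`.
#' @param seed Integer seed.
#' @return Samples data frame: `id`, `x`, `y`, `point_type`, `pH`, one
#'   column per pollutant.
#' @export
generate_concentrations <- function(points, config, seed = config$seed) {
  sc <- config$scene
  n <- nrow(points)
  out <- points
  if (is.null(out$id)) out$id <- sprintf("S%03d", seq_len(n))
  if (is.null(out$point_type)) out$point_type <- "census"
  with_seed(seed, {
    out$pH <- pmin(14, pmax(0, stats::rnorm(n, sc$ph$mean, sc$ph$sd)))
    for (id in names(sc$background)) {
      b <- sc$background[[id]]
      lg <- log(b$median) +
        plume_log_term(points$x, points$y, sc$plumes, id) +
        stats::rnorm(n, 0, log(b$gsd))
      out[[id]] <- exp(lg)
    }
    for (id in names(sc$low_detection)) {
      b <- sc$low_detection[[id]]
      detected <- stats::runif(n) < sc$organic_detection
      lg <- log(b$median) +
        plume_log_term(points$x, points$y, sc$plumes, id) +
        stats::rnorm(n, 0, log(b$gsd))
      v <- exp(lg)
      v[!detected] <- NA_real_
      out[[id]] <- v
    }
  })
  out
}

# representative raw value producing (approximately) the target score
invert_rule <- function(rule, target) {
  switch(rule$kind,
    bins = {
      j <- which.min(abs(rule$scores - target))
      b <- rule$breaks
      nb <- length(b)
      step <- if (nb >= 2) (b[nb] - b[1]) / (nb - 1) else max(abs(b[1]), 1)
      if (j == 1L) {
        lo <- b[1] - 0.5 * step
        if (lo < 0 && b[1] >= 0) lo <- b[1] / 2
        lo
      } else if (j == nb + 1L) {
        b[nb] + 0.5 * step
      } else {
        (b[j - 1] + b[j]) / 2
      }
    },
    categorical = {
      s <- unlist(rule$mapping)
      names(s)[which.min(abs(s - target))]
    },
    boolean = {
      abs(rule$score_true - target) <= abs(rule$score_false - target)
    })
}

#' Generate polluting factories with known latent risk tiers
#'
#' Each factory gets a latent risk tier (drawn from the configured tier
#' probabilities) that drives all of its raw indicator values: indicator
#' target scores are the tier's class midpoint plus Gaussian noise, and the
#' raw attribute is the value the default scoring rule maps back onto that
#' score. Factories are placed inside hotspot zones except for a configured
#' scattered fraction; none in the reservoir.
#'
#' @param config A `soilrisk_config`.
#' @param seed Integer seed.
#' @return List with `factories` (data frame `id`, `x`, `y`, `industry`,
#'   raw indicator columns) and `truth` (data frame `id`, `tier`).
#' @export
generate_factories <- function(config, seed = config$seed) {
  sc <- config$scene
  fc <- sc$factories
  n <- as.integer(fc$count)
  tier_mid <- c(low = 0.5, moderate = 1.5, high = 2.25, extreme = 2.75)
  inds <- config$factory$indicators
  with_seed(seed, {
    tiers <- sample(names(fc$tier_probs), n, replace = TRUE,
                    prob = as.numeric(unlist(fc$tier_probs)))
    xs <- numeric(n); ys <- numeric(n)
    for (i in seq_len(n)) {
      repeat {
        if (length(sc$hotspots) && stats::runif(1) >= fc$scatter_fraction) {
          hs <- sc$hotspots[[sample.int(length(sc$hotspots), 1)]]$rect
        } else {
          hs <- c(0, 0, sc$extent[1], sc$extent[2])
        }
        x <- stats::runif(1, hs[1], hs[3])
        y <- stats::runif(1, hs[2], hs[4])
        if (is.null(sc$reservoir) || !in_rect(x, y, sc$reservoir)) break
      }
      xs[i] <- x; ys[i] <- y
    }
    fac <- data.frame(id = sprintf("F%03d", seq_len(n)), x = xs, y = ys,
                      industry = sample(unlist(fc$industries), n, replace = TRUE),
                      stringsAsFactors = FALSE)
    for (ind_id in names(inds)) {
      rule <- inds[[ind_id]]$rule
      targets <- pmin(3, pmax(0, tier_mid[tiers] + stats::rnorm(n, 0, fc$score_sd)))
      fac[[ind_id]] <- vapply(targets, function(t) invert_rule(rule, t),
                              invert_rule(rule, 0))
    }
    list(factories = fac,
         truth = data.frame(id = fac$id, tier = tiers, stringsAsFactors = FALSE))
  })
}

#' Generate the land-use raster
#'
#' Rectangle-based class painting over an agriculture background, with
#' priority conservation > residential > industrial > agriculture where
#' rectangles overlap; reservoir cells are nodata. Codes index
#' [land_use_classes()] (1 = industrial, 2 = agriculture, 3 = residential,
#' 4 = conservation).
#'
#' @param config A `soilrisk_config`.
#' @return `soil_raster` of land-use codes.
#' @export
generate_landuse <- function(config) {
  spec <- scene_grid_spec(config)
  cc <- cell_centers(spec)
  codes <- rep(2, nrow(cc))  # agriculture background
  paint <- function(codes, rects, code) {
    for (r in rects) codes[in_rect(cc$x, cc$y, r)] <- code
    codes
  }
  lu <- config$scene$landuse
  codes <- paint(codes, lu$industrial, 1)
  codes <- paint(codes, lu$residential, 3)
  codes <- paint(codes, lu$conservation, 4)
  vals <- matrix(NA_real_, spec$n_rows, spec$n_cols)
  vals[cbind(cc$row, cc$col)] <- codes
  vals[reservoir_mask(config, spec)] <- NA_real_
  soil_raster(spec, vals)
}

#' Generate a complete synthetic scene
#'
#' Runs the design, concentration, factory and land-use generators from a
#' single seed and bundles the ground truth needed to score recovery tests
#' (plume centers/amplitudes, land-use rectangles, factory tiers).
#'
#' @param config A `soilrisk_config`.
#' @param seed Integer seed; sub-generators use `seed`, `seed + 1`,
#'   `seed + 2`.
#' @return List: `samples`, `factories`, `landuse`, `truth`, `spec`, `mask`.
#' @export
generate_scene <- function(config, seed = config$seed) {
  design <- generate_sampling_design(config, seed)
  samples <- generate_concentrations(design, config, seed + 1L)
  fx <- generate_factories(config, seed + 2L)
  landuse <- generate_landuse(config)
  spec <- scene_grid_spec(config)
  truth <- list(
    seed = seed,
    plumes = config$scene$plumes,
    landuse_zones = config$scene$landuse,
    reservoir = config$scene$reservoir,
    factory_tiers = fx$truth)
  list(samples = samples, factories = fx$factories, landuse = landuse,
       truth = truth, spec = spec, mask = reservoir_mask(config, spec))
}
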