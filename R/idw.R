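#' Inverse-distance-weighted prediction at one location
#'
#' Weighted mean of the `k` nearest sample values with weights
#' `d^(-power)`. Exact at data points: a query within `snap_eps` of a sample
#' returns that sample's value. Predictions are convex combinations, hence
#' bounded by the range of the values used. Ties at the k-th neighbour
#' distance include every co-distant point, so the result is independent of
#' input order.
#'
#' @param points Two-column matrix (or data frame) of sample coordinates.
#' @param values Numeric vector, one value per point.
#' @param at Length-2 numeric, the query location.
#' @param power IDW power, > 0 (default 2).
#' @param k Neighbour count, or `"all"` (default 12).
#' @param snap_eps Snap distance for exact interpolation, meters.
#' @return The interpolated value.
#' @export
idw_predict <- function(points, values, at, power = 2, k = 12,
                        snap_eps = 1e-9) {
  points <- as.matrix(points)
  if (nrow(points) == 0L) stop("empty point set", call. = FALSE)
  if (nrow(points) != length(values)) {
    stop("points and values lengths differ", call. = FALSE)
  }
  d <- sqrt((points[, 1] - at[1])^2 + (points[, 2] - at[2])^2)
  hit <- which(d <= snap_eps)
  if (length(hit)) return(values[hit[1]])
  if (!identical(k, "all") && k < length(d)) {
    dk <- sort.int(d, partial = k)[k]
    use <- d <= dk
  } else {
    use <- rep(TRUE, length(d))
  }
  du <- d[use]
  w <- (du / min(du))^(-power)  # scaled to avoid under/overflow at large powers
  sum(w * values[use]) / sum(w)
}

#' IDW interpolation onto a raster grid
#'
#' Evaluates [idw_predict()] at every unmasked cell center.
#'
#' @param points,values,power,k,snap_eps As in [idw_predict()].
#' @param spec A [grid_spec()].
#' @param mask Optional logical matrix (`n_rows x n_cols`, north row first);
#'   `TRUE` cells become nodata.
#' @return A `soil_raster`.
#' @export
idw_grid <- function(points, values, spec, power = 2, k = 12,
                     snap_eps = 1e-9, mask = NULL) {
  points <- as.matrix(points)
  if (nrow(points) == 0L) stop("empty point set", call. = FALSE)
  if (nrow(points) != length(values)) {
    stop("points and values lengths differ", call. = FALSE)
  }
  if (!is.null(mask) && !all(dim(mask) == c(spec$n_rows, spec$n_cols))) {
    stop("mask dimensions do not match grid spec", call. = FALSE)
  }
  cc <- cell_centers(spec)
  n <- nrow(points)
  # cells x points squared distances, vectorized
  d2 <- outer(cc$x, points[, 1], `-`)^2 + outer(cc$y, points[, 2], `-`)^2
  d <- sqrt(d2)
  use_all <- identical(k, "all") || k >= n
  pred <- numeric(nrow(cc))
  for (i in seq_len(nrow(cc))) {
    di <- d[i, ]
    hit <- which(di <= snap_eps)
    if (length(hit)) {
      pred[i] <- values[hit[1]]
    } else {
      if (use_all) {
        use <- seq_len(n)
      } else {
        dk <- sort.int(di, partial = k)[k]
        use <- which(di <= dk)
      }
      du <- di[use]
      w <- (du / min(du))^(-power)
      pred[i] <- sum(w * values[use]) / sum(w)
    }
  }
  vals <- matrix(pred, spec$n_rows, spec$n_cols, byrow = TRUE)
  if (!is.null(mask)) vals[mask] <- NA_real_
  soil_raster(spec, vals)
}

#' Leave-one-out cross-validation RMSE
#'
#' Each sample is predicted from all the others; the root mean square of
#' the prediction errors measures interpolation quality in the units of the
#' values.
#'
#' @param points,values,power,k,snap_eps As in [idw_predict()].
#' @return The LOO RMSE.
#' @export
loo_rmse <- function(points, values, power = 2, k = 12, snap_eps = 1e-9) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 2L) stop("leave-one-out needs at least 2 points", call. = FALSE)
  err2 <- numeric(n)
  for (i in seq_len(n)) {
    pred <- idw_predict(points[-i, , drop = FALSE], values[-i], points[i, ],
                        power = power, k = k, snap_eps = snap_eps)
    err2[i] <- (values[i] - pred)^2
  }
  sqrt(mean(err2))
}
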