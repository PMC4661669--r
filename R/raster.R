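#' Grid specification for a planar raster
#'
#' @param x_origin,y_origin Lower-left corner, meters.
#' @param cell_size Cell edge length, meters.
#' @param n_cols,n_rows Grid dimensions.
#' @param nodata Nodata sentinel used in file output (internally nodata is
#'   `NA`).
#' @return A `grid_spec` object.
#' @export
grid_spec <- function(x_origin, y_origin, cell_size, n_cols, n_rows,
                      nodata = -9999) {
  stopifnot(cell_size > 0, n_cols >= 1, n_rows >= 1,
            is.finite(x_origin), is.finite(y_origin))
  structure(list(x_origin = x_origin, y_origin = y_origin,
                 cell_size = cell_size, n_cols = as.integer(n_cols),
                 n_rows = as.integer(n_rows), nodata = nodata),
            class = "grid_spec")
}

#' Construct a raster
#'
#' Values are stored as an `n_rows x n_cols` matrix whose first row is the
#' northernmost row (the ESRI ASCII file order); `NA` marks nodata cells.
#'
#' @param spec A [grid_spec()].
#' @param values Numeric matrix (`n_rows x n_cols`) or a single fill value.
#' @return A `soil_raster` object.
#' @export
soil_raster <- function(spec, values = NA_real_) {
  stopifnot(inherits(spec, "grid_spec"))
  if (is.matrix(values)) {
    if (!all(dim(values) == c(spec$n_rows, spec$n_cols))) {
      stop("values dimensions do not match grid spec", call. = FALSE)
    }
  } else {
    values <- matrix(as.numeric(values), spec$n_rows, spec$n_cols)
  }
  structure(list(spec = spec, values = values), class = "soil_raster")
}

#' @export
print.soil_raster <- function(x, ...) {
  s <- x$spec
  cat("<soil_raster> ", s$n_rows, "x", s$n_cols, " cells of ", s$cell_size,
      " m, origin (", s$x_origin, ", ", s$y_origin, ")\n", sep = "")
  v <- x$values[!is.na(x$values)]
  if (length(v)) {
    cat("  range:", format(min(v)), "..", format(max(v)),
        " nodata cells:", sum(is.na(x$values)), "\n")
  } else {
    cat("  all nodata\n")
  }
  invisible(x)
}

#' Cell-center coordinates
#'
#' @param spec A [grid_spec()].
#' @return Data frame `row`, `col`, `x`, `y` in row-major (north-first)
#'   order matching the value matrix layout.
#' @export
cell_centers <- function(spec) {
  cols <- rep(seq_len(spec$n_cols), times = spec$n_rows)
  rows <- rep(seq_len(spec$n_rows), each = spec$n_cols)
  data.frame(
    row = rows, col = cols,
    x = spec$x_origin + (cols - 0.5) * spec$cell_size,
    y = spec$y_origin + (spec$n_rows - rows + 0.5) * spec$cell_size)
}

#' Look up raster values at point locations
#'
#' @param r A `soil_raster`.
#' @param x,y Point coordinates, meters.
#' @return Values of the containing cells; `NA` for points outside the grid
#'   or on nodata cells.
#' @export
extract_cells <- function(r, x, y) {
  s <- r$spec
  col <- floor((x - s$x_origin) / s$cell_size) + 1
  row_s <- floor((y - s$y_origin) / s$cell_size) + 1
  row <- s$n_rows - row_s + 1
  ok <- col >= 1 & col <= s$n_cols & row >= 1 & row <= s$n_rows &
    is.finite(col) & is.finite(row)
  out <- rep(NA_real_, length(x))
  out[ok] <- r$values[cbind(row[ok], col[ok])]
  out
}

same_grid <- function(a, b, rel_tol = 1e-6) {
  near <- function(p, q) {
    scale <- max(abs(p), abs(q), 1)
    abs(p - q) <= rel_tol * scale
  }
  a$n_cols == b$n_cols && a$n_rows == b$n_rows &&
    near(a$x_origin, b$x_origin) && near(a$y_origin, b$y_origin) &&
    near(a$cell_size, b$cell_size)
}

#' Classify a raster against break values
#'
#' Cellwise interval lookup using the shared lower-open/upper-closed
#' convention (a cell exactly at a break takes the lower class); nodata
#' propagates.
#'
#' @param r A `soil_raster` of values.
#' @param breaks Strictly increasing break vector.
#' @return A `soil_raster` of integer class ranks (0-based).
#' @export
classify_raster <- function(r, breaks) {
  ranks <- classify_interval(as.vector(r$values), breaks)
  soil_raster(r$spec, matrix(as.numeric(ranks), r$spec$n_rows, r$spec$n_cols))
}

# shortest decimal representation that round-trips through as.numeric
fmt_num <- function(x) {
  out <- character(length(x))
  for (i in seq_along(x)) {
    v <- x[i]
    s <- sprintf("%.15g", v)
    if (as.numeric(s) != v) s <- sprintf("%.16g", v)
    if (as.numeric(s) != v) s <- sprintf("%.17g", v)
    out[i] <- s
  }
  out
}

#' Write a raster as an ESRI ASCII grid
#'
#' Header keys `ncols nrows xllcorner yllcorner cellsize NODATA_value` in
#' canonical order, then whitespace-separated rows, northernmost row first.
#' Numbers use the shortest representation that survives a read/write round
#' trip exactly.
#'
#' @param r A `soil_raster`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_raster <- function(r, path) {
  s <- r$spec
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", s$n_cols),
    paste("nrows", s$n_rows),
    paste("xllcorner", fmt_num(s$x_origin)),
    paste("yllcorner", fmt_num(s$y_origin)),
    paste("cellsize", fmt_num(s$cell_size)),
    paste("NODATA_value", fmt_num(s$nodata))), con)
  vals <- r$values
  vals[is.na(vals)] <- s$nodata
  for (i in seq_len(s$n_rows)) {
    writeLines(paste(fmt_num(vals[i, ]), collapse = " "), con)
  }
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path Path to a `.asc` file written in the dialect of
#'   [write_raster()].
#' @return A `soil_raster`; cells equal to the header's nodata value become
#'   `NA`.
#' @export
read_raster <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 7L) stop("not an ESRI ASCII grid: ", path, call. = FALSE)
  hdr_keys <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
                "NODATA_value")
  hdr <- list()
  for (i in 1:6) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(tok) != 2L || tolower(tok[1]) != tolower(hdr_keys[i])) {
      stop("malformed header at line ", i, " of ", path,
           " (expected '", hdr_keys[i], "')", call. = FALSE)
    }
    v <- suppressWarnings(as.numeric(tok[2]))
    if (is.na(v)) {
      stop("unparseable header value at line ", i, " of ", path, call. = FALSE)
    }
    hdr[[hdr_keys[i]]] <- v
  }
  body <- paste(lines[-(1:6)], collapse = " ")
  toks <- strsplit(trimws(body), "\\s+")[[1]]
  vals <- suppressWarnings(as.numeric(toks))
  if (anyNA(vals)) {
    stop("unparseable raster token at position ", which(is.na(vals))[1],
         " of ", path, call. = FALSE)
  }
  nc <- as.integer(hdr$ncols)
  nr <- as.integer(hdr$nrows)
  if (length(vals) != nc * nr) {
    stop("dimension mismatch in ", path, ": header promises ", nr, " x ", nc,
         " = ", nr * nc, " cells, found ", length(vals), call. = FALSE)
  }
  vals[vals == hdr$NODATA_value] <- NA_real_
  spec <- grid_spec(hdr$xllcorner, hdr$yllcorner, hdr$cellsize, nc, nr,
                    nodata = hdr$NODATA_value)
  soil_raster(spec, matrix(vals, nr, nc, byrow = TRUE))
}
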