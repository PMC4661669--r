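# deterministic CSV writer: numerics via shortest round-trip representation,
# NA as empty cell, stable column order
write_table_csv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) {
      s <- rep("", nrow(out))
      ok <- !is.na(out[[j]])
      s[ok] <- fmt_num(out[[j]][ok])
      out[[j]] <- s
    } else {
      out[[j]] <- ifelse(is.na(out[[j]]), "", as.character(out[[j]]))
    }
  }
  utils::write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "")
  invisible(path)
}

#' Write a samples table
#'
#' @param samples Samples data frame (see [read_samples()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(samples, path) write_table_csv(samples, path)

#' Read a samples table
#'
#' CSV contract: mandatory columns `id`, `x`, `y`, `point_type`, `pH`,
#' followed by one column per pollutant id (header names are registry ids).
#' Empty concentration cells are nondetects (`NA`). Malformed numeric cells
#' are reported with their line number.
#'
#' @param path CSV path.
#' @param registry Optional pollutant registry; when given, pollutant
#'   columns must all be registered.
#' @return Samples data frame.
#' @export
read_samples <- function(path, registry = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        na.strings = "")
  mandatory <- c("id", "x", "y", "point_type", "pH")
  missing_cols <- setdiff(mandatory, names(df))
  if (length(missing_cols)) {
    stop("missing mandatory column", if (length(missing_cols) > 1) "s", " in ",
         path, ": ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  poll_cols <- setdiff(names(df), mandatory)
  if (!is.null(registry)) {
    unknown <- setdiff(poll_cols, names(registry))
    if (length(unknown)) {
      stop("pollutant missing from registry: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
  }
  for (colname in c("x", "y", "pH", poll_cols)) {
    v <- df[[colname]]
    if (!is.numeric(v)) {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(num))
      if (length(bad)) {
        stop("non-numeric value in column '", colname, "' of ", path,
             " at line ", bad[1] + 1L, ": '", v[bad[1]], "'", call. = FALSE)
      }
      df[[colname]] <- num
    }
  }
  neg <- poll_cols[vapply(poll_cols, function(cn) any(df[[cn]] < 0, na.rm = TRUE), TRUE)]
  if (length(neg)) {
    stop("negative concentration in column(s): ", paste(neg, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Write a factories table
#'
#' @param factories Factories data frame (see [read_factories()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_factories <- function(factories, path) write_table_csv(factories, path)

#' Read a factories table
#'
#' CSV contract: `id`, `x`, `y`, `industry`, then one raw column per
#' indicator id (numeric, label, or TRUE/FALSE flag).
#'
#' @param path CSV path.
#' @return Factories data frame.
#' @export
read_factories <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        na.strings = "")
  mandatory <- c("id", "x", "y")
  missing_cols <- setdiff(mandatory, names(df))
  if (length(missing_cols)) {
    stop("missing mandatory column", if (length(missing_cols) > 1) "s", " in ",
         path, ": ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df
}
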