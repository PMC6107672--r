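#' Aligned spectra-by-peaks feature matrix
#'
#' The product of preprocessing: one row per spectrum (pixel of a section),
#' one column per aligned peak interval. Intervals are half-open
#' `[center - halfwidth, center + halfwidth)`, non-overlapping and sorted.
#'
#' @param values numeric `n_spectra x n_peaks` matrix, nonnegative
#' @param meta data.frame with columns `x`, `y`, `section`, `group`, one row
#'   per spectrum
#' @param centers ascending peak center m/z values (Da), one per column
#' @param halfwidth interval halfwidth (Da)
#' @return object of class `feature_matrix`
#' @export
feature_matrix <- function(values, meta, centers, halfwidth) {
  stopifnot(is.matrix(values), nrow(values) == nrow(meta),
            ncol(values) == length(centers))
  if (any(values < 0)) stop("feature_matrix: negative value")
  if (length(centers) > 1 && any(diff(centers) <= 0)) {
    stop("feature_matrix: centers not strictly increasing")
  }
  if (length(centers) > 1 && any(diff(centers) < 2 * halfwidth)) {
    stop("feature_matrix: overlapping intervals")
  }
  key <- paste(meta$section, meta$x, meta$y)
  if (anyDuplicated(key)) stop("feature_matrix: a row maps to more than one pixel")
  colnames(values) <- sprintf("mz_%.4f", centers)
  structure(
    list(values = values, meta = as.data.frame(meta), centers = centers,
         halfwidth = halfwidth),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d spectra x %d peak intervals (+/- %.3f Da), m/z %.2f-%.2f\n",
              nrow(x$values), ncol(x$values), x$halfwidth,
              min(x$centers), max(x$centers)))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Find the column index whose interval covers an m/z value
#' @param fm a `feature_matrix`
#' @param mz target m/z (Da)
#' @return integer column index
#' @export
feature_column <- function(fm, mz) {
  d <- abs(fm$centers - mz)
  j <- which.min(d)
  if (d[j] >= fm$halfwidth) {
    stop(sprintf("feature_column: no interval covers m/z %.4f (nearest center %.4f)",
                 mz, fm$centers[j]))
  }
  j
}

#' Subset a feature matrix by rows and/or columns
#' @param fm a `feature_matrix`
#' @param rows,cols logical or integer indices
#' @export
fm_subset <- function(fm, rows = NULL, cols = NULL) {
  v <- fm$values
  m <- fm$meta
  cen <- fm$centers
  if (!is.null(rows)) {
    v <- v[rows, , drop = FALSE]
    m <- m[rows, , drop = FALSE]
  }
  if (!is.null(cols)) {
    v <- v[, cols, drop = FALSE]
    cen <- cen[cols]
  }
  feature_matrix(v, m, cen, fm$halfwidth)
}

#' Serialize a feature matrix to CSV plus a JSON column manifest
#'
#' The CSV holds `x, y, section, group` (plus `tic_raw`, the pre-normalization
#' TIC used for off-tissue detection, when the preprocessing chain recorded
#' it) followed by one column per peak interval; the manifest records centers
#' and halfwidth.
#'
#' @param fm a `feature_matrix`
#' @param path CSV path; the manifest goes to `<path>.manifest.json`
#' @export
write_feature_matrix <- function(fm, path) {
  meta_cols <- intersect(c("x", "y", "section", "group", "tic_raw"),
                         names(fm$meta))
  out <- cbind(fm$meta[, meta_cols], as.data.frame(fm$values))
  utils::write.csv(out, path, row.names = FALSE)
  jsonlite::write_json(
    list(centers = fm$centers, halfwidth = fm$halfwidth),
    paste0(path, ".manifest.json"), digits = NA)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#' @param path CSV path
#' @return a `feature_matrix`
#' @export
read_feature_matrix <- function(path) {
  man <- jsonlite::read_json(paste0(path, ".manifest.json"), simplifyVector = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta_cols <- intersect(c("x", "y", "section", "group", "tic_raw"), names(tab))
  feature_matrix(as.matrix(tab[, setdiff(names(tab), meta_cols), drop = FALSE]),
                 tab[, meta_cols], as.numeric(man$centers),
                 as.numeric(man$halfwidth))
}
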