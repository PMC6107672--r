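#' MSI datacube container
#'
#' In-memory model of one imaging-MS section: a pixel grid, an m/z axis and
#' one intensity vector per pixel. Two axis modes are supported:
#' `"continuous"`-style data where every pixel shares one axis (profile or
#' centroid), stored as a dense `pixels x mz` matrix, and `"processed"`-style
#' data with per-pixel axes, stored as lists.
#'
#' @param coords data.frame with integer columns `x`, `y` (0-based, x
#'   rightward, y downward), one row per pixel
#' @param mz shared ascending m/z axis (Da), or a list of per-pixel axes
#' @param intensities `length(pixels) x length(mz)` matrix, or a list of
#'   per-pixel intensity vectors when `mz` is a list
#' @param mode `"profile"` or `"centroid"`
#' @param section_id section identifier
#' @param group treatment group label (e.g. `"MSC_TX"`, `"control"`)
#' @param pixel_pitch pixel raster width in micrometers (metadata only)
#' @param metadata free-form named list (acquisition settings etc.)
#' @return an object of class `msi_dataset`
#' @export
msi_dataset <- function(coords, mz, intensities, mode = c("profile", "centroid"),
                        section_id = "section1", group = NA_character_,
                        pixel_pitch = 80, metadata = list()) {
  mode <- match.arg(mode)
  coords <- as.data.frame(coords)
  stopifnot(all(c("x", "y") %in% names(coords)))
  coords$x <- as.integer(coords$x)
  coords$y <- as.integer(coords$y)
  d <- structure(
    list(
      coords = coords[, c("x", "y")],
      mz = mz,
      intensities = intensities,
      mode = mode,
      shared_axis = !is.list(mz),
      section_id = section_id,
      group = group,
      pixel_pitch = pixel_pitch,
      metadata = metadata
    ),
    class = "msi_dataset"
  )
  validate_msi_dataset(d)
}

#' Validate an msi_dataset against its invariants
#'
#' Checks: no duplicate pixel coordinates, strictly increasing positive m/z,
#' nonnegative intensities, spectrum count equal to pixel count.
#'
#' @param d an `msi_dataset`
#' @return `d`, invisibly unchanged, or an error
#' @export
validate_msi_dataset <- function(d) {
  if (nrow(d$coords) == 0L) stop("msi_dataset: no pixels")
  key <- paste(d$coords$x, d$coords$y)
  if (anyDuplicated(key)) {
    stop("msi_dataset: duplicate pixel coordinate (",
         d$coords$x[duplicated(key)][1], ",", d$coords$y[duplicated(key)][1], ")")
  }
  check_axis <- function(mz) {
    if (any(mz <= 0)) stop("msi_dataset: nonpositive m/z value")
    if (length(mz) > 1L && any(diff(mz) <= 0)) {
      stop("msi_dataset: m/z axis not strictly increasing")
    }
  }
  if (d$shared_axis) {
    check_axis(d$mz)
    if (!is.matrix(d$intensities)) stop("msi_dataset: intensities must be a matrix for a shared axis")
    if (nrow(d$intensities) != nrow(d$coords)) {
      stop("msi_dataset: spectrum count (", nrow(d$intensities),
           ") != pixel count (", nrow(d$coords), ")")
    }
    if (ncol(d$intensities) != length(d$mz)) {
      stop("msi_dataset: intensity columns != axis length")
    }
    if (any(d$intensities < 0)) stop("msi_dataset: negative intensity")
  } else {
    if (length(d$mz) != nrow(d$coords) || length(d$intensities) != nrow(d$coords)) {
      stop("msi_dataset: per-pixel axis/intensity list length != pixel count")
    }
    for (i in seq_along(d$mz)) {
      check_axis(d$mz[[i]])
      if (length(d$mz[[i]]) != length(d$intensities[[i]])) {
        stop("msi_dataset: pixel ", i, ": axis and intensity lengths differ")
      }
      if (any(d$intensities[[i]] < 0)) stop("msi_dataset: negative intensity at pixel ", i)
    }
  }
  invisible(d)
}

#' @export
print.msi_dataset <- function(x, ...) {
  cat(sprintf("msi_dataset '%s' (%s): %d pixels, %s axis (%s), group=%s\n",
              x$section_id, x$mode, nrow(x$coords),
              if (x$shared_axis) paste0(length(x$mz), " m/z bins, shared")
              else "per-pixel",
              if (x$shared_axis) sprintf("%.2f-%.2f Da", min(x$mz), max(x$mz)) else "",
              x$group))
  invisible(x)
}

#' Number of pixels in a dataset
#' @param d an `msi_dataset`
#' @export
n_pixels <- function(d) nrow(d$coords)

#' Per-pixel total ion count
#' @param d an `msi_dataset`
#' @return numeric vector, one TIC per pixel
#' @export
tic <- function(d) {
  if (d$shared_axis) rowSums(d$intensities) else vapply(d$intensities, sum, 0)
}

#' Mean spectrum over one or several datasets sharing an axis
#'
#' All sections are pooled before averaging ("simultaneous preprocessing"),
#' so a single peak list serves every section.
#'
#' @param datasets an `msi_dataset` or list of them, all on the same axis
#' @return list with `mz` and `intensity`
#' @export
mean_spectrum <- function(datasets) {
  if (inherits(datasets, "msi_dataset")) datasets <- list(datasets)
  ax <- datasets[[1]]$mz
  for (d in datasets) {
    if (!d$shared_axis) stop("mean_spectrum: requires shared-axis datasets")
    if (!isTRUE(all.equal(d$mz, ax))) stop("mean_spectrum: axes differ between sections")
  }
  tot <- Reduce(`+`, lapply(datasets, function(d) colSums(d$intensities)))
  n <- sum(vapply(datasets, n_pixels, 0L))
  list(mz = ax, intensity = tot / n)
}
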