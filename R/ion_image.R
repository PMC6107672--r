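#' Render an ion image
#'
#' Extracts the intensity of one m/z interval per pixel and lays it out on the
#' pixel grid's bounding box. For a centroid dataset, the interval intensity is
#' the sum of centroids with m/z in `[mz - halfwidth, mz + halfwidth)`; for a
#' profile dataset it is the mean over the profile points in that interval
#' (the same conventions as peak alignment). For an aligned
#' [feature_matrix()], the column whose interval covers `mz` is used directly
#' and `halfwidth` is ignored. Grid positions without a measured pixel are
#' `NA`, never zero-filled, so storage order can never change the image.
#'
#' @param x an `msi_dataset` or `feature_matrix`
#' @param mz target m/z (Da)
#' @param halfwidth interval halfwidth in Da (default 0.156, the alignment
#'   interval of the pipeline)
#' @param section for a multi-section feature matrix, which section to render
#' @return a numeric matrix (rows = y, cols = x) of class `ion_image`, with
#'   attributes `mz`, `x0`, `y0` (grid offsets)
#' @export
render_ion_image <- function(x, mz, halfwidth = 0.156, section = NULL) {
  UseMethod("render_ion_image")
}

place_image <- function(coords, values) {
  x0 <- min(coords$x); y0 <- min(coords$y)
  img <- matrix(NA_real_,
                nrow = max(coords$y) - y0 + 1L,
                ncol = max(coords$x) - x0 + 1L)
  img[cbind(coords$y - y0 + 1L, coords$x - x0 + 1L)] <- values
  structure(img, x0 = x0, y0 = y0, class = c("ion_image", "matrix", "array"))
}

#' @export
render_ion_image.msi_dataset <- function(x, mz, halfwidth = 0.156, section = NULL) {
  rng <- if (x$shared_axis) range(x$mz) else range(unlist(lapply(x$mz, range)))
  if (mz < rng[1] || mz > rng[2]) {
    stop("render_ion_image: m/z ", mz, " outside axis range [",
         rng[1], ", ", rng[2], "]")
  }
  lo <- mz - halfwidth
  hi <- mz + halfwidth
  vals <- if (x$shared_axis) {
    sel <- x$mz >= lo & x$mz < hi
    if (!any(sel)) {
      rep(0, n_pixels(x))
    } else if (x$mode == "centroid") {
      rowSums(x$intensities[, sel, drop = FALSE])
    } else {
      rowMeans(x$intensities[, sel, drop = FALSE])
    }
  } else {
    vapply(seq_len(n_pixels(x)), function(i) {
      sel <- x$mz[[i]] >= lo & x$mz[[i]] < hi
      if (!any(sel)) return(0)
      v <- x$intensities[[i]][sel]
      if (x$mode == "centroid") sum(v) else mean(v)
    }, 0)
  }
  place_image(x$coords, vals)
}

#' @export
render_ion_image.feature_matrix <- function(x, mz, halfwidth = 0.156, section = NULL) {
  j <- feature_column(x, mz)
  meta <- x$meta
  keep <- rep(TRUE, nrow(meta))
  if (!is.null(section)) keep <- meta$section == section
  if (!any(keep)) stop("render_ion_image: no pixels for section ", section)
  place_image(data.frame(x = meta$x[keep], y = meta$y[keep]),
              x$values[keep, j])
}

#' Save an image matrix as a grayscale PNG
#'
#' `NA` pixels are rendered black. Intended for quick-look ion images and
#' label maps.
#'
#' @param img numeric matrix (e.g. from [render_ion_image()])
#' @param path output PNG path
#' @export
save_image_png <- function(img, path) {
  m <- unclass(img)
  rng <- range(m, na.rm = TRUE)
  scaled <- if (rng[2] > rng[1]) (m - rng[1]) / (rng[2] - rng[1]) else m * 0
  scaled[is.na(scaled)] <- 0
  png::writePNG(scaled, path)
  invisible(path)
}
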