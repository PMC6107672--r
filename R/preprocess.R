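# Preprocessing: baseline removal -> TIC normalization -> (smoothing inside
# peak detection on the joint mean spectrum) -> fixed-interval peak alignment.
# The order is fixed; preprocess_batch() logs each stage.

moving_min <- function(y, width) {
  n <- length(y)
  half <- floor(width / 2)
  shifts <- (-half):(width - half - 1L)
  do.call(pmin, lapply(shifts, function(s) {
    idx <- pmin(pmax(seq_len(n) + s, 1L), n)
    y[idx]
  }))
}

moving_mean <- function(y, width) {
  n <- length(y)
  half <- floor(width / 2)
  shifts <- (-half):(width - half - 1L)
  Reduce(`+`, lapply(shifts, function(s) {
    idx <- pmin(pmax(seq_len(n) + s, 1L), n)
    y[idx]
  })) / width
}

#' Convolution baseline removal
#'
#' Estimates the baseline of a profile-mode spectrum as a moving minimum
#' followed by a moving average, both with the same window, then subtracts it
#' and clips at zero. The window (`width`) is counted in profile data points.
#' Peak apexes are preserved because the minimum filter ignores narrow peaks
#' and the mean filter only smooths the resulting floor.
#'
#' @param y numeric profile intensity vector, or an `msi_dataset` (profile
#'   mode), in which case every pixel spectrum is corrected
#' @param width window width in data points (default 20)
#' @return same type as the input, baseline-subtracted and clipped at 0
#' @export
remove_baseline <- function(y, width = 20) {
  stopifnot(width >= 1)
  if (inherits(y, "msi_dataset")) {
    if (y$mode != "profile") {
      stop("remove_baseline: baseline removal is a profile-mode operation ",
           "(dataset is centroid)")
    }
    if (y$shared_axis) {
      y$intensities <- t(apply(y$intensities, 1L, remove_baseline, width = width))
    } else {
      y$intensities <- lapply(y$intensities, remove_baseline, width = width)
    }
    return(validate_msi_dataset(y))
  }
  baseline <- moving_mean(moving_min(y, width), width)
  pmax(y - baseline, 0)
}

#' Total ion count normalization
#'
#' Scales every spectrum so that its summed intensity equals the dataset-wide
#' mean pre-normalization TIC. When a list of sections is given, the target is
#' the joint mean over all sections, so sections stay mutually comparable
#' ("simultaneous preprocessing"). All-zero spectra cannot be rescaled; they
#' are left at zero and flagged in the `zero_spectra` attribute so downstream
#' statistics can exclude them.
#'
#' @param x an `msi_dataset`, a list of them, or a `feature_matrix`
#' @param target optional fixed target TIC (used internally for joint
#'   normalization); defaults to the mean observed TIC
#' @return same type as the input
#' @export
tic_normalize <- function(x, target = NULL) {
  if (is.list(x) && !inherits(x, c("msi_dataset", "feature_matrix"))) {
    tics <- unlist(lapply(x, tic))
    if (all(tics == 0)) stop("tic_normalize: all spectra have zero TIC")
    target <- target %||% mean(tics)
    return(lapply(x, tic_normalize, target = target))
  }
  if (inherits(x, "feature_matrix")) {
    t_i <- rowSums(x$values)
    if (all(t_i == 0)) stop("tic_normalize: all spectra have zero TIC")
    target <- target %||% mean(t_i)
    scale <- ifelse(t_i > 0, target / t_i, 0)
    x$values <- x$values * scale
    attr(x, "zero_spectra") <- which(t_i == 0)
    return(x)
  }
  stopifnot(inherits(x, "msi_dataset"))
  t_i <- tic(x)
  if (all(t_i == 0)) stop("tic_normalize: all spectra have zero TIC")
  target <- target %||% mean(t_i)
  scale <- ifelse(t_i > 0, target / t_i, 0)
  if (x$shared_axis) {
    x$intensities <- x$intensities * scale
  } else {
    x$intensities <- Map(function(v, s) v * s, x$intensities, scale)
  }
  attr(x, "zero_spectra") <- which(t_i == 0)
  x
}

SMOOTHING_SIGMA <- c(weak = 1, medium = 2, strong = 4)

gaussian_smooth <- function(y, sigma) {
  half <- max(1L, ceiling(4 * sigma))
  k <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  k <- k / sum(k)
  n <- length(y)
  ypad <- c(rep(y[1], half), y, rep(y[n], half))
  as.numeric(stats::filter(ypad, k, sides = 2))[(half + 1):(half + n)]
}

#' Detect peaks on a mean spectrum
#'
#' Profile mode: smooths the mean spectrum with a Gaussian kernel ("weak",
#' "medium", "strong" map to sigma = 1, 2, 4 profile points), finds local
#' maxima and keeps those above `snr` times the noise level, where noise is
#' the median absolute deviation of the residual (raw minus smoothed).
#' Centroid mode: the centroid positions are the peaks and are passed through
#' (any entry with nonzero mean intensity).
#'
#' @param spec list with `mz` and `intensity` (e.g. from [mean_spectrum()])
#' @param smoothing `"weak"`, `"medium"` (default) or `"strong"`
#' @param snr signal-to-noise floor (default 3)
#' @param mode `"profile"` or `"centroid"`
#' @return numeric vector of peak center m/z values
#' @export
detect_peaks <- function(spec, smoothing = c("medium", "weak", "strong"),
                         snr = 3, mode = c("profile", "centroid")) {
  smoothing <- match.arg(smoothing)
  mode <- match.arg(mode)
  if (length(spec$intensity) == 0) stop("detect_peaks: empty spectrum")
  if (mode == "centroid") {
    return(spec$mz[spec$intensity > 0])
  }
  y <- spec$intensity
  sm <- gaussian_smooth(y, SMOOTHING_SIGMA[[smoothing]])
  noise <- stats::mad(y - sm)
  n <- length(sm)
  if (n < 3) stop("detect_peaks: spectrum too short")
  is_max <- c(FALSE, sm[2:(n - 1)] > sm[1:(n - 2)] & sm[2:(n - 1)] >= sm[3:n], FALSE)
  # peak height is measured above the smoothed floor (median level), so a
  # clipped noise floor with positive mean does not count as signal
  keep <- is_max & (sm - stats::median(sm)) > snr * noise & sm > 0
  spec$mz[keep]
}

#' Align peaks into a fixed-interval feature matrix
#'
#' One column per peak center, with half-open interval
#' `[center - halfwidth, center + halfwidth)`. The column value is the mean of
#' the profile points inside the interval ("mean interval processing"); for
#' centroid data it is the sum of the centroid intensities inside. Centers
#' closer than `2 * halfwidth` would overlap; the weaker one (by joint mean
#' spectrum intensity) is merged away and the merge is logged.
#'
#' @param datasets an `msi_dataset` or list of them on a shared axis
#' @param peak_centers sorted peak center m/z values
#' @param halfwidth interval halfwidth in Da (default 0.156)
#' @return a [feature_matrix()]
#' @export
align_peaks <- function(datasets, peak_centers, halfwidth = 0.156) {
  stopifnot(halfwidth > 0, !is.unsorted(peak_centers))
  if (inherits(datasets, "msi_dataset")) datasets <- list(datasets)
  ms <- mean_spectrum(datasets)

  # resolve overlaps: keep the stronger of any pair closer than 2*halfwidth
  centers <- peak_centers
  repeat {
    if (length(centers) < 2) break
    gaps <- diff(centers)
    bad <- which(gaps < 2 * halfwidth)
    if (length(bad) == 0) break
    i <- bad[1]
    h <- vapply(centers[c(i, i + 1)], function(cm) {
      sel <- ms$mz >= cm - halfwidth & ms$mz < cm + halfwidth
      if (any(sel)) max(ms$intensity[sel]) else 0
    }, 0)
    drop <- if (h[1] >= h[2]) i + 1L else i
    msg("align_peaks: merged overlapping centers %.4f / %.4f -> kept %.4f",
        centers[i], centers[i + 1], centers[c(i, i + 1)][which.max(h)])
    centers <- centers[-drop]
  }

  ax <- datasets[[1]]$mz
  mode <- datasets[[1]]$mode
  cols <- lapply(centers, function(cm) which(ax >= cm - halfwidth & ax < cm + halfwidth))

  blocks <- lapply(datasets, function(d) {
    v <- matrix(0, nrow = n_pixels(d), ncol = length(centers))
    for (j in seq_along(cols)) {
      idx <- cols[[j]]
      if (length(idx) == 0) next
      block <- d$intensities[, idx, drop = FALSE]
      v[, j] <- if (mode == "centroid") rowSums(block) else rowMeans(block)
    }
    v
  })
  meta <- do.call(rbind, lapply(datasets, function(d) {
    data.frame(x = d$coords$x, y = d$coords$y,
               section = d$section_id, group = d$group,
               stringsAsFactors = FALSE)
  }))
  feature_matrix(do.call(rbind, blocks), meta, centers, halfwidth)
}

#' Run the full preprocessing chain on a batch of sections
#'
#' Profile data: per-pixel baseline removal, joint TIC normalization, peak
#' detection on the joint mean spectrum, interval alignment. Centroid data
#' skips baseline removal (a profile-mode operation) and passes the centroid
#' positions through as peak centers.
#'
#' @param datasets list of `msi_dataset` on a shared axis
#' @param baseline_width baseline window in data points
#' @param smoothing smoothing strength for peak detection
#' @param snr signal-to-noise floor for peak detection
#' @param halfwidth alignment interval halfwidth (Da)
#' @return a [feature_matrix()]
#' @export
preprocess_batch <- function(datasets, baseline_width = 20,
                             smoothing = "medium", snr = 3,
                             halfwidth = 0.156) {
  if (inherits(datasets, "msi_dataset")) datasets <- list(datasets)
  mode <- datasets[[1]]$mode
  if (mode == "profile") {
    msg("preprocess: baseline removal (width %d points)", baseline_width)
    datasets <- lapply(datasets, remove_baseline, width = baseline_width)
  } else {
    msg("preprocess: centroid data, baseline removal skipped")
  }
  tic_raw <- unlist(lapply(datasets, tic))  # pre-normalization TIC, kept for
  msg("preprocess: joint TIC normalization over %d section(s)", length(datasets))
  datasets <- tic_normalize(datasets)       # off-tissue detection downstream
  ms <- mean_spectrum(datasets)
  centers <- detect_peaks(ms, smoothing = smoothing, snr = snr, mode = mode)
  msg("preprocess: %d peaks detected (%s smoothing, SNR >= %g)",
      length(centers), smoothing, snr)
  fm <- align_peaks(datasets, centers, halfwidth = halfwidth)
  msg("preprocess: aligned %d m/z intervals (+/- %g Da)", ncol(fm$values), halfwidth)
  fm$meta$tic_raw <- tic_raw
  fm
}
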