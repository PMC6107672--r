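# Region-contrast statistics: rank-based ROC AUC, Wilcoxon rank-sum tests
# (exact by enumeration for small samples, tie-corrected normal approximation
# otherwise), balanced subsampling, and the joint AUC / p-value / intensity
# gates used to call discriminative peaks. Midranks are used everywhere, so
# the statistics are invariant under any strictly monotone transform.

#' Rank-based ROC AUC
#'
#' The probability that a randomly drawn value of `a` exceeds a randomly drawn
#' value of `b`, ties counted half: the Mann-Whitney U statistic divided by
#' `n_a * n_b`.
#'
#' @param a,b numeric vectors, each with >= 1 value (>= 2 for any inference)
#' @return AUC in \[0, 1\]
#' @export
roc_auc <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("roc_auc: empty group")
  r <- rank(c(a, b))
  u <- sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
  u / (length(a) * length(b))
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' For `n_a + n_b <= exact_max` (default 12) the exact null distribution of
#' the U statistic is obtained by enumerating every assignment of the pooled
#' midranks to group a, and the two-sided p-value is the probability of a U
#' at least as far from its null mean `n_a n_b / 2` as observed. Larger
#' samples use the normal approximation with tie and continuity corrections.
#'
#' @param a,b numeric vectors with >= 2 values each
#' @param exact_max sample-size boundary for the exact path
#' @return p-value in (0, 1\]
#' @export
wilcoxon_p <- function(a, b, exact_max = 12) {
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("wilcoxon_p: each group needs >= 2 values")
  r <- rank(c(a, b))
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  if (na + nb <= exact_max) {
    combos <- utils::combn(na + nb, na)
    u_all <- colSums(matrix(r[combos], nrow = na)) - na * (na + 1) / 2
    return(mean(abs(u_all - mu) >= abs(u - mu) - 1e-12))
  }
  n <- na + nb
  ties <- table(r)
  sigma2 <- na * nb * (n + 1) / 12 -
    na * nb * sum(ties^3 - ties) / (12 * n * (n - 1))
  if (sigma2 <= 0) return(1)
  z <- (abs(u - mu) - 0.5) / sqrt(sigma2)   # continuity-corrected
  min(1, 2 * stats::pnorm(-max(z, 0)))
}

#' Balanced random subsample of spectra
#'
#' Uniform sampling without replacement, seeded. When fewer than `n` spectra
#' are available, all are returned with a warning (mirroring how balanced ROC
#' re-analysis falls back on small regions).
#'
#' @param idx integer vector of spectrum indices (one ROI/group)
#' @param n target subsample size (default 6000)
#' @param seed integer seed
#' @return integer vector of selected indices
#' @export
subsample_balanced <- function(idx, n = 6000, seed = 1) {
  if (length(idx) <= n) {
    warning("subsample_balanced: only ", length(idx),
            " spectra available (<= ", n, "); returning all")
    return(idx)
  }
  with_seed(seed, sort(sample(idx, n)))
}

#' Contrast specification for marker discovery
#'
#' Two named filter presets are provided. `"treatment_marker"` uses the
#' region-specific group-contrast gates (AUC < 0.35 or > 0.65, p < 0.01,
#' intensity ratio > 1.2 or < 0.8); `"region_marker"` uses the
#' pathophysiological-region profile (AUC < 0.35 or > 0.65, p < 0.001,
#' delta of min-max-normalized mean intensities > 0.3). The two profiles are
#' kept as published, not reconciled.
#'
#' @param roi_a,roi_b lists selecting spectra, with elements `region` and/or
#'   `group` (e.g. `list(region = "tam", group = "MSC_TX")`)
#' @param preset `"treatment_marker"` or `"region_marker"`
#' @param auc_low,auc_high AUC gates (pass if AUC < auc_low or > auc_high)
#' @param p_max p-value gate
#' @param ratio_low,ratio_high intensity-ratio gates (pass if ratio <
#'   ratio_low or > ratio_high); `NULL` disables
#' @param min_delta minimum delta of min-max-normalized mean intensities;
#'   `NULL` disables
#' @param balance_n balanced subsample size per side; `NULL` disables
#' @param seed seed for subsampling
#' @return a `contrast_spec` list
#' @export
contrast_spec <- function(roi_a, roi_b,
                          preset = c("treatment_marker", "region_marker"),
                          auc_low = 0.35, auc_high = 0.65,
                          p_max = NULL, ratio_low = NULL, ratio_high = NULL,
                          min_delta = NULL, balance_n = NULL, seed = 1) {
  preset <- match.arg(preset)
  if (preset == "treatment_marker") {
    p_max <- p_max %||% 0.01
    ratio_low <- ratio_low %||% 0.8
    ratio_high <- ratio_high %||% 1.2
  } else {
    p_max <- p_max %||% 0.001
    min_delta <- min_delta %||% 0.3
  }
  stopifnot(auc_low >= 0, auc_low < auc_high, auc_high <= 1)
  if (!is.null(ratio_low)) stopifnot(ratio_low < 1, ratio_high > 1)
  structure(list(roi_a = roi_a, roi_b = roi_b, preset = preset,
                 auc_low = auc_low, auc_high = auc_high, p_max = p_max,
                 ratio_low = ratio_low, ratio_high = ratio_high,
                 min_delta = min_delta, balance_n = balance_n, seed = seed),
            class = "contrast_spec")
}

roi_select <- function(annotation, roi) {
  sel <- rep(TRUE, nrow(annotation))
  if (!is.null(roi$region)) sel <- sel & annotation$region %in% roi$region
  if (!is.null(roi$group)) sel <- sel & annotation$group %in% roi$group
  which(sel)
}

#' Discover discriminative peaks between two ROIs
#'
#' Evaluates every aligned peak column: ROC AUC (direction a vs b), two-sided
#' Wilcoxon rank-sum p-value, ratio of mean intensities a/b and delta of
#' min-max-normalized means. A column passes when it clears the AUC gate, the
#' p-value gate and the preset's intensity gate (ratio or delta). Raw
#' statistics are retained for failing columns; no multiple-testing correction
#' is applied by default (the joint gates are the published filter), but
#' Benjamini-Hochberg adjusted p-values can be added with `adjust = "BH"`.
#'
#' @param fm a `feature_matrix`
#' @param annotation a `region_annotation` aligned with `fm`'s rows
#' @param contrast a [contrast_spec()]
#' @param adjust `"none"` (default) or `"BH"`
#' @return a `marker_table` data.frame, one row per column in column order:
#'   `mz, auc, p_value, ratio, delta_norm_intensity, passes, direction`
#' @export
discover_markers <- function(fm, annotation, contrast, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  ia <- roi_select(annotation, contrast$roi_a)
  ib <- roi_select(annotation, contrast$roi_b)
  if (length(intersect(ia, ib)) > 0) stop("discover_markers: overlapping ROIs")
  if (length(ia) < 2 || length(ib) < 2) stop("discover_markers: empty ROI")
  zero <- attr(fm, "zero_spectra")
  if (length(zero)) {
    ia <- setdiff(ia, zero)
    ib <- setdiff(ib, zero)
  }
  if (!is.null(contrast$balance_n)) {
    ia <- subsample_balanced(ia, contrast$balance_n,
                             derive_seed(contrast$seed, "balance_a"))
    ib <- subsample_balanced(ib, contrast$balance_n,
                             derive_seed(contrast$seed, "balance_b"))
  }
  p <- ncol(fm$values)
  auc <- pval <- ratio <- delta <- numeric(p)
  for (j in seq_len(p)) {
    a <- fm$values[ia, j]
    b <- fm$values[ib, j]
    auc[j] <- roc_auc(a, b)
    pval[j] <- wilcoxon_p(a, b)
    mb <- mean(b)
    ratio[j] <- if (mb == 0) Inf else mean(a) / mb
    rng <- range(c(a, b))
    delta[j] <- if (rng[2] == rng[1]) 0 else {
      abs(mean(a) - mean(b)) / (rng[2] - rng[1])
    }
  }
  if (adjust == "BH") pval <- stats::p.adjust(pval, "BH")
  auc_pass <- auc < contrast$auc_low | auc > contrast$auc_high
  p_pass <- pval < contrast$p_max
  int_pass <- rep(TRUE, p)
  if (!is.null(contrast$ratio_low)) {
    int_pass <- int_pass &
      is.finite(ratio) & (ratio < contrast$ratio_low | ratio > contrast$ratio_high)
  }
  if (!is.null(contrast$min_delta)) {
    int_pass <- int_pass & delta > contrast$min_delta
  }
  out <- data.frame(
    mz = fm$centers, auc = auc, p_value = pval, ratio = ratio,
    delta_norm_intensity = delta,
    passes = auc_pass & p_pass & int_pass,
    direction = ifelse(auc > 0.5, "up_in_a", "up_in_b")
  )
  structure(out, contrast = contrast, n_a = length(ia), n_b = length(ib),
            class = c("marker_table", "data.frame"))
}
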