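# Marker-based annotation of pathophysiological regions. Two abundant marker
# peaks (Acts-like, depressed in the trauma core) anchor the split of tissue
# into tm (low marker intensity) and tam (high); off-tissue pixels are found
# from the raw TIC floor. Marker concordance is verified by the Pearson
# correlation of their ion images before any annotation is produced.

#' Marker rule for region annotation
#'
#' @param marker_mzs m/z values of the annotation marker peaks (>= 1)
#' @param low_region label for low-intensity pixels (default `"tm"`)
#' @param high_region label for high-intensity pixels (default `"tam"`)
#' @param min_marker_correlation minimum pairwise image correlation required
#'   between markers (default 0.65)
#' @param tic_floor off-tissue threshold as a fraction of the median raw TIC
#' @return a `marker_rule` list
#' @export
marker_rule <- function(marker_mzs, low_region = "tm", high_region = "tam",
                        min_marker_correlation = 0.65, tic_floor = 0.1) {
  stopifnot(length(marker_mzs) >= 1,
            min_marker_correlation >= -1, min_marker_correlation <= 1)
  structure(list(marker_mzs = marker_mzs, low_region = low_region,
                 high_region = high_region,
                 min_marker_correlation = min_marker_correlation,
                 tic_floor = tic_floor),
            class = "marker_rule")
}

#' Per-pixel region annotation
#'
#' @param meta data.frame with `x`, `y`, `section`, `group` (one row per
#'   spectrum, same order as the feature matrix)
#' @param region character vector in {tm, tam, off_tissue}
#' @param source `"marker_based"`, `"ground_truth"` or `"segmentation"`
#' @return a `region_annotation` (data.frame)
#' @export
region_annotation <- function(meta, region,
                              source = c("marker_based", "ground_truth",
                                         "segmentation")) {
  source <- match.arg(source)
  stopifnot(nrow(meta) == length(region))
  bad <- setdiff(unique(region), c("tm", "tam", "off_tissue"))
  if (length(bad)) stop("region_annotation: unknown label(s): ",
                        paste(bad, collapse = ", "))
  ann <- cbind(meta[, c("x", "y", "section", "group")], region = region)
  structure(ann, source = source, class = c("region_annotation", "data.frame"))
}

raw_tic_of <- function(fm) {
  # raw (pre-normalization) TIC when the preprocessing chain recorded it;
  # otherwise the aligned interval sums
  fm$meta$tic_raw %||% rowSums(fm$values)
}

tissue_mask_of <- function(fm, tic_floor = 0.1) {
  t_raw <- raw_tic_of(fm)
  # reference TIC = median over tissue-like pixels (above the grand mean),
  # so the floor stays put no matter how much of the grid is background
  ref <- stats::median(t_raw[t_raw > mean(t_raw)])
  if (!is.finite(ref)) ref <- stats::median(t_raw)
  t_raw >= tic_floor * ref
}

#' Pearson correlation of two ion images
#'
#' Correlates the per-pixel intensities of two aligned peak columns over
#' tissue pixels. Used as the marker-concordance check before annotation.
#'
#' @param fm a `feature_matrix`
#' @param mz_a,mz_b m/z of the two columns
#' @param tissue_mask logical vector (default: TIC-floor tissue mask)
#' @return correlation in \[-1, 1\]
#' @export
image_correlation <- function(fm, mz_a, mz_b, tissue_mask = NULL) {
  tissue_mask <- tissue_mask %||% tissue_mask_of(fm)
  if (sum(tissue_mask) < 3) stop("image_correlation: fewer than 3 tissue pixels")
  a <- fm$values[tissue_mask, feature_column(fm, mz_a)]
  b <- fm$values[tissue_mask, feature_column(fm, mz_b)]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("image_correlation: constant image, correlation undefined")
  }
  stats::cor(a, b)
}

# Sarle's bimodality coefficient; > 0.555 indicates more structure than a
# unimodal (normal-like) distribution.
bimodality_coefficient <- function(x) {
  n <- length(x)
  m <- mean(x)
  s <- stats::sd(x)
  if (s == 0) return(0)
  g1 <- mean((x - m)^3) / s^3
  g2 <- mean((x - m)^4) / s^4 - 3
  (g1^2 + 1) / (g2 + 3 * (n - 1)^2 / ((n - 2) * (n - 3)))
}

#' Annotate tm/tam regions from marker peaks
#'
#' Off-tissue pixels are those whose raw TIC falls below `tic_floor` times the
#' median. The marker ion images are min-max rescaled over tissue pixels and
#' averaged; a two-class Otsu threshold splits tissue into the low side
#' (`low_region`, tm) and the high side (`high_region`, tam). Because the
#' threshold operates on min-max-rescaled values and Otsu is invariant to
#' affine rescaling, the annotation is unchanged by any monotone-affine
#' rescaling of marker images. With two or more markers, annotation is refused
#' unless every marker pair correlates at least `min_marker_correlation`;
#' annotation is also refused when the averaged marker image shows no bimodal
#' structure (single-region input).
#'
#' @param fm a `feature_matrix`
#' @param rule a [marker_rule()]
#' @return a [region_annotation()] with source `"marker_based"`
#' @export
annotate_from_markers <- function(fm, rule) {
  tissue <- tissue_mask_of(fm, rule$tic_floor)
  if (sum(tissue) < 10) stop("annotate_from_markers: almost no tissue pixels")
  cols <- vapply(rule$marker_mzs, function(m) feature_column(fm, m), 0L)
  if (length(cols) >= 2) {
    pairs <- utils::combn(seq_along(cols), 2)
    for (k in seq_len(ncol(pairs))) {
      i <- pairs[1, k]; j <- pairs[2, k]
      r <- image_correlation(fm, rule$marker_mzs[i], rule$marker_mzs[j], tissue)
      if (r < rule$min_marker_correlation) {
        stop(sprintf(paste0("annotate_from_markers: markers %.4f and %.4f ",
                            "disagree (image correlation %.3f < %.2f); ",
                            "annotation refused"),
                     rule$marker_mzs[i], rule$marker_mzs[j], r,
                     rule$min_marker_correlation))
      }
    }
  }
  scaled <- vapply(cols, function(j) {
    v <- fm$values[tissue, j]
    if (max(v) == min(v)) {
      stop("annotate_from_markers: no bimodal structure in marker image ",
           "(constant); annotation refused")
    }
    rescale01(v)
  }, numeric(sum(tissue)))
  avg <- rowMeans(scaled)
  if (bimodality_coefficient(avg) <= 0.555) {
    stop("annotate_from_markers: no bimodal structure in averaged marker ",
         "image; annotation refused")
  }
  thr <- otsu_threshold(avg)
  region <- rep("off_tissue", nrow(fm$meta))
  region[tissue] <- ifelse(avg > thr, rule$high_region, rule$low_region)
  region_annotation(fm$meta, region, source = "marker_based")
}

#' Validate the tm-vs-tam contrast of a marker peak
#'
#' Computes the ROC AUC (direction: probability that a tm intensity exceeds a
#' tam intensity, so a marker depressed in tm scores well below 0.5) and the
#' two-sided Wilcoxon rank-sum p-value for one marker column across the
#' annotated regions, pooling groups. The marker is accepted when
#' `auc < auc_max` and `p < p_max`.
#'
#' @param fm a `feature_matrix`
#' @param annotation a `region_annotation`
#' @param marker_mz marker m/z
#' @param auc_max AUC acceptance bound (default 0.35)
#' @param p_max p-value acceptance bound (default 0.001)
#' @return list with `auc`, `p_value`, `passes`
#' @export
validate_roi_contrast <- function(fm, annotation, marker_mz,
                                  auc_max = 0.35, p_max = 0.001) {
  j <- feature_column(fm, marker_mz)
  a <- fm$values[annotation$region == "tm", j]
  b <- fm$values[annotation$region == "tam", j]
  if (length(a) < 2 || length(b) < 2) {
    stop("validate_roi_contrast: a region has fewer than 2 spectra")
  }
  auc <- roc_auc(a, b)
  p <- wilcoxon_p(a, b)
  list(auc = auc, p_value = p, passes = auc < auc_max && p < p_max)
}
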