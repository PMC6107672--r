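# Synthetic MALDI-IMS datacubes with planted region and treatment effects.
# The generator emulates the statistical structure the downstream analysis
# assumes: a tissue blob holding a trauma core (tm) inside trauma-adjacent
# tissue (tam), two treatment groups, region markers depressed in tm,
# treatment markers with tam-only group effects, log-normal peak abundances,
# per-pixel TIC variation, an additive noise floor and (in profile mode)
# Gaussian peak shapes on a decaying baseline.

ellipse_mask <- function(nx, ny, cx, cy, ax, ay) {
  xs <- matrix(rep(0:(nx - 1), each = ny), nrow = ny)
  ys <- matrix(rep(0:(ny - 1), nx), nrow = ny)
  ((xs - cx) / ax)^2 + ((ys - cy) / ay)^2 <= 1
}

#' Generate a tissue layout (region mask)
#'
#' Places an elliptical tissue blob covering roughly `tissue_fraction` of the
#' grid, and an elliptical trauma core (tm) inside it covering roughly
#' `tm_fraction` of the tissue; the remaining tissue is trauma-adjacent (tam),
#' everything else off-tissue. Geometry is jittered from the seed; the tm
#' share is corrected iteratively to land within 20% of `tm_fraction`.
#'
#' @param nx,ny grid dimensions (pixels)
#' @param tm_fraction target share of tissue pixels in the trauma core,
#'   in (0, 1)
#' @param seed integer seed; same seed, same mask
#' @param tissue_fraction target share of grid pixels covered by tissue
#' @return object of class `tissue_layout`: `nx`, `ny`, `coords` (all grid
#'   pixels, 0-based), `region` factor per pixel in {tm, tam, off_tissue}
#' @export
make_layout <- function(nx, ny, tm_fraction, seed, tissue_fraction = 0.5) {
  stopifnot(tm_fraction > 0, tm_fraction < 1)
  with_seed(seed, {
    cx <- (nx - 1) / 2 + stats::runif(1, -0.05, 0.05) * nx
    cy <- (ny - 1) / 2 + stats::runif(1, -0.05, 0.05) * ny
    ecc <- stats::runif(1, 0.8, 1.25)
    # pi*ax*ay = tissue_fraction * nx * ny
    ax <- sqrt(tissue_fraction * nx * ny / pi * ecc)
    ay <- ax / ecc
    tissue <- ellipse_mask(nx, ny, cx, cy, ax, ay)
    if (sum(tissue) < 16) {
      stop("make_layout: grid too small to host tissue plus both regions")
    }
    tcx <- cx + stats::runif(1, -0.15, 0.15) * ax
    tcy <- cy + stats::runif(1, -0.15, 0.15) * ay
    tecc <- stats::runif(1, 0.8, 1.25)
    tm_area <- tm_fraction * sum(tissue)
    tax <- sqrt(tm_area / pi * tecc)
    tay <- tax / tecc
    tm <- ellipse_mask(nx, ny, tcx, tcy, tax, tay) & tissue
    for (k in 1:8) {
      share <- sum(tm) / sum(tissue)
      if (share > 0 && abs(share - tm_fraction) <= 0.1 * tm_fraction) break
      adj <- sqrt(tm_fraction / max(share, 1e-3))
      tax <- tax * adj; tay <- tay * adj
      tm <- ellipse_mask(nx, ny, tcx, tcy, tax, tay) & tissue
    }
    if (sum(tm) < 4 || sum(tissue & !tm) < 4) {
      stop("make_layout: grid too small to host tissue plus both regions")
    }
    share <- sum(tm) / sum(tissue)
    if (abs(share - tm_fraction) > 0.2 * tm_fraction) {
      stop(sprintf("make_layout: achieved tm share %.3f outside 20%% of target %.3f",
                   share, tm_fraction))
    }
    region <- ifelse(as.vector(tm), "tm",
                     ifelse(as.vector(tissue), "tam", "off_tissue"))
    coords <- data.frame(x = rep(0:(nx - 1), each = ny), y = rep(0:(ny - 1), nx))
    structure(list(nx = nx, ny = ny, coords = coords, region = region),
              class = "tissue_layout")
  })
}

#' @export
print.tissue_layout <- function(x, ...) {
  cat(sprintf("tissue_layout %dx%d: %d tm, %d tam, %d off-tissue pixels\n",
              x$nx, x$ny, sum(x$region == "tm"), sum(x$region == "tam"),
              sum(x$region == "off_tissue")))
  invisible(x)
}

#' Build a peak panel with planted markers
#'
#' Emulates, at reduced scale, an aligned peak panel over the tryptic-peptide
#' range m/z 800-3500. Three peak roles are planted:
#' \itemize{
#'   \item region markers, depressed in tm relative to tam (factor
#'     `region_ratio_range`); the first two are strong "annotation anchors"
#'     (factor `anchor_ratio`) placed at the Acts-like m/z values 976.44 and
#'     1198.63 and given high base abundance, mirroring how abundant muscle
#'     actin peptides anchor region annotation;
#'   \item treatment markers, group effects in tam only, with
#'     treated/control intensity ratios drawn from `ratio_range` and
#'     alternating direction (up in treated / up in control); by default they
#'     sit at the m/z positions of the bundled reference peptides so that
#'     identity transfer can be exercised end to end;
#'   \item null peaks, all factors 1.
#' }
#' Treatment markers get a below-average base abundance so that, as in real
#' data with hundreds of aligned peaks, discriminative peptides contribute
#' negligibly to the total ion count.
#'
#' @param n_peaks total panel size
#' @param n_region_markers region markers including the two anchors
#' @param n_treatment_markers treatment markers (tam-only group effect)
#' @param ratio_range treated/control intensity ratio range for treatment
#'   markers (default c(1.5, 4))
#' @param seed integer seed
#' @param region_ratio_range tm/tam factor range for non-anchor region markers
#' @param anchor_ratio tm/tam factor of the two annotation anchors
#' @param mz_range panel m/z range (Da)
#' @return data.frame of class `peak_panel`: `mz`, `base`, `tm_factor`,
#'   `tam_group_factor` (treated/control), `role`, `direction`
#' @export
make_peak_panel <- function(n_peaks, n_region_markers = 10,
                            n_treatment_markers = 5,
                            ratio_range = c(1.5, 4), seed = 1,
                            region_ratio_range = c(0.25, 0.6),
                            anchor_ratio = 0.15,
                            mz_range = c(800, 3500)) {
  stopifnot(n_region_markers + n_treatment_markers <= n_peaks,
            ratio_range[1] > 1, ratio_range[1] <= ratio_range[2])
  ref <- reference_peptides()
  with_seed(seed, {
    anchors <- c(976.44, 1198.63)
    n_anchor <- min(2L, n_region_markers)
    trt_mz <- ref$ims_mz_observed[match(
      c("DAGTIAGLNVLR", "TTPSYVAFTDTER", "GGPLSGPYRLR", "SMLRGGPLSGPYR",
        "LGSFGSITR", "GVAGVPAEFSIWTR", "ALGQNPTQAEVLR", "YAPISGGDHAEIDVPK",
        "EGDPATINAATEIDAPR", "AAPAPAAAPAAAPEPERPK"),
      ref$sequence)]
    if (n_treatment_markers > length(trt_mz)) {
      stop("make_peak_panel: at most ", length(trt_mz), " treatment markers supported")
    }
    trt_mz <- trt_mz[seq_len(n_treatment_markers)]
    fixed <- c(anchors[seq_len(n_anchor)], trt_mz)
    n_free <- n_peaks - length(fixed)
    free_mz <- numeric(0)
    pool <- fixed
    while (length(free_mz) < n_free) {
      cand <- stats::runif(1, mz_range[1], mz_range[2])
      if (all(abs(cand - pool) > 1)) {
        free_mz <- c(free_mz, cand)
        pool <- c(pool, cand)
      }
    }
    n_region_free <- n_region_markers - n_anchor
    role <- c(rep("anchor", n_anchor), rep("treatment", n_treatment_markers),
              rep("region", n_region_free),
              rep("null", n_free - n_region_free))
    mz <- c(fixed, free_mz)
    base <- stats::rlnorm(n_peaks, meanlog = log(150), sdlog = 0.4)
    base[role == "anchor"] <- stats::rlnorm(n_anchor, log(250), 0.2)
    base[role == "treatment"] <- stats::rlnorm(n_treatment_markers, log(40), 0.3)
    tm_factor <- rep(1, n_peaks)
    tm_factor[role == "anchor"] <- anchor_ratio
    tm_factor[role == "region"] <- stats::runif(n_region_free,
                                                region_ratio_range[1],
                                                region_ratio_range[2])
    direction <- rep(NA_character_, n_peaks)
    is_trt <- which(role == "treatment")
    direction[is_trt] <- rep(c("up_in_treated", "up_in_treated",
                               "up_in_control", "up_in_control",
                               "up_in_treated"),
                             length.out = n_treatment_markers)
    r <- stats::runif(n_treatment_markers, ratio_range[1], ratio_range[2])
    tam_group_factor <- rep(1, n_peaks)
    tam_group_factor[is_trt] <- ifelse(direction[is_trt] == "up_in_treated", r, 1 / r)
    panel <- data.frame(mz = mz, base = base, tm_factor = tm_factor,
                        tam_group_factor = tam_group_factor,
                        role = role, direction = direction)
    panel <- panel[order(panel$mz), ]
    rownames(panel) <- NULL
    class(panel) <- c("peak_panel", "data.frame")
    panel
  })
}

#' The bundled reference peptide identifications
#'
#' A published validation set of tryptic peptides from rat skeletal-muscle
#' trauma tissue (genes Col6a1, Hspa8, Ca3, Myl3, Flnc, Tnc) with their
#' experimentally reported LC-MS/MS neutral masses, the IMS m/z values they
#' were assigned to, and search-engine scores. Protein accessions are
#' synthetic placeholders (`REF_*`); sequences and masses are as published.
#'
#' @return data.frame with columns `protein_accession`, `gene_name`,
#'   `description`, `sequence`, `lcms_neutral_mass`, `ims_mz_observed`, `score`
#' @export
reference_peptides <- function() {
  path <- system.file("extdata", "reference_peptides.csv", package = "msimarkers")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Simulate one tissue section
#'
#' Per-pixel peak intensity = base x region/group factor x LogNormal(cv) x
#' per-pixel TIC multiplier LogNormal(tic_cv), plus an additive Gaussian noise
#' floor clipped at zero. Off-tissue pixels carry only baseline and noise. In
#' profile mode each peak becomes a Gaussian of width `peak_sigma` on a
#' regular axis, on top of an exponentially decaying baseline. Log-normal
#' multipliers are mean-one, so the noise-free limit and expected intensities
#' both equal base x factor.
#'
#' @param layout a [make_layout()] result
#' @param panel a [make_peak_panel()] result
#' @param group `"MSC_TX"` (treated) or `"control"`
#' @param seed integer seed
#' @param cv log-normal coefficient of variation of peak abundances
#' @param tic_cv log-normal CV of the per-pixel TIC multiplier
#' @param noise_sd additive Gaussian noise floor (intensity units)
#' @param mode `"centroid"` (axis = panel m/z) or `"profile"`
#' @param section_id section identifier
#' @param profile_step axis spacing in Da (profile mode)
#' @param peak_sigma Gaussian peak width in Da (profile mode)
#' @param baseline_params list(b0, lambda): baseline b0*exp(-(mz-min)/lambda)
#'   (profile mode)
#' @param mz_range axis range for profile mode (defaults to panel range +- 5)
#' @return list with `dataset` (an `msi_dataset`) and `truth` (layout, panel,
#'   planted-marker table)
#' @export
simulate_section <- function(layout, panel, group = c("MSC_TX", "control"),
                             seed = 1, cv = 0.3, tic_cv = 0.2, noise_sd = 1,
                             mode = c("centroid", "profile"),
                             section_id = NULL,
                             profile_step = 0.05, peak_sigma = 0.05,
                             baseline_params = list(b0 = 20, lambda = 300),
                             mz_range = NULL) {
  group <- match.arg(group)
  mode <- match.arg(mode)
  if (noise_sd < 0) stop("simulate_section: negative noise_sd")
  if (cv < 0 || tic_cv < 0) stop("simulate_section: negative cv")
  section_id <- section_id %||% paste0(group, "_s", seed)
  treated <- group == "MSC_TX"
  npx <- nrow(layout$coords)
  np <- nrow(panel)

  # expected peak intensity per (pixel, peak): base x region/group factor
  factor_matrix <- matrix(0, nrow = npx, ncol = np)
  for (r in c("tm", "tam")) {
    sel <- layout$region == r
    if (!any(sel)) next
    f <- if (r == "tm") panel$tm_factor else rep(1, np)
    if (r == "tam" && treated) f <- f * panel$tam_group_factor
    factor_matrix[sel, ] <- matrix(panel$base * f, nrow = sum(sel),
                                   ncol = np, byrow = TRUE)
  }

  with_seed(seed, {
    sdlog <- sqrt(log(1 + cv^2))
    noise_mult <- if (cv > 0) {
      matrix(stats::rlnorm(npx * np, -sdlog^2 / 2, sdlog), npx, np)
    } else {
      1
    }
    sdlog_t <- sqrt(log(1 + tic_cv^2))
    tic_mult <- if (tic_cv > 0) {
      stats::rlnorm(npx, -sdlog_t^2 / 2, sdlog_t)
    } else {
      rep(1, npx)
    }
    peak_int <- factor_matrix * noise_mult * tic_mult

    if (mode == "centroid") {
      ints <- peak_int
      if (noise_sd > 0) {
        ints <- pmax(ints + matrix(stats::rnorm(npx * np, 0, noise_sd), npx, np), 0)
      }
      ds <- msi_dataset(layout$coords, panel$mz, ints, mode = "centroid",
                        section_id = section_id, group = group)
    } else {
      mz_range <- mz_range %||% (range(panel$mz) + c(-5, 5))
      ax <- seq(mz_range[1], mz_range[2], by = profile_step)
      shapes <- matrix(0, nrow = np, ncol = length(ax))
      for (j in seq_len(np)) {
        shapes[j, ] <- exp(-(ax - panel$mz[j])^2 / (2 * peak_sigma^2))
      }
      base_curve <- baseline_params$b0 * exp(-(ax - mz_range[1]) / baseline_params$lambda)
      ints <- peak_int %*% shapes +
        matrix(base_curve, npx, length(ax), byrow = TRUE)
      if (noise_sd > 0) {
        ints <- ints + matrix(stats::rnorm(npx * length(ax), 0, noise_sd),
                              npx, length(ax))
      }
      ints <- pmax(ints, 0)
      ds <- msi_dataset(layout$coords, ax, ints, mode = "profile",
                        section_id = section_id, group = group)
    }
    planted <- panel[panel$role != "null", c("mz", "role", "direction",
                                             "tm_factor", "tam_group_factor")]
    list(dataset = ds,
         truth = structure(list(layout = layout, panel = panel,
                                planted = planted, group = group),
                           class = "ground_truth"))
  })
}

#' Simulate the default study-shaped batch
#'
#' Two treatment groups with `sections_per_group` sections each, every section
#' on its own seeded layout, all sections sharing one peak panel. This is the
#' dataset shape the whole pipeline is exercised on.
#'
#' @param seed master seed; layouts, panel and sections derive their own seeds
#' @param nx,ny grid size per section
#' @param sections_per_group sections per treatment group (default 2)
#' @param n_peaks,n_region_markers,n_treatment_markers,ratio_range panel
#'   settings, see [make_peak_panel()]
#' @param tm_fraction,tissue_fraction layout settings, see [make_layout()]
#' @param cv,tic_cv,noise_sd,mode noise settings, see [simulate_section()]
#' @param ... further arguments passed to [simulate_section()]
#' @return list with `datasets` (list of `msi_dataset`), `panel`,
#'   `truths` (per section), `region` / `group` (per pooled spectrum, in
#'   dataset order)
#' @export
simulate_batch <- function(seed = 1, nx = 40, ny = 40, sections_per_group = 2,
                           n_peaks = 50, n_region_markers = 10,
                           n_treatment_markers = 5, ratio_range = c(1.5, 4),
                           tm_fraction = 0.3, tissue_fraction = 0.5,
                           cv = 0.3, tic_cv = 0.2, noise_sd = 1,
                           mode = "centroid", ...) {
  panel <- make_peak_panel(n_peaks, n_region_markers, n_treatment_markers,
                           ratio_range, seed = derive_seed(seed, "panel"))
  datasets <- list()
  truths <- list()
  k <- 0
  for (group in c("MSC_TX", "control")) {
    for (s in seq_len(sections_per_group)) {
      k <- k + 1
      lay <- make_layout(nx, ny, tm_fraction,
                         seed = derive_seed(seed, paste0("layout_", group, "_", s)),
                         tissue_fraction = tissue_fraction)
      sim <- simulate_section(lay, panel, group = group,
                              seed = derive_seed(seed, paste0("section_", group, "_", s)),
                              cv = cv, tic_cv = tic_cv, noise_sd = noise_sd,
                              mode = mode,
                              section_id = paste0(group, "_s", s), ...)
      datasets[[k]] <- sim$dataset
      truths[[k]] <- sim$truth
    }
  }
  list(datasets = datasets, panel = panel, truths = truths,
       region = unlist(lapply(truths, function(t) t$layout$region)),
       group = unlist(lapply(seq_along(datasets),
                             function(i) rep(datasets[[i]]$group,
                                             n_pixels(datasets[[i]])))))
}

#' Emulate a bottom-up LC-MS/MS identification table
#'
#' Experimental neutral masses are the theoretical monoisotopic masses
#' perturbed by a Gaussian ppm error.
#'
#' @param peptides data.frame with `protein_accession`, `gene_name`,
#'   `description`, `sequence` and optionally `score`
#' @param mass_error_sd_ppm Gaussian mass error (ppm), 0 for exact masses
#' @param seed integer seed
#' @return a `peptide_id_table`
#' @export
make_id_table <- function(peptides, mass_error_sd_ppm = 0, seed = 1) {
  peptides <- as.data.frame(peptides)
  if (nrow(peptides) == 0) {
    empty <- data.frame(protein_accession = character(), gene_name = character(),
                        description = character(), sequence = character(),
                        experimental_neutral_mass = numeric(), score = numeric())
    return(as_peptide_id_table(empty))
  }
  theo <- vapply(peptides$sequence, monoisotopic_mass, 0)
  with_seed(seed, {
    err <- stats::rnorm(length(theo), 0, mass_error_sd_ppm)
    peptides$experimental_neutral_mass <- theo * (1 + err * 1e-6)
  })
  if (is.null(peptides$score)) peptides$score <- 50
  as_peptide_id_table(peptides[, PEPTIDE_ID_COLUMNS])
}
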