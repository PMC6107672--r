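# End-to-end orchestration: simulate -> preprocess -> annotate -> segment ->
# decompose -> markers (tam and tm group contrasts) -> match -> report.
# Every stage consumes a seed derived from the master seed, all outputs are
# plain CSV/JSON/PNG on disk, and a manifest records paths, timings and seeds,
# so a rerun with the same config reproduces every CSV byte-identically.

#' Default run configuration
#'
#' All tunable parameters of every stage, with defaults equal to the
#' pipeline's standard settings: baseline width 20 points, alignment interval
#' halfwidth 0.156 Da, medium smoothing, annotation anchors at m/z 976.44 and
#' 1198.63 with marker correlation bound 0.65, treatment-marker gates
#' AUC < 0.35 or > 0.65 / p < 0.01 / ratio < 0.8 or > 1.2, match tolerance
#' 0.9 Da, and the default synthetic batch (40 x 40 grid, 2 sections per
#' group, 50 peaks, 5 treatment markers with ratios 1.5-4, cv 0.3).
#'
#' @param seed master seed (every stage derives its own seed from it)
#' @param out_dir output directory
#' @param ... named overrides of any default element
#' @return a `run_config` list
#' @export
default_run_config <- function(seed = 1, out_dir = "msimarkers_run", ...) {
  cfg <- list(
    seed = seed,
    out_dir = out_dir,
    simulate = list(nx = 40, ny = 40, sections_per_group = 2, n_peaks = 50,
                    n_region_markers = 10, n_treatment_markers = 5,
                    ratio_range = c(1.5, 4), tm_fraction = 0.3,
                    tissue_fraction = 0.5, cv = 0.3, tic_cv = 0.2,
                    noise_sd = 1, mode = "centroid"),
    preprocess = list(baseline_width = 20, smoothing = "medium", snr = 3,
                      halfwidth = 0.156),
    annotate = list(marker_mzs = c(976.44, 1198.63),
                    min_marker_correlation = 0.65, tic_floor = 0.1,
                    validate_auc_max = 0.35, validate_p_max = 0.001),
    segment = list(n_segments = 3),
    decompose = list(n_components = 5),
    markers = list(auc_low = 0.35, auc_high = 0.65, p_max = 0.01,
                   ratio_low = 0.8, ratio_high = 1.2, balance_n = NULL),
    match = list(tolerance = 0.9, mass_error_sd_ppm = 10)
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  validate_run_config(cfg)
}

#' Validate a run configuration
#' @param cfg a run-config list
#' @return the config, classed `run_config`, or an error
#' @export
validate_run_config <- function(cfg) {
  if (is.null(cfg$seed)) stop("run_config: seed must be explicit")
  stopifnot(cfg$preprocess$halfwidth > 0,
            cfg$markers$auc_low < cfg$markers$auc_high,
            cfg$markers$p_max > 0, cfg$markers$p_max <= 1,
            cfg$markers$ratio_low < 1, cfg$markers$ratio_high > 1,
            cfg$annotate$min_marker_correlation >= -1,
            cfg$annotate$min_marker_correlation <= 1,
            cfg$match$tolerance > 0,
            cfg$simulate$tm_fraction > 0, cfg$simulate$tm_fraction < 1)
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#' @param path YAML file with the [default_run_config()] structure
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- unclass(default_run_config(seed = cfg$seed %||% stop("run_config: seed must be explicit"),
                                     out_dir = cfg$out_dir %||% "msimarkers_run"))
  for (nm in setdiff(names(cfg), c("seed", "out_dir"))) {
    if (is.list(cfg[[nm]]) && is.list(base[[nm]])) {
      base[[nm]][names(cfg[[nm]])] <- cfg[[nm]]
    } else {
      base[[nm]] <- cfg[[nm]]
    }
  }
  validate_run_config(base)
}

#' Write a run configuration to YAML
#' @param cfg a `run_config`
#' @param path output path
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  write_run_config(cfg, tf)
  unname(tools::md5sum(tf))
}

#' Run the full pipeline on a synthetic batch
#'
#' Executes, in fixed order: simulate, preprocess, annotate, segment,
#' decompose (PCA and PLSA), markers (tam and tm group contrasts), match,
#' report. Any stage failure halts with the stage name while earlier outputs
#' remain on disk. All stage outputs are CSV/JSON/PNG under `cfg$out_dir`.
#'
#' @param cfg a [default_run_config()]-style `run_config`
#' @return a `run_manifest`: config hash, per-stage output paths and wall
#'   times, seed registry, package version, plus in-memory `results`
#' @export
run_all <- function(cfg) {
  cfg <- validate_run_config(unclass(cfg))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config_hash = config_hash(cfg),
                   version = as.character(utils::packageVersion("msimarkers")),
                   seed = cfg$seed, stages = list())
  results <- list()
  run_stage <- function(name, fn) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(fn(), error = function(e) {
      stop("run_all: stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- list(
      outputs = out$paths, wall_time_s = round(proc.time()[["elapsed"]] - t0, 3))
    results[[name]] <<- out$value
    msg("stage %-10s done (%.2fs)", name, manifest$stages[[name]]$wall_time_s)
  }

  run_stage("simulate", function() {
    sim <- do.call(simulate_batch, c(list(seed = derive_seed(cfg$seed, "simulate")),
                                     cfg$simulate))
    dir <- file.path(cfg$out_dir, "datacubes")
    man <- write_msi_batch(sim$datasets, dir)
    truth_path <- file.path(cfg$out_dir, "ground_truth.json")
    jsonlite::write_json(
      list(panel = sim$panel,
           region = sim$region, group = sim$group),
      truth_path, digits = NA)
    list(value = sim, paths = c(man, truth_path))
  })
  sim <- results$simulate

  run_stage("preprocess", function() {
    fm <- do.call(preprocess_batch, c(list(datasets = sim$datasets),
                                      cfg$preprocess))
    p <- file.path(cfg$out_dir, "feature_matrix.csv")
    write_feature_matrix(fm, p)
    list(value = fm, paths = p)
  })
  fm <- results$preprocess

  run_stage("annotate", function() {
    rule <- marker_rule(cfg$annotate$marker_mzs,
                        min_marker_correlation = cfg$annotate$min_marker_correlation,
                        tic_floor = cfg$annotate$tic_floor)
    ann <- annotate_from_markers(fm, rule)
    val <- lapply(cfg$annotate$marker_mzs, function(m) {
      v <- validate_roi_contrast(fm, ann, m,
                                 auc_max = cfg$annotate$validate_auc_max,
                                 p_max = cfg$annotate$validate_p_max)
      c(mz = m, auc = v$auc, p_value = v$p_value, passes = v$passes)
    })
    p <- file.path(cfg$out_dir, "annotation.csv")
    utils::write.csv(as.data.frame(ann), p, row.names = FALSE)
    vp <- file.path(cfg$out_dir, "annotation_validation.csv")
    utils::write.csv(do.call(rbind, val), vp, row.names = FALSE)
    png_p <- file.path(cfg$out_dir, "annotation_labels.png")
    lab <- place_image(ann[ann$section == ann$section[1], c("x", "y")],
                       as.integer(factor(ann$region[ann$section == ann$section[1]],
                                         levels = c("off_tissue", "tm", "tam"))))
    save_image_png(lab, png_p)
    list(value = ann, paths = c(p, vp, png_p))
  })
  ann <- results$annotate

  tissue <- ann$region != "off_tissue"

  run_stage("segment", function() {
    tree <- bisect_kmeans(fm, cfg$segment$n_segments,
                          seed = derive_seed(cfg$seed, "segment"),
                          rows = tissue)
    p <- file.path(cfg$out_dir, "segmentation.csv")
    out <- cbind(fm$meta[tree$rows, c("x", "y", "section", "group")],
                 as.data.frame(tree$labels))
    names(out)[-(1:4)] <- paste0("level_", seq_len(ncol(tree$labels)))
    utils::write.csv(out, p, row.names = FALSE)
    list(value = tree, paths = p)
  })

  run_stage("decompose", function() {
    pca <- pca_decompose(fm, cfg$decompose$n_components, rows = tissue)
    pl <- plsa_decompose(fm, cfg$decompose$n_components, rows = tissue)
    pp <- file.path(cfg$out_dir, "pca_scores.csv")
    utils::write.csv(cbind(fm$meta[pca$rows, c("x", "y", "section", "group")],
                           as.data.frame(pca$scores)), pp, row.names = FALSE)
    lp <- file.path(cfg$out_dir, "pca_loadings.csv")
    utils::write.csv(data.frame(mz = pca$centers_used, pca$loadings), lp,
                     row.names = FALSE)
    sp <- file.path(cfg$out_dir, "plsa_scores.csv")
    utils::write.csv(cbind(fm$meta[pl$rows, c("x", "y", "section", "group")],
                           as.data.frame(pl$scores)), sp, row.names = FALSE)
    tp <- file.path(cfg$out_dir, "plsa_loglik.csv")
    utils::write.csv(data.frame(iteration = seq_along(pl$log_likelihood),
                                log_likelihood = pl$log_likelihood), tp,
                     row.names = FALSE)
    list(value = list(pca = pca, plsa = pl), paths = c(pp, lp, sp, tp))
  })

  run_stage("markers", function() {
    mk <- list()
    paths <- character(0)
    for (reg in c("tam", "tm")) {
      ctr <- contrast_spec(
        roi_a = list(region = reg, group = "MSC_TX"),
        roi_b = list(region = reg, group = "control"),
        preset = "treatment_marker",
        auc_low = cfg$markers$auc_low, auc_high = cfg$markers$auc_high,
        p_max = cfg$markers$p_max, ratio_low = cfg$markers$ratio_low,
        ratio_high = cfg$markers$ratio_high,
        balance_n = cfg$markers$balance_n,
        seed = derive_seed(cfg$seed, paste0("markers_", reg)))
      mk[[reg]] <- discover_markers(fm, ann, ctr)
      p <- file.path(cfg$out_dir, paste0("markers_", reg, ".csv"))
      utils::write.csv(as.data.frame(mk[[reg]]), p, row.names = FALSE)
      paths <- c(paths, p)
    }
    list(value = mk, paths = paths)
  })
  mk <- results$markers

  run_stage("match", function() {
    ids <- make_id_table(reference_peptides(),
                         mass_error_sd_ppm = cfg$match$mass_error_sd_ppm,
                         seed = derive_seed(cfg$seed, "ids"))
    idp <- file.path(cfg$out_dir, "peptide_ids.csv")
    write_peptide_ids(ids, idp)
    passing <- unique(c(mk$tam$mz[mk$tam$passes], mk$tm$mz[mk$tm$passes]))
    rep <- match_ims_to_lcms(passing, ids, tolerance = cfg$match$tolerance)
    mp <- file.path(cfg$out_dir, "matches.csv")
    utils::write.csv(rep$matches, mp, row.names = FALSE)
    pp <- file.path(cfg$out_dir, "proteins.csv")
    utils::write.csv(rep$proteins, pp, row.names = FALSE)
    list(value = rep, paths = c(idp, mp, pp))
  })

  run_stage("report", function() {
    rep <- build_report(results$match, mk)
    p <- file.path(cfg$out_dir, "identification_report.csv")
    utils::write.csv(rep, p, row.names = FALSE)
    list(value = rep, paths = p)
  })

  manifest$results <- results
  manifest_path <- file.path(cfg$out_dir, "run_manifest.json")
  jsonlite::write_json(
    manifest[c("config_hash", "version", "seed", "stages")],
    manifest_path, auto_unbox = TRUE)
  manifest$path <- manifest_path
  structure(manifest, class = "run_manifest")
}

#' Compare the passing-marker counts of the tam and tm contrasts
#'
#' Summarizes how strongly each pathophysiological region discriminates the
#' treatment groups: counts of passing markers per contrast and their ratio.
#' On the default synthetic batch (treatment effects planted in tam only) the
#' tam contrast must dominate.
#'
#' @param manifest a [run_all()] manifest, or a named list of `marker_table`s
#'   with elements `tam` and `tm`
#' @return list with `tam_count`, `tm_count`, `ratio_tam_tm`
#' @export
compare_contrasts <- function(manifest) {
  mk <- if (inherits(manifest, "run_manifest")) manifest$results$markers else manifest
  if (is.null(mk$tam) || is.null(mk$tm)) {
    stop("compare_contrasts: missing 'tam' or 'tm' marker table")
  }
  tam_n <- sum(mk$tam$passes)
  tm_n <- sum(mk$tm$passes)
  list(tam_count = tam_n, tm_count = tm_n,
       ratio_tam_tm = if (tm_n == 0) Inf else tam_n / tm_n)
}
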