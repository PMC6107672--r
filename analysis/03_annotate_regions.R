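# Annotate the pathophysiological regions from the two Acts-like anchor peaks
# (m/z 976.44 / 1198.63): check marker concordance by ion-image correlation,
# split tissue by the averaged rescaled marker image (Otsu), and confirm each
# anchor's tm-vs-tam contrast (expected: AUC well below 0.35, p < 0.001).

source("analysis/00_config.R")

fm <- read_feature_matrix(file.path(cfg$out_dir, "feature_matrix.csv"))
rule <- marker_rule(cfg$annotate$marker_mzs,
                    min_marker_correlation = cfg$annotate$min_marker_correlation,
                    tic_floor = cfg$annotate$tic_floor)
say("anchor image correlation: %.3f",
    image_correlation(fm, rule$marker_mzs[1], rule$marker_mzs[2]))
ann <- annotate_from_markers(fm, rule)
write.csv(as.data.frame(ann), file.path(cfg$out_dir, "annotation.csv"),
          row.names = FALSE)
say("regions: %d tm, %d tam, %d off-tissue pixels",
    sum(ann$region == "tm"), sum(ann$region == "tam"),
    sum(ann$region == "off_tissue"))
for (m in rule$marker_mzs) {
  v <- validate_roi_contrast(fm, ann, m)
  say("anchor m/z %.2f: AUC(tm/tam) = %.3f, p = %.3g -> %s",
      m, v$auc, v$p_value, if (v$passes) "accepted" else "REJECTED")
}
truth <- jsonlite::read_json(file.path(cfg$out_dir, "ground_truth.json"),
                             simplifyVector = TRUE)
say("agreement with ground truth: %.1f%%",
    100 * mean(ann$region == truth$region))
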