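# Preprocess all sections jointly: (profile data would get convolution
# baseline removal, width 20 points, first), TIC normalization to the joint
# mean, peak detection on the pooled mean spectrum, and +-0.156 Da interval
# alignment into one spectra-by-peaks feature matrix.

source("analysis/00_config.R")

datasets <- read_msi_batch(file.path(cfg$out_dir, "datacubes"))
fm <- do.call(preprocess_batch, c(list(datasets = datasets), cfg$preprocess))
write_feature_matrix(fm, file.path(cfg$out_dir, "feature_matrix.csv"))
say("aligned %d m/z intervals over %d spectra -> %s",
    ncol(fm$values), nrow(fm$values),
    file.path(cfg$out_dir, "feature_matrix.csv"))
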