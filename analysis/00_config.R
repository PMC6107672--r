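# Shared settings for the analysis scripts. Every script can be run from the
# repository root with:  Rscript analysis/0X_<name>.R [seed]
# Stage outputs accumulate under results/run_seed<seed>/.

suppressPackageStartupMessages(library(msimarkers))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L
cfg <- default_run_config(seed = seed,
                          out_dir = file.path("results", paste0("run_seed", seed)))
dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
say <- function(...) cat(sprintf(...), "\n")
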