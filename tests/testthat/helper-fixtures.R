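# Shared fixtures, built once per test run. The "default batch" is the
# study-shaped synthetic dataset: two groups x two sections on 40x40 grids,
# 50 peaks with 2 anchors + 8 region markers + 5 treatment markers, cv 0.3.

.fixtures <- new.env(parent = emptyenv())

default_batch <- function() {
  if (is.null(.fixtures$batch)) {
    cfg <- default_run_config(seed = 1, out_dir = tempfile())
    sim <- do.call(simulate_batch,
                   c(list(seed = derive_seed(1, "simulate")), cfg$simulate))
    fm <- suppressMessages(
      do.call(preprocess_batch, c(list(datasets = sim$datasets), cfg$preprocess)))
    truth_ann <- region_annotation(fm$meta, sim$region, source = "ground_truth")
    .fixtures$batch <- list(cfg = cfg, sim = sim, fm = fm, truth_ann = truth_ann)
  }
  .fixtures$batch
}

# small noise-free section for separable-limit tests
noise_free_section <- function() {
  if (is.null(.fixtures$nf)) {
    lay <- make_layout(20, 20, 0.3, seed = 11, tissue_fraction = 0.6)
    pan <- make_peak_panel(12, 3, 2, ratio_range = c(2, 2), seed = 12)
    .fixtures$nf <- list(
      layout = lay, panel = pan,
      treated = simulate_section(lay, pan, "MSC_TX", seed = 13,
                                 cv = 0, tic_cv = 0, noise_sd = 0),
      control = simulate_section(lay, pan, "control", seed = 14,
                                 cv = 0, tic_cv = 0, noise_sd = 0))
  }
  .fixtures$nf
}

toy_dataset <- function() {
  msi_dataset(data.frame(x = c(0, 1, 0, 1), y = c(0, 0, 1, 1)),
              mz = c(900.5, 1000.25, 1100.75),
              intensities = matrix(c(1, 2, 3,
                                     4, 5, 6,
                                     7, 8, 9,
                                     10, 11, 12), nrow = 4, byrow = TRUE),
              mode = "centroid", section_id = "toy", group = "control")
}

brute_force_auc <- function(a, b) {
  wins <- 0
  for (x in a) for (y in b) wins <- wins + (x > y) + 0.5 * (x == y)
  wins / (length(a) * length(b))
}

python_bin <- function() Sys.which("python")
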