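# Generate the study-shaped synthetic batch: two treatment groups (MSC_TX vs
# control), two 40x40 sections each, 50 aligned peaks of which 2 are abundant
# Acts-like annotation anchors, 8 further region markers depressed in the
# trauma core, and 5 tam-only treatment markers (ratios 1.5-4x, both
# directions). Writes the datacubes plus ground truth.

source("analysis/00_config.R")

sim <- do.call(simulate_batch,
               c(list(seed = derive_seed(cfg$seed, "simulate")), cfg$simulate))
write_msi_batch(sim$datasets, file.path(cfg$out_dir, "datacubes"))
jsonlite::write_json(list(panel = sim$panel, region = sim$region,
                          group = sim$group),
                     file.path(cfg$out_dir, "ground_truth.json"), digits = NA)

say("simulated %d sections (%d pixels each), %d peaks",
    length(sim$datasets), n_pixels(sim$datasets[[1]]), nrow(sim$panel))
say("planted: %d anchors, %d region markers, %d treatment markers (%d up / %d down in MSC_TX)",
    sum(sim$panel$role == "anchor"), sum(sim$panel$role == "region"),
    sum(sim$panel$role == "treatment"),
    sum(sim$panel$direction %in% "up_in_treated"),
    sum(sim$panel$direction %in% "up_in_control"))
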