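# Transfer LC-MS/MS peptide identities onto the discriminative IMS m/z values:
# emulate the bottom-up identification table from the bundled reference
# peptides (10 ppm mass error), match at < 0.9 Da with the lowest-difference
# rule, accept proteins with >= 2 matched peptides, and write the report.

source("analysis/00_config.R")

mk_tam <- read.csv(file.path(cfg$out_dir, "markers_tam.csv"))
mk_tm <- read.csv(file.path(cfg$out_dir, "markers_tm.csv"))
ids <- make_id_table(reference_peptides(),
                     mass_error_sd_ppm = cfg$match$mass_error_sd_ppm,
                     seed = derive_seed(cfg$seed, "ids"))
passing <- unique(c(mk_tam$mz[mk_tam$passes], mk_tm$mz[mk_tm$passes]))
match <- match_ims_to_lcms(passing, ids, tolerance = cfg$match$tolerance)
print(match)
rep <- build_report(match, list(tam = mk_tam, tm = mk_tm))
write.csv(rep, file.path(cfg$out_dir, "identification_report.csv"),
          row.names = FALSE)
say("report: %d peptide rows for %d accepted protein(s) -> %s",
    nrow(rep), sum(match$proteins$accepted),
    file.path(cfg$out_dir, "identification_report.csv"))
print(rep[, c("ims_mz_observed", "ratio_tam", "auc_tam", "sequence",
              "gene_name")])
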