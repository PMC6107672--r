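# Unsupervised views of the batch: bisecting k-means segmentation (3 levels,
# on OMP-selected standardized peaks), 5-component PCA with unit-variance
# scaling, and 5-component PLSA with deterministic initialization.

source("analysis/00_config.R")

fm <- read_feature_matrix(file.path(cfg$out_dir, "feature_matrix.csv"))
ann <- read.csv(file.path(cfg$out_dir, "annotation.csv"))
tissue <- ann$region != "off_tissue"

tree <- bisect_kmeans(fm, cfg$segment$n_segments,
                      seed = derive_seed(cfg$seed, "segment"), rows = tissue)
seg <- cbind(fm$meta[tree$rows, c("x", "y", "section", "group")],
             level_2 = tree$labels[, 2], level_3 = tree$labels[, 3])
write.csv(seg, file.path(cfg$out_dir, "segmentation.csv"), row.names = FALSE)
say("segmentation: split lineage %s",
    paste(tree$split_lineage, collapse = " -> "))
say("level-2 ARI vs marker annotation (tm/tam): %.3f",
    adjusted_rand_index(tree$labels[, 2], ann$region[tree$rows]))

pca <- pca_decompose(fm, cfg$decompose$n_components, rows = tissue)
say("PCA explained variance: %s",
    paste(sprintf("%.1f%%", pca$explained), collapse = ", "))
pl <- plsa_decompose(fm, cfg$decompose$n_components, rows = tissue)
say("PLSA: %d EM iterations, log-likelihood monotone: %s",
    pl$n_iter, all(diff(pl$log_likelihood) >= -1e-8 * abs(pl$log_likelihood[1])))
write.csv(cbind(fm$meta[pca$rows, c("x", "y", "section", "group")],
                pca = pca$scores, plsa = pl$scores),
          file.path(cfg$out_dir, "decomposition_scores.csv"), row.names = FALSE)
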