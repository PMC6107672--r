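Package: msimarkers
Title: Spatial Marker Discovery for MALDI Imaging Mass Spectrometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An open pipeline for region-resolved marker discovery in MALDI
    imaging mass spectrometry (IMS) of tryptic peptides: imzML and plain-array
    datacube I/O, convolution baseline removal, total-ion-count normalization,
    mean-spectrum peak detection and fixed-interval peak alignment,
    marker-based annotation of pathophysiological tissue regions, unsupervised
    segmentation (bisecting k-means on OMP-selected peaks), PCA and
    probabilistic latent semantic analysis of spectra, ROC/Wilcoxon
    discriminative-peak discovery between treatment groups, and transfer of
    bottom-up LC-MS/MS peptide identities onto IMS m/z values. A synthetic
    tissue-datacube generator with planted region and treatment effects makes
    the whole chain testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
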