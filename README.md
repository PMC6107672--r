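# msimarkers

Region-resolved marker discovery for MALDI imaging mass spectrometry (IMS) of
tryptic peptides, built for the question of *where* a therapy changes an
injured tissue: in the primary trauma core (**tm**) or in the trauma-adjacent
region (**tam**).

MALDI-IMS acquires one peptide mass spectrum per pixel of a tissue section.
`msimarkers` turns a batch of such datacubes into region-resolved treatment
markers with transferred peptide identities:

1. **Preprocessing** — convolution baseline removal (moving minimum + moving
   average, window 20 points), TIC normalization to the joint batch mean,
   peak detection on the pooled mean spectrum (Gaussian smoothing, SNR ≥ 3),
   and alignment into half-open ±0.156 Da intervals: a spectra × peaks
   feature matrix.
2. **Region annotation** — abundant muscle-actin marker peaks (m/z 976.44,
   1198.63), strongly depressed in the trauma core, are cross-checked by
   ion-image correlation (≥ 0.65) and split tissue by an Otsu threshold on
   the averaged rescaled marker image; off-tissue pixels are removed by a raw
   TIC floor. Anchors must re-validate with ROC AUC(tm/tam) < 0.35 and
   Wilcoxon p < 0.001.
3. **Unsupervised cross-checks** — bisecting k-means segmentation (on
   OMP-selected, standardized peaks), 5-component PCA with unit-variance
   scaling, and 5-component PLSA (EM aspect model,
   `P(w|d) = Σ_z P(z|d) P(w|z)`, deterministic nonnegative-SVD init).
4. **Marker discovery** — per peak: rank-based ROC AUC (Mann-Whitney
   U / n_a·n_b), two-sided Wilcoxon rank-sum p (exact by enumeration for
   n ≤ 12), mean-intensity ratio; the joint treatment gates are
   AUC < 0.35 or > 0.65, p < 0.01, ratio < 0.8 or > 1.2, with optional
   balanced subsampling for unequal regions.
5. **Identity transfer** — IMS m/z → neutral mass (−1.007276 Da), matched to
   bottom-up LC-MS/MS peptides within < 0.9 Da by lowest mass difference;
   proteins accepted only with ≥ 2 matched peptides; report in the standard
   column order (IMS m/z, Mr, ratios/AUCs per region, LC-MS/MS Mr, delta Da,
   delta ppm, score, sequence, gene).

Because the motivating study deposited no data, the package ships a
ground-truthed synthetic generator (`simulate_batch()`): tissue layouts with
a tm core inside tam, log-normal peak abundances, per-pixel TIC variation,
region markers depressed in tm and tam-only treatment markers with 1.5–4×
effects in both directions. Every stage is tested against that ground truth.
I/O covers imzML (continuous + processed; interoperable with pyimzML) and a
plain-array JSON exchange format.

## Worked example

The numbered scripts under `analysis/` run the whole study shape; the same
happens in one call with `run_all()`:

```r
library(msimarkers)
cfg <- default_run_config(seed = 1, out_dir = "msimarkers_run")
man <- run_all(cfg)        # simulate -> ... -> report, all outputs as CSV/JSON/PNG
compare_contrasts(man)
```

Running the scripts (`Rscript analysis/01_simulate.R` … `06_transfer_identities.R`)
prints, at seed 1:

```
simulated 4 sections (1600 pixels each), 50 peaks
planted: 2 anchors, 8 region markers, 5 treatment markers (3 up / 2 down in MSC_TX)
aligned 50 m/z intervals over 6400 spectra
anchor image correlation: 0.677
regions: 972 tm, 2223 tam, 3205 off-tissue pixels
anchor m/z 976.44: AUC(tm/tam) = 0.000, p = 0 -> accepted
agreement with ground truth: 99.8%
level-2 ARI vs marker annotation (tm/tam): 0.981
PCA explained variance: 17.1%, 4.9%, 2.4%, 2.3%, 2.2%
passing markers: 5 in tam contrast, 0 in tm contrast (ratio Inf)
tam markers: 937.56, 1172.57, 1199.70, 1390.75, 1487.82
balanced-subsample check (tm, 400/side): max AUC shift 0.0216
match_report: assigned 5 out of 5 m/z values to 3 protein(s), 2 accepted (>= 2 peptides)
  ims_mz_observed ratio_tam     auc_tam      sequence gene_name
1         1172.57 0.5786665 0.104433310   GGPLSGPYRLR       Ca3
2         1390.75 0.3716520 0.009312622 SMLRGGPLSGPYR       Ca3
3         1199.70 3.9006458 0.999663272  DAGTIAGLNVLR     Hspa8
4         1487.82 2.3231860 0.976817600 TTPSYVAFTDTER     Hspa8
```

Reading this output: the two actin anchors annotate the regions almost
perfectly; all five planted treatment markers — and nothing else — pass the
gates in the **tam** contrast while the **tm** contrast stays empty (the
treatment effect lives next to the trauma, not inside it); subsampling
barely moves the AUCs; and identity transfer accepts Hspa8 (both peptides up
in treated tam, ratios 3.9 and 2.3) and Ca3 (both peptides up in control tam,
ratios 0.58 and 0.37) while the single-peptide Flnc match is correctly left
unaccepted. Mass arithmetic is exact: e.g. `monoisotopic_mass("LGSFGSITR")`
= 936.50, `mz_to_neutral(976.44)` = 975.43, `ppm_error(0.0037, 975.43)`
= 3.79.

## Documentation

The methods vignette (`vignettes/msimarkers-methods.Rmd`) documents the
models, every tunable parameter with its default and rationale, the
synthetic-data design (including what it does *not* emulate), numerical
choices, and known limitations.
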