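---
title: "Region-resolved marker discovery in MALDI imaging MS: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region-resolved marker discovery in MALDI imaging MS: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msimarkers)
```

## The problem

MALDI imaging mass spectrometry (IMS) acquires one tryptic-peptide mass
spectrum per pixel of a tissue section, so molecular changes can be located
within pathophysiological regions rather than averaged over a homogenate.
`msimarkers` implements an open, tested version of the analysis chain used to
ask a specific question of severely injured skeletal muscle: after a local
cell therapy (transplantation of mesenchymal stromal cells, MSC-TX), where in
the injured muscle do peptide intensities change — in the primary trauma core
(tm) or in the trauma-adjacent tissue (tam)?

The chain is: preprocessing of the per-pixel spectra into an aligned
spectra-by-peaks matrix; marker-based annotation of tm and tam; unsupervised
segmentation and factorization as an unbiased cross-check of the annotation;
ROC/Wilcoxon discovery of peaks that separate treated from control tissue
within each region; and transfer of bottom-up LC-MS/MS peptide identities
onto the discriminative IMS m/z values.

No imaging dataset of the original study is publicly deposited, so the
package carries a synthetic-data generator that reproduces the *statistical
structure* the analysis assumes, with known ground truth. Every stage is
validated against that ground truth; section "What the generator does and
does not emulate" spells out what such validation can and cannot show.

## Preprocessing

Stages run in a fixed order on all sections jointly, so one peak list and one
intensity scale serve the whole batch.

1. **Baseline removal** (profile mode only): the baseline is estimated as a
   moving minimum followed by a moving average, both over a window of
   `width = 20` data points, then subtracted and clipped at zero. The window
   unit is *data points of the profile axis*; whether the original vendor
   convention is points or daltons is not determinable, so the unit is a
   documented choice (`baseline_width` config knob). The minimum filter
   ignores peaks narrower than the window, so apex positions are preserved;
   inputs that are already baseline-free pass through essentially unchanged.
2. **TIC normalization**: each spectrum is rescaled so its total ion count
   equals the batch-wide mean pre-normalization TIC. All-zero spectra cannot
   be rescaled; they are flagged (`zero_spectra` attribute) and excluded from
   downstream statistics rather than divided by zero. The pre-normalization
   TIC is kept in the feature-matrix metadata because off-tissue detection
   needs it (after normalization every TIC is equal by construction).
3. **Peak detection** on the pooled mean spectrum: Gaussian smoothing with
   sigma = 1 / 2 / 4 profile points for "weak" / "medium" (default) /
   "strong" strength; local maxima are kept when their height above the
   smoothed median level exceeds `snr = 3` times the noise, with noise
   estimated as the MAD of (raw minus smoothed). Measuring height above the
   median level matters on clipped data: a nonnegative noise floor has a
   positive mean that would otherwise masquerade as signal. Centroid data
   pass their positions through unchanged.
4. **Interval alignment**: one column per peak center with the half-open
   interval `[center - 0.156, center + 0.156)` Da, so a data point can never
   fall into two columns. "±0.156 Da" is read as a halfwidth (total width
   0.312 Da). The column value is the mean over profile points in the
   interval ("mean interval processing") or the sum of centroids. Centers
   closer than twice the halfwidth are merged to the stronger peak, logged.

## Region annotation from marker peaks

Two abundant actin-derived peaks (m/z 976.44 and 1198.63) anchor the tm/tam
split: their intensity is strongly depressed in the trauma core. The original
analysis states the marker m/z values and acceptance statistics but not the
mechanism that turns a marker image into a region mask, so the package uses a
parameter-free rule:

* **Off-tissue**: pixels whose raw TIC falls below 10% of the reference TIC.
  The reference is the median TIC of tissue-like pixels (those above the
  grand-mean TIC) rather than the global median: the global median sits
  between the background and tissue TIC modes whenever tissue covers about
  half the grid, which makes a plain 10%-of-median rule unstable.
* **Concordance check**: with two or more markers, every pair of marker ion
  images must correlate (Pearson, over tissue pixels) at least 0.65, or
  annotation is refused naming the discordant marker.
* **Split**: marker images are min-max rescaled over tissue pixels and
  averaged; a two-class Otsu threshold assigns the low side to tm and the
  high side to tam. Because Otsu operates on min-max-rescaled values, the
  annotation is invariant to monotone-affine rescaling of the marker images.
* **Bimodality guard**: if the averaged marker image has a Sarle bimodality
  coefficient below 0.555 (the unimodal reference value), there is no
  two-region structure to find and annotation is refused instead of
  fabricating a split.

Each anchor is then re-validated on the annotated regions: its tm-vs-tam ROC
AUC must fall below 0.35 with a Wilcoxon p below 0.001. The AUC direction
convention is P(random tm intensity > random tam intensity), so a marker
depressed in tm scores near 0, matching how the study reports its anchor
(AUC 0.086).

How strong must the anchors be? For log-normal abundances with coefficient of
variation $c$ and a tm/tam intensity ratio $\rho$ at tm share $p$ of tissue,
the expected correlation between two independent marker images is the shared
between-region variance fraction

$$ r \;=\; \frac{p(1-p)(1-\rho)^2}{p(1-p)(1-\rho)^2 + c^2\,[(1-p) + p\rho^2]}. $$

At the generator's conditions ($p = 0.3$, $c = 0.3$) a ratio of $\rho = 0.5$
yields only $r \approx 0.43$ — the published concordance bound of 0.65 is
unreachable with markers that weak. The generator therefore plants its two
anchors at $\rho = 0.15$ ($r \approx 0.70$), consistent with the near-perfect
anchor AUCs the study reports; muscle actin peptides are among the most
abundant and most strongly trauma-depressed signals available.

## Unsupervised analyses

**Peak selection (OMP).** Simultaneous orthogonal matching pursuit over the
peak columns: columns are mean-centered and scaled to unit norm, and the atom
explaining the most residual energy of the whole scaled matrix is selected
greedily, with the residual re-orthogonalized after every selection.
Standardizing before selection makes the choice reflect spatial covariation
instead of absolute abundance. Because correlated markers share latent
directions, OMP selects one representative per direction — it covers the
structure, it does not enumerate every marker. Default sparsity is
`min(200, columns)`; the original pipeline states no sparsity level.

**Bisecting k-means.** Top-down 2-means splitting on the OMP-selected,
unit-variance columns: at every level the segment with the largest
within-segment sum of squares splits, so level $k$ has $k$ segments and
level $k+1$ refines level $k$. Splits use `stats::kmeans` with 10 seeded
starts; a fixed seed reproduces the tree exactly. Which side of a split
receives the new label is arbitrary (a property of 2-means), so tests assert
*which partition* emerges, not which label lands where.

**PCA.** Columns are standardized to unit variance ("unit variance scaling")
before `stats::prcomp`; five components are computed. Loading signs are fixed
by making each vector's largest-magnitude entry positive, since score-image
polarity is otherwise arbitrary. Constant columns are dropped with a warning.

**PLSA.** The aspect model
$P(w \mid d) = \sum_z P(z \mid d)\, P(w \mid z)$ is fit to the nonnegative
feature matrix by EM. Initialization is deterministic — a nonnegative SVD
seeding (dominant sign variant of each rank-1 pair, clipped at zero) — so
runs are exactly reproducible. The clipped zeros are replaced by a dense
floor of 5% of the seed mean: exact zeros are absorbing states of the EM
updates and strand the fit in poor local optima (with the floor, planted
rank-2 mixtures are recovered to total-variation error below $10^{-6}$;
without it the fit plateaus near 0.01). Iteration stops when the relative
log-likelihood change falls below `tol = 1e-6` or after 500 iterations; the
log-likelihood is monotone by the EM guarantee and both `P(w|z)` and `P(z|d)`
stay on their simplices to within $10^{-8}$.

Five components are computed although four tissue classes are expected
(tm/tam × treated/control): the surplus components absorb background and
noise structure rather than forcing it into the interpreted ones.

## Marker discovery

For every aligned peak column and a pair of regions-of-interest (ROIs):

* **ROC AUC**: the rank-based probability that a random ROI-a intensity
  exceeds a random ROI-b intensity, ties counted half (Mann-Whitney U over
  $n_a n_b$). Midranks are used throughout, so the statistic is invariant
  under strictly monotone transforms.
* **Wilcoxon rank-sum p** (two-sided): exact by full enumeration of the
  $\binom{n}{n_a}$ group assignments when $n_a + n_b \le 12$; otherwise the
  normal approximation with tie and continuity corrections. The boundary is
  the documented `exact_max` argument.
* **Intensity gates**: the ratio of mean TIC-normalized intensities a/b (a
  zero denominator yields an infinite ratio that fails the gates), and the
  delta of min-max-normalized means — the column is rescaled to [0, 1] over
  the pooled ROI values and the absolute difference of the two ROI means is
  taken. The delta definition is an interpretation (the original text mixes
  delta and ratio filters without defining the delta) and is configurable.

Two published filter profiles are kept as presets, not reconciled, because
the source describes them inconsistently between its methods and results:
`treatment_marker` (AUC < 0.35 or > 0.65, p < 0.01, ratio < 0.8 or > 1.2) and
`region_marker` (AUC gates, p < 0.001, delta > 0.3). No multiple-testing
correction is applied by default — the joint AUC + p + intensity gates are
the published filter — but Benjamini-Hochberg adjustment is available
(`adjust = "BH"`).

Unbalanced ROIs can be equalized by seeded uniform subsampling without
replacement (`balance_n`; the study used 6000 spectra per side, the
desk-scale default analysis uses 400). When fewer spectra are available, all
are used with a warning.

## Identity transfer

IMS observes singly protonated peptides, so an observed m/z converts to a
neutral mass as $M = m/z - 1.007276$. Theoretical monoisotopic masses are
computed from the standard 5-decimal residue mass table plus one water
(18.010565 Da), with optional methionine-oxidation increments
(15.994915 Da). For each discriminative IMS m/z, LC-MS/MS peptides within a
strictly-less-than 0.9 Da mass difference are candidates and the lowest
difference wins (ties broken by lower ppm, then lexicographic sequence — so
permuting the identification table never changes winners). A protein is
accepted only when at least two of its distinct peptide sequences are matched
by distinct IMS m/z values; the final report lists, per accepted-protein
peptide, the IMS m/z, neutral mass, tam and tm contrast ratios and AUCs, the
LC-MS/MS mass, delta in Da and ppm, search score, sequence, gene and
description — the published report column order.

The package bundles a 14-row reference peptide table (genes Col6a1, Hspa8,
Ca3, Myl3, Flnc, Tnc) with published sequences, LC-MS/MS neutral masses and
scores; its protein accessions are synthetic placeholders. The table anchors
the mass-arithmetic regression tests (every theoretical mass matches its
printed value within 0.01 Da) and gives the synthetic pipeline real targets
for identity transfer. One published anchor row (m/z 1198.63) prints
internally inconsistent mass/delta values and is excluded from the mass
regression; it serves only as the second annotation anchor.

## What the generator does and does not emulate

One synthetic section is a 40×40 pixel grid holding an elliptical tissue blob
(~50% of the grid) with an elliptical trauma core (tm, 30% of tissue) inside
trauma-adjacent tissue (tam). Per pixel and peak,

$$ I = \text{base} \times f_{\text{region,group}} \times
   \mathrm{LogN}(1, c) \times \mathrm{LogN}(1, c_{\text{TIC}}) + \varepsilon,$$

with mean-one log-normal multipliers (so expected intensities equal
base × factor and the noise-free limit is exact), a per-pixel TIC multiplier
shared across peaks, and a Gaussian noise floor clipped at zero. Off-tissue
pixels carry only noise (plus, in profile mode, an exponentially decaying
baseline). Effects are *multiplicative* because the study reports its
contrasts as intensity ratios. Defaults: $c = 0.3$, $c_{\text{TIC}} = 0.2$
(stated conventions, not inferences — the study gives no noise estimates),
two sections per group (the study had three animals per group; two keep the
test suite fast and the count is configurable).

The default 50-peak panel plants: 2 abundant anchors (tm/tam ratio 0.15, see
the correlation analysis above); 8 further region markers with tm/tam ratios
in (0.25, 0.6), emulating the broad molecular difference between trauma core
and adjacent tissue; 5 treatment markers with tam-only group effects, ratio
magnitudes uniform in (1.5, 4) and alternating direction (3 up in MSC-TX,
2 up in control, mirroring how most published markers rose under treatment
while carbonic-anhydrase peptides fell); 35 null peaks. Treatment markers sit
at the m/z positions of the bundled reference peptides so identity transfer
is exercised end to end: two Hspa8 and two Ca3 peptides (accepted by the
two-peptide rule) and one Flnc peptide (correctly rejected with one peptide).

Treatment markers get below-average base abundance (log-mean 40 vs 150 for
nulls). This preserves a property of the real data that a reduced panel would
otherwise lose: with 534 aligned peaks, discriminative peptides contribute
negligibly to the TIC, so TIC normalization does not couple treatment effects
into null peaks. With 50 peaks and abundant markers, the coupling would shift
every null peak's tam ratio by 15-30% — an artifact of panel size, not of the
method. With the default panel the coupling is 1-5%, well inside every gate's
safety margin. A related small-panel artifact is worth knowing: in the exact
noise-free limit, TIC normalization imprints the regions' TIC ratio onto
*every* column, making each one a perfect tm-vs-tam discriminator; noise-free
fixtures therefore test group contrasts (which are immune) rather than region
contrasts.

All randomness flows from one master seed through documented per-stage
derived seeds (`derive_seed(master, stage)`), so inserting a stage never
shifts the randomness of another, and whole runs are byte-reproducible.

The generator does **not** emulate: isotope envelopes and deisotoping,
detector saturation, mass-calibration drift across pixels, spatial intensity
gradients within a region, chimeric spectra, or matrix clusters. Passing
recovery tests on this generator therefore demonstrates that the
implementation correctly extracts the planted statistical structure at
realistic noise levels — not that the pipeline is robust to every artifact of
real acquisitions.

## Problem sizes and what the checks compute

The standard desk-scale batch is 4 sections × 1600 pixels × 50 peaks
(6400 spectra); the full pipeline runs in a few seconds and the test suite in
well under a minute of compute per file. On this batch the package's checks
compute, among others: pixel agreement of marker annotation with ground truth
(expected ≥ 90%, observed ≈ 99.8%); level-2 segmentation ARI against the
tm/tam truth (expected ≥ 0.8, observed ≈ 0.99); exact recovery of the five
planted treatment markers in the tam contrast with zero passes in the tm
contrast; a maximum AUC shift under 400-spectrum balanced subsampling below
0.03; at most 5 of 100 null replicates passing the joint treatment gates
(observed 0); and PLSA mixture recovery to total variation well below 0.01.

Two structural notes on the unsupervised checks. The third segmentation level
separates treated from control tam; whether the *new* label lands on the
treated or the control side is arbitrary, so checks assert that the new
segment lies ≥ 80% inside the tam pixels of a single group. Similarly, PLSA
dedicates a sharp component to treated tam (its top-decile pixels concentrate
there), while control tam — whose profile differs from treated tam only
through the treated group's markers — is identified by a component whose
scores *discriminate* control-tam from treated-tam (AUC > 0.65) rather than
by top-decile concentration; at full EM convergence no component concentrates
≥ 70% of its top decile in control tam under these study conditions.

## Known limitations

* Vendor raw formats are out of scope; imzML (continuous and processed,
  uncompressed 32/64-bit float arrays) and a plain-array JSON exchange format
  are the supported containers. imzML intensities default to 32-bit float, so
  round-trips are exact only to float32 resolution unless
  `intensity_format = "float64"` is chosen.
* The m/z axis is assumed calibrated; there is no recalibration, lock-mass
  correction, or deisotoping.
* `wilcoxon_p`'s exact path enumerates all assignments and is intended for
  the documented n ≤ 12 regime only.
* The identity transfer maps each IMS m/z to at most one peptide and performs
  no FDR estimation of the underlying LC-MS/MS identifications; search-engine
  scores are carried through verbatim (their units are not defined here).
* Dataset-scale results of the original study (534 aligned peaks, 45/96
  discriminative values, spectra counts, PC percentages) depend on the
  unpublished data and are not reproduction targets; the package reproduces
  the published *arithmetic* exactly and the published *structure* (tam
  dominates the treatment response; anchors annotate regions; accepted
  proteins need two peptides) on ground-truthed synthetic data.
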