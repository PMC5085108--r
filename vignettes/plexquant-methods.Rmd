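---
title: "Methods: 8-plex reporter quantification and PTM-level deregulation calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 8-plex reporter quantification and PTM-level deregulation calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plexquant)
library(dplyr)
```

## The experimental design the package models

One iTRAQ 8-plex labelling multiplexes eight samples: four brain regions,
each contributing a wild-type (WT) and a transgenic amyloidosis (AD)
sample. The default channel map is 113/114 = hippocampus WT/AD,
115/116 = neocortex, 117/118 = olfactory bulb, 119/121 = brainstem
(channel 120 does not exist in the 8-plex chemistry). Three biological
replicates mean three independent 8-plex mixes, each quantified as a
PSM table with eight reporter-intensity columns.

Because all eight samples are fragmented together, reporter intensities
within one spectrum share ionisation and sampling effects; the
informative quantity is the *within-spectrum channel contrast*, which is
why the pipeline works on log2 intensities and why every downstream
ratio is a within-row difference of two channels.

## Normalization model

Let $x_{f,c,r}$ be the log2 intensity of feature $f$ in channel $c$ of
replicate $r$ (PSMs of the same modified peptide are first merged per
channel by the median of their raw intensities — robust to a single
outlier spectrum).

1. **Median normalization (per channel, within replicate).** Unequal
   amounts of labelled material per channel shift a whole column; we
   subtract each channel's median so every channel median is 0. The
   choice of a *per-channel* (column) median is ours: channel loading is
   the artefact being corrected. A global median would leave loading
   differences in place.
2. **Mean-centering (per feature row, within replicate).** Subtracting
   each feature's mean over its non-missing channels removes the
   feature's replicate-specific absolute abundance so replicates can be
   merged. Centering leaves every within-row channel difference — and
   hence every AD/WT ratio — exactly unchanged; this invariance is
   tested. Rows with fewer than two observed channels carry no contrast
   and are dropped.

The intensity container records its `scale_state`
(`raw_log2 → median_normalized → mean_centered`) and each step checks
and advances it, so stages cannot be run out of order.

## Rollup

*Modified peptides* are merged by arithmetic mean of their member
peptides' centered values per channel, with single-member groups
("one-hit-wonders") retained: a PTM site is often covered by exactly one
peptide, and discarding it would discard the site. *Proteins* are rolled
up from unmodified, unique peptides only, require at least two of them,
and proteoform-ambiguous evidence (peptides mapping to several entries;
isoform accessions carried by an identical peptide set) is removed
first. Proteins with a single unique peptide are kept in a side table:
they are good enough to *normalize a PTM against*, but not to *report*
as a quantified protein — using them only for normalization maximises
the number of PTM features that can be protein-corrected without
weakening the protein results.

## Ratios, the deregulation rule, and its operating point

Per region and replicate, the linear ratio is $2^{x_{AD} - x_{WT}}$; a
replicate counts only if both channels are observed. We aggregate by the
arithmetic mean of the per-replicate linear ratios and quantify spread
as the relative SD (SD of the linear ratios divided by their mean).
Where the convention was genuinely open we chose: mean-of-ratios rather
than ratio-of-means (each replicate is an independent biological
contrast and should weigh equally), and relative SD on the linear rather
than log scale (a "SD ≤ 30 %" rule reads as a ratio-scale CV). A feature
is called deregulated when

* it is present in at least $n-1$ of $n$ replicates (with $n=3$: at
  least 2) — for proteins the two-unique-peptide identification must
  hold in the counted replicates, for PTM features one peptide suffices;
* the relative SD is ≤ 0.30; and
* the mean ratio is ≥ 1.30 (up) or ≤ 0.77 (down), boundaries inclusive.

No multiple-testing correction is applied: the rule is a fold-change /
reproducibility filter, not a p-value procedure; this is a faithfulness
choice and is stated here rather than hidden.

The thresholds' operating point at the design conditions was quantified
by a Monte-Carlo simulation of the decision rule itself (independent of
the pipeline code): with $|log_2|$ effect 1 and null-ratio CV 8.4 % at
$n=3$, sensitivity and specificity are both effectively 1 (false-positive
rate below $10^{-4}$). The acceptance suite therefore requires
sensitivity and specificity ≥ 0.9 on the full synthetic pipeline — a
bound the decision rule meets with a wide margin, leaving room for the
pipeline's additional loss channels (missingness, filtered PSMs).

## PTM normalization and the absorption property

A PTM peptide's ratio confounds change of the modification with change
of the protein. Dividing the PTM ratio by the protein ratio *in the same
replicate* (using main and single-peptide protein tables) removes the
protein component: if a protein changes by the same factor in every
replicate and the modification itself is untouched, the normalized PTM
ratio is exactly 1 and the feature is never called. This absorption
property is exact in the noise-free limit and is tested there (0
violations over > 1000 feature-region pairs); with technical noise it
holds in distribution and is covered by the null false-positive bound.
Replicates in which the protein was not quantified keep the
un-normalized PTM ratio and are counted in `n_normalized`.

Deglyco features (deamidated Asn left by PNGase F) must additionally lie
in an N-glycosylation sequon N-X-(S/T/C), X ≠ P, at the site mapped onto
the protein by exact substring search (ties resolved to the lowest
coordinate and logged); the site residue may read N or D since the
database may or may not reflect the deamidation.

## PCA quality control

Channel-samples (8 channels × $n$ replicates = 24 observations) are
decomposed over the features complete in all samples, unscaled
(the data are already normalized log2 values; unit-variance scaling
would up-weight noise-dominated features). Component signs are
canonicalized (largest-magnitude loading positive) so results are
reproducible across platforms. Genotype separation is summarised as the
mean silhouette width of WT vs AD samples within each region in PC
space; positive silhouettes in all regions indicate the genotype effect
dominates technical scatter.

## The qPCR module

$\Delta Ct$ subtracts each sample's median over all targets (plate-offset
invariant; per-sample rather than per-plate-pooled, our choice where the
convention was unstated); $\Delta\Delta Ct$ is the AD−WT difference of
group means; the linear fold change is $2^{-\Delta\Delta Ct}$, reported
with the signed convention (values < 1 become negative reciprocals, so
the down threshold reads ≤ −1.2). The test is the classic pooled-variance
unpaired t-test, two-sided; numerically constant groups fall back to
p = 1 (equal means) or 0 (separated means) where the statistic is
undefined. Benjamini–Hochberg adjustment is available behind
`fdr = TRUE`, off by default to match the stated criteria.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes —
it is the package's test bed, not a spectrum simulator:

* a proteome of random tryptic peptides (ending K/R, interior free of
  K/R, unique across the proteome) concatenated into proteins, with
  planted phospho sites (S/T/Y) and valid sequons for deglyco sites;
* per replicate, log2 reporter intensities = peptide abundance
  (N(20, 1.5²)) + per-(protein, region) biological offset (sd 0.5,
  shared by both genotypes, so it shapes PCA but cancels in ratios) +
  per-(channel, replicate) loading bias (U(−0.3, 0.3), removed by median
  normalization) + genotype effect + noise;
* spiked effects of $|log_2| = 1$ at protein level (applied to all of a
  protein's peptides) and at PTM level (applied to the modified peptide
  on top of any protein effect), per (feature, region) at rate 0.05,
  plus a configurable set of PTM features deregulated in all four
  regions to exercise the overlap logic;
* noise calibration: the quantity the ±1.30/0.77 and ±1.2 thresholds
  were derived from is the replicate-to-replicate variability of *null
  AD/WT ratios* (8.4 %). A ratio of two independently noised channels
  has CV ≈ √2 times the channel CV, so we set the per-channel log2 sd to
  $\sqrt{\ln(1+cv^2)}/\ln 2/\sqrt 2$, making the realised null-ratio CV
  equal `technical_cv`. The realised pooled CV is checked by a sampling
  test (within 20 % at > 500 features);
* channel-block missingness (a feature drops both channels of a region
  in a replicate, rate 0.05) exercising the $n-1$ presence rule, and a
  10 % admixture of PSMs violating exactly one confidence criterion
  exercising the filter;
* Ct tables: per-target baseline U(22, 30), per-sample plate offset
  U(−1, 1), group-mean shifts of $\mp log_2 FC$ for spiked targets,
  noise in Ct units equal to the log2-scale sd implied by
  `technical_cv`.

Everything is deterministic under `seed` (sub-generators use fixed small
offsets of it).

**What passing tests do and do not show.** The generator reproduces the
design's hierarchy, noise scale, missingness and filter structure, but
real data differ in ways it does not model: correlated co-isolation
interference between channels, intensity-dependent variance, shared
peptides between homologous proteins beyond a uniqueness flag,
phospho-site localisation uncertainty, and biological replicate variance
beyond the technical calibration. Recovery results on synthetic data
therefore validate the *implementation and the decision rule at its
documented operating point*, not the biology of any particular dataset.

## Numerical and degenerate-input choices

* Missing intensities are represented as `NA`, never imputed to zero;
  presence rules operate on missingness.
* Zero/negative raw intensities become missing with a warning (log2
  undefined).
* Xcorr bounds are strict inequalities; all other bounds are inclusive.
  Charges above +4 use the +4 bound.
* `rel_sd` is `NA` with fewer than two observed replicates, which fails
  the SD criterion (a single observation carries no reproducibility
  evidence).
* A channel that is entirely missing within a replicate is an error at
  median normalization (the design requires all eight channels).
* Venn cells are computed exactly over all $2^k - 1$ region
  combinations; duplicate members are deduplicated with a warning.

## Known limitations

* The median-of-targets qPCR reference assumes deregulation is sparse or
  balanced. When the spiked directions are unbalanced, the reference
  itself shifts and null targets acquire a correlated ΔΔCt bias; under
  the default simulation (10 % deregulated, random directions) this
  costs qPCR specificity even though the type-I error under a true null
  stays below the p threshold (both behaviours are tested). This is a
  property of the normalization scheme, shared with any analysis that
  uses it.
* Protein inference is accession-based; the proteoform filter removes
  straightforward isoform redundancy but does not perform parsimony
  inference.
* Site mapping uses exact substring search; a peptide absent from the
  supplied database yields an unmapped (and for deglyco, uncallable)
  feature rather than an error.

## Problem sizes used by the test-suite and acceptance script

Boundary scans use grids of 151–402 points; oracle-equivalence checks
run 100 random small instances per operation; parameter recovery uses
150 proteins (≈ 900 peptides, > 1300 truth-labelled feature-region
pairs) with 3 replicates; the absorption check uses ≈ 1400 PTM
feature-region pairs; the null-CV check pools ≈ 8000 replicate ratios.
These sizes give stable estimates for every reported quantity while the
whole suite stays quick to run.
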