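# plexquant

Quantitative analysis of isobaric-tag (iTRAQ 8-plex) brain proteomics
experiments with PTM-level deregulation calling, plus a 2^−ΔΔCt qPCR-array
module and a ground-truth-labelled synthetic data generator.

## The problem

In an 8-plex reporter-ion experiment, eight samples — here four brain
regions (hippocampus, neocortex, olfactory bulb, brainstem), each as a
wild-type (WT) and a transgenic amyloidosis (AD) sample — are labelled,
mixed, and quantified together; every identified peptide-spectrum match
(PSM) carries eight reporter intensities. Three biological replicates give
three such tables. The analytical questions are: which proteins, which
phosphopeptides, and which formerly sialylated N-glycopeptides (recognised
by the deamidation scar left at the Asn after enzymatic deglycosylation)
change between AD and WT within each region — and does a PTM-level change
survive normalization against its protein's own expression change?

## The method

For each replicate, PSMs are filtered on search-engine confidence
(rank 1; percolator *q* ≤ 0.01; Mascot ≥ 22; ΔCn ≥ 0.1; Xcorr strictly
above 1.5 / 2 / 2.25 / 2.5 for charges +1..+4; ≤ 1 missed cleavage), then:

1. log2-transform reporter intensities (PSMs of one modified peptide are
   merged by the median);
2. median-normalize each channel (column median → 0);
3. mean-center each peptide across the eight channels so replicates merge;
4. roll up: modified peptides by group mean (one-hit-wonders allowed),
   proteins from ≥ 2 unique unmodified peptides (single-peptide proteins
   kept in a side table used only for PTM normalization; proteoform-
   ambiguous evidence removed);
5. per region and replicate, the linear ratio is `2^(x_AD − x_WT)`; a
   feature is deregulated when it is observed in ≥ *n*−1 replicates, the
   relative SD of its replicate ratios is ≤ 30 %, and the mean ratio is
   ≥ 1.30 (up) or ≤ 0.77 (down);
6. PTM ratios are divided replicate-wise by the protein ratio, so protein-
   level change is absorbed and only PTM-level change is called; deglyco
   calls additionally require the N-glycosylation sequon N-X-(S/T/C),
   X ≠ P, at the mapped protein site;
7. PCA over the 8 × *n* channel-samples serves as a quality check.

The qPCR module implements 2^−ΔΔCt with median-of-all-targets
normalization, two-sided pooled-variance t-tests, and a signed
fold-change call (|FC| ≥ 1.2, *p* ≤ 0.05). Cross-region integration
provides exact Venn cell counts and protein-class fraction summaries.

## Worked example

```r
library(plexquant)
library(dplyr)

sim <- simulate_study(simulation_params(n_proteins = 60, seed = 7))
res <- run_quant_pipeline(sim$psms, sim$proteome$db)

res$ptm_calls |> filter(direction != "none") |> count(region, direction)
#> # A tibble: 8 × 3
#>   region         direction     n
#>   <chr>          <fct>     <int>
#> 1 brainstem      up            1
#> 2 brainstem      down          5
#> 3 hippocampus    up            4
#> 4 hippocampus    down          4
#> 5 neocortex      up            3
#> 6 neocortex      down          4
#> 7 olfactory_bulb up            2
#> 8 olfactory_bulb down          6

res$ptm_calls |> filter(direction == "up") |>
  select(feature_id, region, mean_ratio, rel_sd, n_observed) |> head(3)
#> # A tibble: 3 × 5
#>   feature_id                    region      mean_ratio rel_sd n_observed
#>   <chr>                         <chr>            <dbl>  <dbl>      <dbl>
#> 1 GQNLCHVNIEGAGDR/3:deamidation brainstem         2.01 0.0241          3
#> 2 GQNLCHVNIEGAGDR/3:deamidation hippocampus       1.93 0.0393          3
#> 3 QIDNYNHSFNQK/6:deamidation    hippocampus       2.10 0.0808          3
```

Each row is one modified-peptide feature in one region: the mean of the
three replicate AD/WT ratios (after division by the protein ratio), its
relative SD, and the number of replicates in which both of the region's
channels were observed. A `mean_ratio` of 2.01 with `rel_sd` 0.024 is a
two-fold PTM-level increase, reproducible across replicates, so the
feature is called `up`.

```r
glance(res$pca)
#> # A tibble: 1 × 4
#>   n_samples n_features var_pc1 var_pc2
#>       <int>      <int>   <dbl>   <dbl>
#> 1        24        175   0.387   0.307

pca_genotype_silhouette(res$pca)
#> # A tibble: 4 × 2
#>   region         silhouette
#>   <chr>               <dbl>
#> 1 brainstem           0.822
#> 2 hippocampus         0.800
#> 3 neocortex           0.885
#> 4 olfactory_bulb      0.575
```

All four silhouettes are positive: within every region the WT and AD
channel-samples form separated groups in PC space. `autoplot(res$pca)`
draws the score plot.

```r
analyze_pcr_array(sim$ct) |> filter(direction != "none") |>
  select(target, fold_change_signed, p_value, direction) |> head(4)
#> # A tibble: 4 × 4
#>   target     fold_change_signed  p_value direction
#>   <chr>                   <dbl>    <dbl> <fct>
#> 1 target_010               1.78 0.00694  up
#> 2 target_018               1.96 0.00307  up
#> 3 target_026              -2.27 0.000797 down
#> 4 target_029               1.95 0.00295  up
```

## Scope

The package starts from exported PSM tables; spectral searching, FDR
estimation, raw-spectrum processing, enrichment chemistry, and
pathway/classification analyses (which it consumes only as external
annotation files) are out of scope.
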