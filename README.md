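# nrscreen

Analysis toolkit for massively parallel reporter screens of RNA
subcellular-localization elements, for computational biologists analysing
nuclear/cytoplasmic fractionation screens (saturating k-mer insert
libraries or random-fragment libraries) and the transcript-level analyses
built on top of them.

## The measurement and the score

A library of short elements is cloned into a reporter's 3' UTR; transfected
cells are fractionated and the insert region is amplicon-sequenced from the
nuclear and cytoplasmic compartments. A read is valid when it contains the
construct's constant 10-bp flanks; the insert between the anchors is counted
per sample. Each element's **nuclear retention score** is

```
NRS = log2( (CPM_nuclear + c) / (CPM_cytoplasmic + c) ),   c = 0.5 CPM
```

with replicate CPMs averaged per fraction. Differential abundance across
replicates is tested with a negative-binomial Wald test (median-of-ratios
size factors, per-element method-of-moments dispersion, t-referenced
statistic), and elements are called **nuclear-enriched** when
`NRS >= 0.58` with `p < 0.05`, or **cytoplasm-enriched** when
`NRS <= -0.58` with `p < 0.05` (0.58 = log2 1.5, truncated).

On top of per-element scores the package provides: exact mapping of
fragment elements back to a reference with coverage and per-base NRS
tracks (bedGraph/BED6 output); sliding-window NRS assignment along
transcripts with peak calling (cutoff ±0.5) and metagene profiles; a
compact attention-based classifier of transcript localization trained on
NRS profiles against randomized-NRS and k-mer-only baselines; a knockdown
shift test (`Δlog2FC` with a Student t-test, strict ±0.58 / p < 0.05
classes); and a synthetic-data generator with known ground truth for every
stage.

## Worked example

```r
library(nrscreen)
library(dplyr)

# a screen with known truth: 110 nuclear / 49 cytoplasmic 6-mers, effect 1
truth   <- sim_kmer_truth(110, 49, effect_log2 = 1, seed = 7)
samples <- fraction_samples(replicates = 3, depth = 5e6)
counts  <- sim_and_count(truth, kmer_library_spec(), samples,
                         seed = 2, whitelist = all_kmers(6))

coverage_summary(counts, threshold = 10)
#> # A tibble: 1 × 4
#>   n_elements median_coverage frac_above_threshold threshold
#>        <int>           <dbl>                <dbl>     <dbl>
#> 1       4096            4438                    1        10

records <- score_elements(counts)
count(records, class)
#> # A tibble: 3 × 2
#>   class           n
#>   <chr>       <int>
#> 1 cytoplasmic    49
#> 2 neutral      3942
#> 3 nuclear       105
```

All 4,096 6-mers are detected with a median fold-coverage of 4,438, and
154 elements pass the enrichment thresholds — 152 of them planted ones
(sensitivity 0.956, false-discovery proportion 0.013 against the known
truth). `plot_nrs_scatter(records)` draws the NRS/significance volcano,
and the same `records` table feeds the fragment-track, transcript-profile
and classifier stages (see the methods vignette in `vignettes/`).

The command-line entry point mirrors the R API:

```sh
Rscript inst/cli/nrscreen.R simulate --preset 6mer --seed 1 --out sim/
Rscript inst/cli/nrscreen.R extract  --dir sim/ --whitelist-6mers --out ext/
Rscript inst/cli/nrscreen.R score    --counts ext/counts.tsv --out scored/
```

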