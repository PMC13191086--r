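---
title: "Methods: nuclear retention scoring for localization reporter screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nuclear retention scoring for localization reporter screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measurement model

A massively parallel localization reporter screen clones a library of short
sequence elements into the 3' UTR of a carrier reporter transcript, transfects
the library, fractionates cells into nuclear and cytoplasmic compartments, and
sequences amplicons of the insert region from each fraction. If an element
promotes nuclear retention, reporter molecules carrying it are relatively
over-represented in the nuclear fraction.

`nrscreen` analyses such screens end to end:

1. **Insert extraction.** A read is *valid* when it contains the constant
   10-bp flanks of the cloning site. The insert is the substring strictly
   between the first exact occurrence of the 5' anchor and the first
   subsequent exact occurrence of the 3' anchor, provided its length lies in
   the library's declared range and it contains no `N`. If the forward search
   fails, the reverse complement of the read is searched once. Matching is
   exact by default; "contains the flanking region" admits several readings,
   and exactness is the most defensible one because it keeps extraction a
   pure, deterministic function of the read. A mismatch-tolerance option
   exists for degraded data but defaults to 0.
2. **Nuclear retention score (NRS).** With counts-per-million (CPM)
   normalisation per sample and replicate CPMs averaged per fraction,

   $$\mathrm{NRS} = \log_2 \frac{\mathrm{CPM}_{nuc} + c}{\mathrm{CPM}_{cyt} + c},$$

   with pseudocount $c = 0.5$ CPM. The pseudocount guards elements absent
   from one fraction and affects only the score, never the test. Averaging
   CPMs before the ratio (rather than averaging per-replicate ratios) is the
   default because it is the more stable estimator at low counts; the
   per-replicate variant is available via `test_config(nrs_aggregate =
   "per_replicate")` and agrees closely at screen-scale depth.
3. **Differential testing.** Counts are modelled negative-binomially with
   variance $\mu + \alpha\mu^2$. Sample size factors come from the
   median-of-ratios against a geometric-mean pseudo-reference (elements with
   any zero count are excluded from the reference); per-element dispersion is
   estimated by method of moments on normalised counts and floored at
   $10^{-8}$; the log2 fold change uses normalised group means with a
   pseudocount; and the Wald statistic is the fold change over its
   delta-method standard error. No empirical-Bayes shrinkage of dispersions
   is applied — the estimator is deliberately per-element and simple, and is
   validated by its type-I error rather than by numerical identity with any
   particular reference implementation.
4. **Enrichment calls.** Nuclear-enriched: $\mathrm{NRS} \ge 0.58$ and
   $p < 0.05$; cytoplasm-enriched: $\mathrm{NRS} \le -0.58$ and $p < 0.05$.
   The NRS boundary is inclusive and the p boundary strict, exactly as the
   screen's rule is stated; 0.58 is $\log_2 1.5$ truncated to two decimals,
   i.e. a 1.5-fold shift between compartments. The rule as published refers
   to the *P* value even though a multiple-testing correction is also
   computed; classification therefore uses the raw p by default, with
   `use_adjusted_p = TRUE` switching to the Benjamini–Hochberg value. Both
   are always reported.

## Why the Wald statistic uses a t reference

With three replicates per fraction and per-element method-of-moments
dispersion, the standard error in the Wald statistic is itself estimated from
roughly four degrees of freedom. Referring the statistic to a normal
distribution ignores that estimation noise and is strongly anticonservative:
in a null simulation at $\alpha = 0.1$ the normal reference rejects about
12–13% of elements at the nominal 5% level. Referring it to a
$t_{n_1+n_2-2}$ distribution restores calibration (≈5.2% in the same
simulation), which the test suite verifies on 200 pooled null libraries.
This is the package's own calibration choice for small replicate numbers;
large designs make the two references indistinguishable.

# The synthetic-data generator

The generator is first-class, tested code; it defines the study conditions
under which every recovery property is evaluated.

* **6-mer library.** All $4^6 = 4096$ elements, log-normal base abundances
  (sdlog 1), 110 planted nuclear and 49 planted cytoplasmic elements at
  effect $\pm 1$ log2 unit by default — the scale of elements a saturating
  screen recovers. The fraction effect is split symmetrically
  ($\pm$effect/2 on each fraction's expected abundance) so the marginal
  library composition is class-independent and the expected
  nuclear:cytoplasmic CPM log-ratio equals the planted effect.
* **Counts.** Negative-binomial with a single dispersion $\alpha$
  (variance $\mu + \alpha\mu^2$; $\alpha = 0$ degenerates to Poisson). The
  default $\alpha = 0.02$ for the amplicon arm reflects the tight biological
  replication of deep amplicon sequencing of a transfected plasmid library;
  reporter-library count data typically show replicate dispersions in the
  0.01–0.05 range. The null-calibration simulations use a deliberately
  harsher $\alpha = 0.1$.
* **Reads.** Each read is `flank5 + insert + flank3`, optionally padded to a
  fixed read length with random bases; by default full amplicons are emitted
  unpadded. Configurable fractions of reads are reverse-complemented
  (default 0, single-orientation amplicons) or replaced by anchorless junk.
  Reads are emitted already trimmed with uniform Phred qualities; quality
  trimming is a pass-through hook since the simulator produces clean reads.
* **Fragment arm.** Fragments sample a reference uniformly with lengths
  uniform in 30–100 nt by default — the range *detected* in fragment
  screens — while the wider 75–150 nt *amplified* range is available by
  argument; the discrepancy between the two published ranges is left as a
  configuration, not resolved. A fragment overlapping a planted nuclear
  region by at least half its length inherits the region's effect.
* **Transcripts.** Random-background transcripts carrying
  `copies_per_transcript` planted 6-mers at non-overlapping positions.
  `placement = "clustered"` lays the copies back-to-back as one contiguous
  block: isolated single 6-mers produce averaged-NRS spikes of at most
  effect/6 (a nucleotide is covered by six windows, of which only one is
  planted), whereas real localization elements cluster within discrete
  regions; the clustered mode is what the peak-calling and metagene
  recovery simulations use, with shift-closed 6-mer families (e.g. CG
  repeats) so that consecutive windows inside a block all score high.
* **Knockdown matrices.** Per-gene control log-ratios drawn from a centred
  normal (sd 0.5); planted genes have the knockdown ratio shifted by
  $\pm\delta$; counts NB at the stated dispersion.

What the generator does **not** emulate: PCR amplification bias, sequencing
errors, splicing, paired-end reads, positional coverage bias, or the
correlated dispersion structure of real libraries. Passing recovery tests
therefore demonstrates the pipeline's correctness under its stated noise
model, not performance on real sequencing data.

# Fragment screen and transcript profiles

Mapping uses exact forward/reverse-complement substring search: synthetic
references are error-free and fragments derive from the reference by
construction, so seeded alignment would add tolerance the data cannot
exercise. Multimapped fragments are flagged and kept at their first
occurrence rather than dropped (transcript-scale references have few
repeats; the flag allows filtering). Coverage and mean-NRS tracks are dense
per-base vectors; all intervals are 0-based half-open end to end, and
bedGraph/BED6 output round-trips through `rtracklayer`.

Enriched-region retrieval automates what region screens do by eye on a
browser track: maximal runs with $|\mathrm{NRS}| \ge$ cut and coverage
$\ge$ `min_cov` (default 10), merging same-sign runs across gaps of at most
`max_gap` = 10 nt, dropping runs shorter than `min_len` = 20 nt. The
defaults are permissive and exposed; they are this package's choice, since
manual retrieval has no published parameters. A merge never bridges a
position qualifying for the opposite sign, so nuclear and cytoplasmic
regions cannot overlap.

Transcript profiles assign each 6-nt window (1-nt step) the NRS of its
6-mer (`raw`, length $L-5$); the `averaged` vector gives each nucleotide
the mean over its covering windows — positions within 5 nt of an end
average only the existing windows, with no padding, so no scores are
invented. Windows containing non-ACGT characters score 0 and are masked.
Peaks (cutoff $\pm 0.5$, inclusive) are called on the averaged vector by
default because peaks are genomic intervals and the per-nucleotide average
is the screen's own smoothing; `on = "raw"` calls on window scores
instead. Peak morphology defaults (`min_len` = 6 nt, `max_gap` = 3 nt) are
configuration, not published values. The randomized-NRS control permutes
the 4,096 table values, preserving the score distribution exactly while
destroying the sequence-to-score map.

# The localization classifier

Transcripts labelled nuclear- or cytoplasmic-enriched (log2 fold change
$\ge 1$ in *every* one of the 12 cell contexts, or $\le -1$; FPKM
pseudocount 0.1) train a compact attention classifier:

* **Encoding.** The per-position scalar (raw or averaged NRS) is lifted to
  an $m$-dimensional embedding by a learned linear map plus sinusoidal
  positional encoding; a learned CLS row is prepended and its final
  representation feeds a linear classification head. The
  `baseline_kmer` mode replaces the NRS lift with a learned 4,096-way
  6-mer embedding, i.e. sequence identity with no screen information. How
  scalar scores become $m$-wide features is not prescribed by the screen's
  description; this linear-lift scheme is the package's declared choice and
  is swappable behind `encoder_config()`.
* **Architecture.** Two residual blocks of 4-head self-attention plus a
  ReLU feed-forward layer, no layer normalisation (unnecessary at this
  depth), width $m = 256$ by default. Forward, backward and the Adam update
  are written out explicitly in base matrix algebra, and the backward pass
  is verified against central finite differences in the test suite.
* **Training.** Stratified 80/20 split under the seed; binary cross-entropy;
  Adam (lr $2\times10^{-3}$, batch 16); training stops at 6 epochs, the
  point at which test loss begins to rise at this scale. Per-epoch
  train/test accuracy and loss are recorded; ROC and PR curves come from a
  threshold sweep with trapezoidal areas, so the AUROC equals the
  pairwise-concordance probability (verified against that oracle).

The acceptance property is *ordering*, not an absolute number: on planted
transcripts, both NRS-guided modes must beat the randomized-NRS controls
and the 6-mer-only baseline by at least 0.1 accuracy, seed-averaged.
Reproducing any particular published accuracy on real fractionation
RNA-seq is out of scope — that depends on external data and an unspecified
architecture.

# Knockdown shift analysis

Within each condition, nuclear and cytoplasmic samples are paired by
replicate index and each replicate contributes one
$\log_2((\mathrm{CPM}_{nuc}+c)/(\mathrm{CPM}_{cyt}+c))$ ratio (the
published analysis does not state the unit of its t-test; replicate
ratios are the natural choice and an all-pairs variant is available).
$\Delta\log_2\mathrm{FC}$ is the difference of condition means and the
test is a two-sided equal-variance Student t-test on the replicate ratios
(Welch by flag). Shift classes use strict inequalities:
$\Delta > 0.58$ with $p < 0.05$ is a shift to nuclear,
$\Delta < -0.58$ a shift to cytoplasm.

# Numerical choices and degenerate inputs

* Zero-count columns abort CPM normalisation with the sample named.
* If no element has all-positive counts, size factors are undefined and the
  test aborts rather than guessing.
* Dispersion estimates are floored at $10^{-8}$; zero standard errors give
  statistic 0 and $p = 1$ rather than NaN.
* Peak and region callers return typed empty tables on empty input;
  opposite-class intervals can never overlap by construction.
* All generators are bit-reproducible under a fixed seed, and every
  stochastic function takes its seed explicitly.

# Problem sizes used by the test and acceptance runs

The 6-mer arm is exercised read-level at the study scale: 5×10⁶ reads per
sample, 3+3 replicates (≈3×10⁷ reads end to end). Null calibration pools
200 simulated libraries of 4,096 elements. The fragment arm uses an
8,000-nt reference with 20,000 fragments at 2×10⁶ reads per sample. The
classifier comparisons run at desk scale — embedding width 16, 100
transcripts per class of 100–180 nt, three seeds per mode — chosen so the
full five-mode comparison completes in minutes on one core while leaving
the ordering margins far above their thresholds; the package defaults
($m = 256$) remain the documented configuration for real use.

# Known limitations

* Exact anchor matching discards reads with sequencing errors inside the
  20 anchor bases; on real data the mismatch tolerance should be opened up
  or reads quality-trimmed first.
* The per-element method-of-moments dispersion is noisy at three
  replicates; the t reference restores calibration but costs some power
  relative to shrinkage-based estimators.
* The exact substring mapper is not a read aligner: it is only appropriate
  for elements that derive verbatim from the reference.
* The classifier is a compact model intended for controlled comparisons of
  encodings, not a production localization predictor.
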