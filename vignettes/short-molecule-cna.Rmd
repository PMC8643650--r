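---
title: "Copy-number inference from short-molecule nanopore runs: models and methods"
author: "poreCNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy-number inference from short-molecule nanopore runs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poreCNA)
```

## The problem

A nanopore flow cell returns far fewer molecules per run than a short-read
instrument, which limits "counting" applications such as genome-wide copy
number alteration (CNA) inference: read-depth CNA calling needs on the order
of 30–50 reads per genomic bin.  Loading *short* DNA fragments (median
~500 bp instead of ~10 kb) raises the molecule count dramatically, because a
pore's throughput is governed by a renewal cycle of

* **residence time** — the time a molecule spends translocating,
  `length / speed` (about 1 s for 400 bp at 450 b/s versus about 22 s for
  10 kb), and
* **vacancy time** — the idle gap before the next molecule docks.

poreCNA implements both halves of this story: the run-kinetics QC that
quantifies the cycle from sequencing-summary tables, and the sparse
read-depth CNA pipeline (variable bins → normalization → circular binary
segmentation → integer copy number) that the extra molecules make possible,
including multiplexed runs demultiplexed by barcode.  A synthetic-data
generator supplies every input with known truth, so each stage is testable
without any sequencing data.

## The kinetics simulator

`simulate_run()` treats each pore as an alternating-renewal process: an
exponential (or fixed) vacancy gap, then a read whose residence is
`length / speed`, repeated until the run ends or the channel dies.

Parameters, units and defaults (`run_sim_params()`):

| parameter | default | meaning |
|---|---|---|
| `n_channels` | 512 | MinION-like device; 126 emulates a Flongle |
| `run_duration` | 48 h | standard run length |
| `speed` | 450 b/s | translocation speed |
| `median_bp`, `sdlog` | 500, 0.55 | log-normal read length, floored at 50 bp |
| `mean_vacancy` | 10 s | mean pore idle gap at 1 molar equivalent (ME) |
| `channel_death_hazard` | 0.02 / h | exponential channel lifetime |
| `loading_factor` | 1 | loading concentration in ME |

Three modelling choices deserve comment, because the underlying physics is
not settled:

* **Read lengths** are log-normal truncated at 50 bp, parameterised by
  median and log-sd.  This reproduces the right-skewed length histograms of
  sonicated libraries qualitatively without claiming their exact shape.
* **Loading concentration** enters twice: vacancy gaps scale as
  `mean_vacancy / loading_factor` (more molecules dock faster) and the
  channel-death hazard scales as `hazard * loading_factor`.  Over-loaded
  flow cells are observed to decay faster; whether the mechanism is pore
  mechanics or reagent exhaustion is unknown, so the linear hazard coupling
  is a modelling choice, not a claim.
* **Q-scores** are normal around mean 10 (sd 1.5) with a pass threshold of
  7, the usual basecaller convention; only per-read means are modelled.

With deterministic vacancy and immortal channels the model collapses to a
closed form — `floor(run_duration / (length/speed + vacancy))` reads per
pore — which the test suite checks exactly, and which makes the computed
kinetics statistics (`vacancy_times()`, `channel_lifetimes()`,
`cumulative_reads()`, `channel_activity()`) verifiable to machine precision.
Reads are attributed to the timeline by their completion time, and a
truncated final read is not emitted.

What the simulator does **not** model: squiggle-level signal, basecalling
errors (beyond barcode substitutions), pore blocking/unblocking dynamics,
mux scans, or the absolute yields of any particular flow cell — so passing
tests say the statistics are computed correctly, not that the simulator
predicts real yields.

## The read-depth model

`simulate_bin_counts()` draws bin counts from a multinomial with
probabilities proportional to

```
effective_cn = purity * cn + (1 - purity) * baseline_cn
```

optionally distorted by a multiplicative GC bias
`exp(-strength * (gc - 0.45)^2)`.  This is exactly the structure read-depth
CNA inference assumes (expected depth proportional to copy number), which is
the point: it lets parameter-recovery tests separate algorithmic error from
model misspecification.  Real data add overdispersion, mappability
artifacts, and wave-like GC residuals that this generator deliberately
omits; accuracy on the simulator is therefore an upper bound, and the
spurious-segment behaviour at very low depth (below) will set in at
somewhat higher depths on real libraries.

The benchmark truth used across the test suite,
`standard_complex_truth()`, is a deterministic complex karyotype: 5,000
variable bins over a human-like 23-chromosome synthetic genome, 30% of bins
in single-copy loss (large interstitial deletions), 10% in focal CN-4 gains
(~40-bin amplicons), the rest diploid, purity 1.  Every event boundary is at
least 5 bins from a chromosome edge so that recovery metrics never conflate
data-driven transitions with forced chromosome breaks.

## Binning and normalization

`build_bins()` divides the genome into bins of equal expected unique-read
mass from a windowed mappability track: bins are allocated to chromosomes by
largest-remainder rounding of their mass share, then placed by greedy
cumulative-mass cuts at window boundaries.  Bins never cross chromosomes and
never split a track window.  On a uniform track this reduces to equal-width
bins — 5,000 bins over ~3 Gbp gives ~600 kb bins, 20,000 gives ~150 kb — and
the package's synthetic pipeline uses exactly that uniform fallback so no
reference genome is needed.  Coordinates are 0-based half-open throughout,
and a read is assigned to the bin containing its leftmost mapped base.
Alignments are first filtered with `mapq >= 20` and the unmapped /
secondary / supplementary flag mask, the standard unique-read filter.

`normalize_bins()` divides counts by their mean and optionally by a lowess
fit of ratio against GC (span 0.3, applied multiplicatively, then rescaled
so the mean ratio is exactly 1).  The GC fit requires at least 100 nonzero
bins; an all-zero profile is an error, and plain mean normalization is
available by disabling the correction.

## Segmentation

`segment_ratios()` is a circular binary segmentation: within each segment it
finds the arc `(i, j]` maximising the pooled-variance two-sample *t*
statistic between arc and complement, accepts the split when a within-
segment permutation test gives `p < alpha`, and recurses.  Defaults are
`alpha = 0.01` with 1,000 permutations, both exposed in `cbs_params()`.

Numerical and design choices:

* **The five-bin rule.**  `min_width = 5` is enforced at candidate time:
  any split that would create a segment of fewer than 5 bins is never
  scanned, matching the reading that five contiguous bins are required to
  *call* a transition.  A side effect worth knowing: a strong 3-bin spike is
  not ignored but absorbed into a shortest-admissible (≥ 5 bin) segment with
  a diluted mean.  At 600 kb / 150 kb bins the rule corresponds to event
  resolutions of 3 Mb / 0.75 Mb (`cn_resolution()`).
* **Canonical arcs.**  An arc and its complement describe the same
  partition, so only arcs with `j < n` are enumerated; exact ties break
  toward the leftmost `(i, j)`.  This makes the scan deterministic and lets
  the brute-force reference (`exhaustive_best_split()`) agree with the fast
  path bin for bin.
* **Permutations** shuffle ratios within the segment under test using R's
  RNG (reproducible via `cbs_params(seed=)`).  The test stops early once the
  exceedance count reaches `ceil(alpha * n_perm)`, at which point the
  p-value is already guaranteed to be `>= alpha`; early stopping therefore
  never changes an accept/reject decision, it only skips permutations that
  cannot matter.
* **Chromosome boundaries** are hard breaks: segmentation runs per
  chromosome, and chromosome starts are never reported as data-driven
  boundaries by `segment_boundaries()`.
* **Degenerate inputs**: profiles shorter than `2 * min_width` return a
  single segment with a warning; constant profiles never split (the
  statistic is 0).

The permutation design controls the per-test false-split rate at `alpha`,
so a genome-scale run performing a few dozen tests will occasionally emit a
false boundary; this is inherent to the method, not a defect, and the
acceptance thresholds below account for it.

## Absolute copy number

`fit_absolute()` maps mean segment ratios to integers through a single
multiplier `m`, chosen on a grid (0.55–8.0, step 0.01) to minimise the
bin-weighted distance of scaled ratios to integers.  Weighting by segment
size stops small noisy segments from steering the ploidy scale.  Two
degeneracies are handled explicitly:

* **Flat profiles** (normal karyotype) leave `m` unidentifiable — every
  integer multiplier fits exactly.  The default resolves to diploid
  (`m = 2`) and sets `ploidy_unresolvable = TRUE`; with
  `diploid_fallback = FALSE` the documented tie-break (smallest grid value)
  applies.
* **Ploidy doubling**: `2m` fits nearly as well as `m` whenever every
  scaled ratio is close to an integer.  A grid step of 0.01 keeps the true
  scale from falling between grid points, which at coarser steps (e.g.
  0.05) can let the doubled multiplier win outright.  Ties break toward the
  smallest multiplier.

`downsample_counts()` performs the read-depth resolution analysis with an
exact multivariate hypergeometric subsample of bin counts — equivalent in
distribution to subsampling reads without replacement — and
`spurious_segments()` / `breakpoint_recall()` / `cn_accuracy()` score a
called profile against a known truth (boundary tolerance ±2 bins for
spurious calls, ±1 for recall).

## Multiplexing

The five 24-nt native barcodes ship with the package
(`ont_native_barcodes()`); their minimum pairwise Hamming distance, by full
enumeration of the ten pairs, is 15 — comfortably above the design floor of
10.  `demultiplex()` assigns each read to the unique barcode within
`max_dist` mismatches of its leading bases, leaving ties and far reads
unclassified.  The default `max_dist = 4 = floor((10 - 1)/2)` is the
perfect-code radius: substitution-only errors of weight ≤ 4 can never move
a read closer to a wrong barcode than to its own, a property the test suite
verifies by exhaustive 1- and 2-error enumeration.  Indels and 3' barcodes
are out of scope.

## Validation design and problem sizes

The acceptance tests exercise the pipeline end to end on the benchmark
truth at the depths the short-molecule regime makes interesting:

* **Concordance**: two independent 4-million-read replicates correlate at
  *r* ≈ 0.993 (median of 10 seed pairs), and a 600,000-read multiplex-depth
  replicate against a full-depth replicate at *r* ≈ 0.976 — the simulation
  counterparts of cross-platform and multiplex-vs-singleplex comparisons.
  These sit where the variance decomposition predicts:
  `r ≈ var_signal / sqrt((var_signal + v1)(var_signal + v2))` with
  Poisson-scale noise `v ≈ n_bins / total_reads`.
* **Resolution**: over 20 seeds, median breakpoint recall (±1 bin) is
  ≥ 95% and median bin-level integer-CN accuracy ≥ 99% at 2 M, 1 M and
  500 k reads, while at 250 k reads the median spurious-boundary count
  strictly exceeds the 2 M value — at 5,000 bins, 250 k reads is ~50 reads
  per bin, the edge of the reliable regime.
* **Engine checks**: 50 seeded noisy-step instances where the recursive
  segmenter's first split must equal the exhaustive scan exactly; exact
  kinetics on deterministic runs; strict yield ordering of short over long
  libraries across 10 seeds.

These sizes (5,000 bins, ≤ 4 M reads, 10–20 seeds) were chosen as the
smallest configurations at which the claims are stable; the whole suite
runs in a few minutes on one core.

## Known limitations

* The generator's multinomial has no overdispersion; real low-pass data
  degrade sooner than the simulated depth thresholds suggest.
* Subclonal (fractional) copy number states are not modelled: purity enters
  the generator but the caller rounds to integers.
* The mappability track is supplied or uniform; the package does not
  compute mappability from a reference sequence.
* Barcode matching is substitution-only at a fixed read offset; indel-rich
  basecalls will inflate the unclassified fraction rather than
  mis-assign.
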