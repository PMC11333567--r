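---
title: "Mapping raw nanopore signals: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping raw nanopore signals: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(squigglemap)
```

squigglemap maps raw nanopore current signals to a reference genome
without basecalling, so that the mapping decision can be made while the
read is still being sequenced.  This vignette explains the underlying
model, the parameters that matter and why their defaults are what they
are, what the bundled simulator does and does not emulate, and the
numerical and design choices a maintainer should know about.

## The signal model

A nanopore read is a time series of current samples.  While a DNA k-mer
occupies the pore, the current fluctuates around a k-mer-specific
expected level; translocation moves the molecule one base at a time, so
the series is approximately piecewise constant with one segment ("event")
per k-mer, a mean dwell of `sampling_rate / bases_per_second` samples
(≈ 8.9 at 4 kHz and 450 b/s) and Gaussian noise around each level.  A
*pore model* tabulates the expected level mean and spread for every
k-mer; with it, a reference sequence can be translated into the same
event space in which the read is observed.  Absolute current units are
irrelevant downstream because both sides are z-score normalized before
comparison — which also absorbs the per-read offset and gain differences
real sequencers exhibit.

## Stage by stage

### Event segmentation

Boundaries are detected where the Welch t-statistic between the windows
of `w` samples on either side of a candidate split peaks above a
threshold; a short window (`w_short = 4`, threshold 4.5) reacts to brief
events while a long window (`w_long = 16`, threshold 3.0) is more
sensitive to small level steps.  Peaks from both windows are pooled and
non-maximum suppression keeps the strongest peak within `w_short`
samples.  Events shorter than `min_dwell = 3` samples are merged into a
neighbour to suppress stutter.  All of these are configuration values,
not claims about optimality for any particular pore chemistry.

The streaming wrapper (`segment_state()` / `extend_events()`) re-detects
over all samples accumulated so far and emits an event only once its
boundaries can no longer change — an event is withheld while it lies
within `w_long + 8 * w_short` samples of the stream end (new samples can
spawn t-statistic peaks up to `w_long` before the end, and a cascade of
suppression flips can walk a few `w_short` radii further) or while it is
one of the last two events (a trailing boundary or short-event merge can
still alter those).  This makes chunked and single-shot segmentation
*identical* on the closed events, which the test suite asserts on random
signals; the price is re-detection cost that is quadratic in read length
in the worst case, acceptable at Read Until scales where reads are
decided within a few chunks.

Normalization uses mean/SD rather than median/MAD; for the roughly
Gaussian level mixtures produced by real pores either works, and
mean/SD keeps the reference and query frames strictly comparable.
Statistics are recomputed over *all* events seen so far each chunk —
per-chunk statistics destabilize the earliest (most valuable) decisions.

### Adaptive quantization

Normalized levels concentrate around zero, so uniform binning wastes
resolution in the tails.  The bifurcated map gives the fine range
`[f_min, f_max] = [-2, 2]` a fraction `f_r = 0.8` of the resolution and
quantizes the coarse tails at `c_r = (1 - f_r) * 0.5` per unit.  The
formula is implemented branch-for-branch as stated in `?quantize` and
its raw value is clamped into `[0, n]`: for large `|s|` the coarse
branches leave the range, and the sub-`f_min` branch can overlap the
fine branch's output values.  The overlap is a property of the published
piecewise form; it is harmless for matching because reference and query
pass through the *same* map, and we deliberately do not "repair" it with
offset bands.  Only piecewise (per-branch) monotonicity is guaranteed,
and that is what the tests assert.

Defaults `n = 15` (4 bits per value) and `e = 5` events per seed were
calibrated on the package's simulation conditions as a
sensitivity/uniqueness trade-off: a seed matches only if all `e`
consecutive events quantize identically on both sides, so the
per-event bucket width must comfortably exceed the post-normalization
noise on an event mean, while `e * bits` must stay large enough that
random 20-bit collisions are rare against a 10^5-scale genome.  Much
finer grids (say `n = 127` with `e = 6`) make exact multi-event matches
vanishingly rare at realistic noise; much coarser ones flood the chainer
with false anchors.  Seed hashes are packed big-endian into doubles
(exact below 2^53, hence the `e * bits <= 52` constraint) and passed
through an invertible affine mixer modulo `2^bits` so that hash order is
decorrelated from level order — without it, minimizer sketching would
systematically prefer low-current seeds.

### Index, minimizers and frequency filters

The reference is indexed on both strands; reverse-strand postings are
kept in reverse-complement k-mer coordinates so that anchors remain
colinear with the query in the chaining DP, and are flipped to forward
base coordinates only when a PAF row is emitted.  Reference levels are
normalized with *global* (all contigs, both strands) statistics, stored
in the index: query normalization is per read, and a single global
reference frame keeps the two sides comparable.

Minimizer sketching (off by default, `minimizer_params()`) keeps a seed
iff it is the minimum of some window of `w_min` consecutive seeds, ties
to the leftmost; expected density on random hashes is `2 / (w_min + 1)`.
The two frequency filters bound hash multiplicity: on the reference,
hashes with more than `max_ref_occ` postings are dropped at build time
(`auto_freq_cap()` offers the minimap2-style "keep 99.8% of distinct
hashes" rule); on the query, hashes repeated more than `max_query_occ`
(default 5) times within a read are dropped before lookup.

### Chaining and mapping quality

Anchors are chained per contig/strand with the gap-penalty recurrence
(`?chain_anchors`).  The penalty `gamma_c(l) = 0.01 w |l| + 0.5 log2 |l|`
is pinned to 0 at `l = 0`, where the printed form is undefined — a zero
gap must cost nothing.  Reference coordinates are event indices and
query coordinates are event indices; the mild scale mismatch between the
two (segmentation merges/splits) is absorbed by the gap penalty rather
than modelled.  `max_skip` / `max_iter` are purely performance heuristics;
the test suite disables them and checks the DP against exhaustive
enumeration of all colinear anchor subsequences on random instances.
Chains need `min_anchors >= 4` anchors and score `>= 25` (calibrated
together with the quantization defaults; true chains on these conditions
score in the hundreds, random ones rarely exceed ~15).  Mapping quality
uses the minimap2-style formula in `?mapping_quality`, capped at 60.

### The weighted decision

After each chunk the mapper computes three ratios — `r1`: primary mapq
against a reference quality of 30; `r2`: best mapq against the mean mapq
of all chains; `r3`: best score against the mean score — caps `r2`/`r3`
at 5, rescales them to `[0, 1]`, and maps the read iff
`w_sum = 0.4 r1 + 0.3 r2 + 0.3 r3 > tau = 0.55`.  A single chain
saturates `r2 = r3 = 1`.  One structural quirk is worth recording:
because non-primary chains always receive mapq 0, `r2` degenerates to
(number of chains)/cap whenever the primary mapq is positive, so the
discriminative burden falls on `r1` and `r3`; the formula is kept as
specified, with a guard (`r2 = 0`) when every mapq is zero.  The read is
reported unmapped (`decision = unmapped_max_chunks`) when the signal or
the `max_chunks = 30` budget is exhausted first — unmapped reads are
reported, not dropped, so sequencing-cost accounting covers every read.

## The simulator

`simulate_reads()` draws read origins uniformly (contigs weighted by
length, fair-coin strand), expands model levels by a rounded-Gamma dwell
(mean `sampling_rate / bases_per_second`, CV `dwell_dispersion = 0.25`,
floor 1 sample), adds Gaussian noise of `noise_sd_scale = 1` times the
model's per-k-mer SD, applies a per-read affine distortion
(`a ~ N(1, 0.02)`, `b ~ N(0, 1)` model units) and snaps samples onto the
SLOW5 integer grid.  These defaults are realistic for R9.4-style DNA
runs: dwell over-dispersion (hence Gamma, not geometric), noise of the
same order as the tabulated level SDs, and percent-level gain drift
between reads.

What it does **not** emulate: stalls and backsteps, skipped k-mers,
within-read drift (an optional linear-drift stress flag was considered
and left out of the default model), adapter/barcode signal, homopolymer
dwell pathologies, or basecaller-visible error structure.  Passing
end-to-end tests therefore demonstrates the pipeline's correctness and
its robustness to level noise, dwell variance and affine distortion —
not performance on real flow-cell data, where segmentation quality and
pore-model fit dominate.

## Numerical choices and degenerate inputs

* t-statistic denominators are floored at `1e-12`, so a noiseless step
  yields a huge but finite peak at the exact boundary; constant signal
  yields one event.
* `normalize_levels()` refuses constant input (zero variance signals an
  unusable read/chunk); the index build instead warns and uses unit
  scale, so a degenerate homopolymer reference is indexable and then
  handled by the frequency filter.
* Sequences containing `N` produce no levels at covering k-mers and
  split the level array into segments — imputing levels would fabricate
  seeds.
* Quantized hash arithmetic is exact double arithmetic below 2^53; the
  mixer uses a 26-bit split so every intermediate stays exact.
* Minimizer ties break to the leftmost position; with fewer seeds than
  one window the whole list is treated as a single window.
* PAF query coordinates come from the `events_per_base` estimate
  (events seen / bases consumed); they are estimates, unlike target
  coordinates, which are exact event-to-base conversions.

## Problem sizes

The test suite and the acceptance script run the full pipeline on a
100 kb two-contig random genome with 200 simulated reads (mean 1 kb)
plus 50 foreign-genome negative controls — sizes chosen so the whole
suite completes in well under a minute of mapping time on one core while
still exercising multi-chunk decisions, both strands, both contigs and
the negative path.  On these conditions the pipeline typically reaches
precision ≈ 1.0, recall ≈ 0.91–0.95, zero-to-one false positives among
the negative controls, and a mean sequencing cost below 520 bases per
decided read against a 13,500-base budget; the exact numbers for a given
seed are computed, not quoted, by `scripts/acceptance.R`.

## Known limitations

* Chains are recomputed from all accumulated anchors at every chunk; an
  incremental DP would be needed for very long undecidable reads.
* Pore models are consumed, never fitted; RNA and R10.4-family
  chemistries need their own segmentation tuning and models.
* Only the ASCII SLOW5 dialect is parsed natively; FAST5/POD5 require
  external converters.
* The mapper reports one primary mapping per read (no supplementary or
  split mappings), which is the Read Until use case.
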