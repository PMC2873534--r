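---
title: "Detecting driver copy-number aberrations with cnapeel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting driver copy-number aberrations with cnapeel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnapeel)
```

## The problem

Tumor genomes carry many somatic copy-number aberrations (SCNAs). A few are
*drivers* — gains of oncogenes or losses of tumor suppressors under positive
selection — while most are *passengers* with no functional role. Given
segmented copy-number profiles for a cohort of tumors, the task is to find
genomic regions aberrant more often, and more strongly, than chance would
allow, and to localize the likely driver within each such region.

cnapeel implements the GISTIC family of marker-level statistics for this
task, including a *limited peel-off* variant designed for the hardest case:
several independent driver loci buried inside one broad aberration (for
instance a whole-arm gain), where the classic algorithm reports a single
peak and discards everything else.

## The score

The input is a markers-by-samples matrix of segmented log2 copy-number
ratios, \(CN(m, i)\), centered at 0 for diploid. (The scale is a
convention, not a requirement of the algorithm, but the default thresholds
assume it.) Amplifications and deletions are analyzed separately and
symmetrically. For amplifications, each marker gets a G-score

\[ G(m) \;=\; \sum_i G(m,i), \qquad
   G(m,i) \;=\; CN(m,i)\, I\!\left[ CN(m,i) \ge \Theta^{AMP} \right], \]

the sum of supra-threshold copy numbers across samples: frequency and
amplitude of aberration in a single statistic. The deletion score mirrors
this with \(CN \le -\Theta^{DEL}\) and a sign flip. The boundary value
counts as aberrant. Defaults are \(\Theta^{AMP} = \Theta^{DEL} = 0.1\)
(log2-ratio units), a conventional operating point for segmented array
data; both are configurable and should be revisited for noisier platforms.

The *focal* variant replaces the fixed threshold by a per-sample one:
\(\Theta\) plus the largest arm median observed in that sample (smallest,
for deletions), floored so it is never laxer than the standard threshold.
Broad, arm-scale events shift whole-arm medians, so their contribution is
discounted and only high-level focal signal remains.

## Significance

Significance is assessed against a genome-wide permutation null: each
sample's per-marker contributions are shuffled independently, so the null
score at a marker is a sum of one random draw per sample. Two estimators
are provided:

* **Histogram convolution** (default): each sample's empirical contribution
  distribution is binned (10,000 bins spanning the maximal possible score)
  and the per-sample histograms convolved. This is the same independence
  null, computed semi-exactly and deterministically; binning error is
  bounded by the bin width and is conservative, because contributions are
  rounded up to their bin edge and observed scores are looked up
  right-closed.
* **Monte-Carlo permutation** behind a flag with a mandatory seed, retained
  as an independent cross-check of the convolution (the two are compared
  within binomial error in the test suite).

Per-marker p-values are corrected across all markers of one direction with
the Benjamini–Hochberg step-up (via `stats::p.adjust`); markers with
q-value below 0.25 are deemed significant, the customary cutoff for this
statistic. `gscore_for_q()` inverts the null: the smallest score whose tail
probability is at most the q-threshold. That score-scale equivalent of the
significance cutoff is what the limited peel-off uses as its abort
threshold \(G_{thres}\).

Two deliberate choices here:

* The null is built once from the observed contribution grid and **frozen**
  across peel-off iterations. It models the chance aberration background;
  rebuilding it after signal has been removed would deflate it and bias
  later iterations toward significance.
* A sample-permutation null means a *single-sample* cohort can never reach
  significance (every marker's q is 1 by symmetry); the pipeline reports
  zero peaks rather than erroring.

## Peak discovery and peel-off

Discovery is iterative: score the working grid, find the marker with
minimal q (ties broken by larger G, then smaller coordinate), extend it to
a region, remove the peak's influence, repeat until nothing is significant.

**Region extension.** A peak defined by few samples has unstable
boundaries, so each sample is left out in turn, q-values are recomputed
against the frozen null, and the q-minimum plateau around the peak is
re-derived. The reported region is the union of these leave-one-out
plateaus with the all-samples plateau (an intersection mode exists behind
a flag for narrower reporting).

**Standard peel-off** zeroes, for every sample whose aberration covers the
peak marker, the whole contiguous run of positive contributions containing
it. On a broad aberration this wipes the entire event after the first peak.
**Arm peel-off** zeroes the full chromosome arm instead; the **focal**
variant is the standard peel applied to the focal contribution grid.

**Limited peel-off** removes only the component of each contribution
attributable to the peak. Walking outward from the region edge within a
sample's run, the peak-attributable part starts at the edge value and can
only decrease:

\[ G_r(m, i) = \min\!\Big( G_r(m-1, i),\;
   \max_{m \le m' \le \min(m+s-1,\,\text{run end})} G(m', i) \Big), \]

with \(G_r = G\) inside the region and \(G_r = 0\) outside the run. A
reduction is accepted only if sustained for at least \(s\) consecutive
markers — the look-ahead window above — because transient segmentation
fluctuations otherwise release spurious signal. \(s = 0\) and \(s = 1\)
both accept instantaneous dips. The peak-independent remainder is
\(G_n(m,i) = \max(0,\, G(m,i) - G_r(m,i))\), and
\(\sum_i G_n(m,i)\) is exactly the score marker \(m\) would retain after
the peel. At the first marker where that sum reaches \(G_{thres}\) — where
the remaining signal would be significant on its own — the peel aborts on
that side: markers beyond keep their contributions, markers between region
edge and abort point are reduced by \(G_r\), and a later iteration can
discover the preserved signal as an independent peak.

If a side's walk completes with no abort, there is no evidence of an
independent peak there and the run is zeroed exactly as the standard peel
would. This makes \(G_{thres} = +\infty\) reproduce the standard variant
peak-for-peak — a property the acceptance suite checks on 20 seeded
cohorts — while lower thresholds preserve progressively more sub-structure.
When the focal null is degenerate (no aberrations in a direction) or cannot
reach the q-threshold, \(G_{thres}\) falls back to \(+\infty\).

Per-sample edits are always confined to that sample's own contiguous run:
leave-one-out extension can push a region edge across a zero gap in one
sample, and editing past the gap would peel aberrations that do not contain
the peak.

**Choosing s.** The persistence parameter is in marker units; the default
is 10. Two diagnostics support tuning: `segment_size_histogram()` (candidate
values are sizes where the segment-count decay steepens) and
`min_peak_distance()` (an excess of near-adjacent peaks indicates spurious
splitting). On fixed input the reported peak count is non-increasing in
\(s\) in our tests; note that genome-wide BH coupling means this is a
strong empirical regularity, not a theorem — removing more signal on one
chromosome can lift another chromosome's q-values across the cutoff.

## Annotation and enrichment

Peaks are annotated with all genes overlapping the reported span by at
least one base pair. `peak_shift_test()` estimates whether peaks contain
likely driver genes more often than size-matched random regions: each
iteration relocates every peak independently to a uniform random genome
position (chromosome chosen proportional to its number of valid start
positions, peak kept wholly on-chromosome), and the p-value uses the
add-one estimator \((1 + \#\{ \text{perm} \ge \text{obs}\})/(1 + n)\), so
it is never exactly zero. Shifted peaks may overlap each other — shifts are
independent. The driver list is a user-supplied flat file; no database
queries at run time.

## The synthetic-cohort generator

`simulate_cohort()` generates the study conditions every test runs under:
per-sample baseline 0, Gaussian marker noise (default SD 0.1 log2-ratio
units, a typical residual level for segmented array data), and planted
events that add their amplitude over a marker span to
\(\lceil \text{fraction} \times N \rceil\) randomly chosen carriers.
An optional segment-noise mode draws one constant noise value per random
segment (geometric lengths) per sample — the regime that motivates \(s\),
since segment boundaries create sustained steps rather than per-marker
jitter. Generation is bit-reproducible given the spec, which includes the
seed.

What the generator does *not* emulate: segmentation artifacts correlated
across samples (shared breakpoints must be planted explicitly, as the
persistence-sweep fixture does), platform-specific noise, GC waves,
subclonal fractional amplitudes, and tumor purity dilution. Passing tests
on these cohorts therefore demonstrate correctness of the statistics and
the peel logic under the stated model, not performance on any particular
array platform.

`two_peak_fixture()` is the canonical hard case, noise-free and fully
deterministic: five samples share a broad gain (0.5 over markers 31–70 of
100) with two embedded stronger sub-regions (1.2 over 45–49, 1.1 over
55–59) separated by a five-marker dip. The standard variant reports one
peak and wipes the rest; the limited variant (any \(s \le 5\)) aborts at
the second sub-region and reports both, and its result is unchanged by a
broad gain planted on another chromosome.

## Problem sizes and numerical choices

The test and acceptance workloads use cohorts of 150–1,000 markers per
chromosome and 5–20 samples, with 20–50 seeded replicates per property —
large enough that every code path (nulls, BH, extension, aborts) is
exercised on realistic structure, small enough to keep the suite fast.
Other conventions, chosen once:

* Coordinates are 1-based inclusive everywhere internally and in reports;
  only BED export converts to 0-based half-open. Chromosome names are
  normalized by stripping a leading `chr`; mitochondrial markers are
  excluded by default; markers in neither arm interval (centromere gaps)
  are dropped with a logged count so arm medians stay well defined.
* Missing entries contribute 0 to every score and are excluded from arm
  medians; a sample with no data at all is an error, named.
* Arm medians use all non-missing markers of the arm (not only
  non-aberrant ones).
* The abort inequality is non-strict (\(\ge G_{thres}\)); the threshold
  boundary of the score indicator is inclusive.
* Scores beyond the null support (possible when top-bin probabilities
  underflow) are assigned the smallest representable tail mass, with a
  message.
* Peel-off progress is asserted every iteration (total score must strictly
  decrease) and the loop is additionally capped at one iteration per
  marker.

## Known limitations

* LOH analysis is out of scope.
* The permutation unit is the marker, independently per sample: marker
  autocorrelation is not preserved under the null, which makes the null
  slightly optimistic about long-range structure. Segment-aware
  permutation is not implemented.
* Reported regions of one direction in one run are kept non-overlapping by
  clipping against earlier peaks; a later peak arising strictly *inside* an
  earlier region (possible, since peels only edit samples carrying the
  earlier peak) is reported as found.
* q-values of later iterations are computed against the frozen null but a
  shrinking effective signal, so they are comparable to first-iteration
  q-values only as decision thresholds, not as error estimates.
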