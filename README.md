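# cnapeel

Detection of candidate **driver copy-number aberrations** in tumor cohorts
from segmented log2-ratio profiles, for cancer-genomics analysts working
with marker-level or SEG-format copy-number data.

Tumor genomes are littered with somatic copy-number changes; only a
minority are drivers under selection. cnapeel implements the GISTIC-style
marker statistic for separating them from passengers: each marker *m* gets
a **G-score**

    G(m) = Σ_i CN(m,i) · I[CN(m,i) ≥ Θ]          (amplifications)

summing supra-threshold log2 ratios across samples (sign-mirrored for
deletions), so frequency and amplitude of aberration combine into one
statistic. Scores are compared with a genome-wide permutation null
(computed semi-exactly by histogram convolution, or by seeded Monte-Carlo
permutation), corrected with Benjamini–Hochberg FDR, and regions with
q < 0.25 are reported. Peaks are discovered iteratively, removing each
peak's influence before searching again ("peel-off").

Four peel-off variants are provided — **standard**, **focal** (per-sample
thresholds discounting broad, arm-scale events), **arm**, and **limited**
peel-off. Limited peel-off is the interesting one: instead of zeroing every
aberration covering a peak, it decomposes each marker's score into a
peak-attributable part `G_r` and a peak-independent part `G_n`
(reductions accepted only when sustained for ≥ s markers), and aborts the
peel where Σ G_n would itself be significant. Independent sub-peaks inside
broad aberrations — where the classic algorithm reports a single peak —
survive and are reported.

Also included: SEG and marker-matrix readers, IGV/BED track export,
peak-to-gene annotation with a peak-shift permutation enrichment test,
tuning diagnostics for s, and a seeded synthetic-cohort generator with
planted ground truth.

## Worked example

The bundled `two_peak_fixture()` is the canonical hard case: five samples
share a broad gain (log2 ratio 0.5, markers 31–70 of 100) containing two
stronger sub-regions (1.2 over markers 45–49 and 1.1 over 55–59) separated
by a short dip.

```r
library(cnapeel)
fx <- two_peak_fixture()
fx$cn
#> cn_matrix: 100 markers x 5 samples on 1 chromosome(s)
#>   missing entries: 0

run_variant(fx$cn, direction = "AMP", variant = "standard")[,
  c("chrom", "start_bp", "end_bp", "q_peak", "g_peak", "order")]
#>          chrom start_bp end_bp   q_peak g_peak order
#> c1_m0045     1   450000 490000 6.25e-06      6     1
```

The standard variant finds the stronger sub-region (G = 6 = 5 samples
× 1.2, q ≈ 6e-6), then peels the entire broad run — the second sub-region
is gone. Limited peel-off aborts the peel where the residual score would be
significant on its own:

```r
run_variant(fx$cn, direction = "AMP", variant = "limited", s = 2,
            verbose = TRUE)[,
  c("chrom", "start_bp", "end_bp", "q_peak", "g_peak", "order")]
#> derived G_thres = 1.701
#> iter 1: AMP peak at 1:450000 (marker 45), q = 6.25e-06, G = 6, region markers 45-49
#> iter 2: AMP peak at 1:550000 (marker 55), q = 0.0002, G = 5.5, region markers 55-59
#>          chrom start_bp end_bp   q_peak g_peak order
#> c1_m0045     1   450000 490000 6.25e-06    6.0     1
#> c1_m0055     1   550000 590000 2.00e-04    5.5     2
```

`G_thres = 1.701` is the G-score equivalent of q = 0.25 on the focal-variant
null; at the second sub-region the peak-independent score (5 × (1.1 − 0.5)
= 3.0) exceeds it, the peel stops, and iteration 2 reports the second peak.
Both reported spans are exactly the planted sub-regions.

For file-based runs use `run_config()` + `run_pipeline()` (writes peak
reports, per-marker G/p/q tables, IGV/BED tracks and a run log), or the
shell wrapper:

```sh
Rscript inst/scripts/cnapeel run --matrix cohort.tsv --arms arms.tsv \
    --genes genes.tsv --variant limited --s 10 --seed 1 -o out/
```

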