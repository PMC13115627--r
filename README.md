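# mitodel

Detection and quantification of large-scale mitochondrial DNA (mtDNA)
deletions from amplification-free long-read sequencing.

Single large-scale mtDNA deletions (SLSMD) and multiple mtDNA deletions
(MMD) are a major class of pathogenic variation in primary mitochondrial
disease. Because long HiFi reads traverse entire deletion junctions,
aligned long reads carry each deletion as an explicit gap — which makes
breakpoints exact and heteroplasmy (the fraction of mtDNA molecules
carrying the deletion) directly countable, without the long-range-PCR
amplification bias that prevents short-read assays from quantifying
deletion load. `mitodel` implements that analysis for the circular
16,569 bp mitochondrial genome, for anyone analysing PacBio-style long
reads aligned to `chrM`/NC_012920.1.

## What it computes

Given alignments of one sample restricted to the mitochondrial contig:

1. **Deletion calling** — every CIGAR `D` operation and every split
   (supplementary) alignment pair implying a reference gap of 500 bp to
   15,000 bp becomes a deletion event with 5′ breakpoint `b5` (first
   deleted base) and 3′ breakpoint `b3` (first retained base). Coordinates
   live on a circle: a deletion is the half-open arc `[b5, b3)` with
   length `b3 − b5 (mod L)`, so the common deletion `(8470, 13447)` spans
   4977 bp.
2. **Breakpoint clustering** — DBSCAN over `(b5, b3)` with a wrap-aware
   Euclidean metric (defaults ε = 50 bp, minPts = 2). One recurrent
   cluster holding all events ⇒ **SLSMD**; two or more clusters ⇒ **MMD**;
   no events ⇒ **Negative**.
3. **Heteroplasmy** — `100 × n_del / cov(MT-RNR2)`: deletion-bearing reads
   over mean MT-RNR2 coverage, the long-read analogue of the ddPCR
   reference probe. The companion ddPCR estimate is
   `[1 − ND4/RNR2] × 100 %`.
4. **Method agreement** — Pearson correlation and Bland–Altman bias /
   limits of agreement (`bias ± 1.96 · SD(diff)`, sample SD) between
   long-read and ddPCR heteroplasmy.
5. **Microhomology** — for each unique junction (outside the D-loop), the
   run of position-wise identical bases through the breakpoint shared by
   the two 40 bp junction flanks; distributions compare against
   MITOMAP/MitoBreak-style catalogues.
6. **Support tooling** — a coverage-downsampling precision experiment,
   benchmark sensitivity/specificity/precision/recall with the
   fixed-denominator convention `TN = 16,569 − calls`, and a seeded
   simulator that writes SAM fixtures with known truth.

## Worked example

Simulate an SLSMD sample (common deletion at 30 % heteroplasmy, 800×) and
run the full pipeline:

```r
library(mitodel)

ref  <- simulate_reference(16569, seed = 3)
sim  <- simulate_sample(ref, sim_preset("slsmd", seed = 3))
call <- mito_detect(sim$reads, ref, sample_id = "demo")
call
#> <mito_call> demo: SLSMD
#>   mean coverage 798.1x | MT-RNR2 coverage 865.92x
#>   247 deletion read(s) in 1 cluster(s) | heteroplasmy 28.52%

tidy(call)
#> # A tibble: 1 × 8
#>   cluster_id rep_b5 rep_b3 del_len support recurrent name                heteroplasmy_pct
#> 1          1   8470  13447    4977     247 TRUE      m.8470_13446del4977             28.5
```

The planted junction is recovered exactly (8470/13447, 4977 bp); the
estimate 28.52 % sits within sampling error of the planted 30 % (binomial
SE ≈ 1.6 points at this depth). `glance(call)` returns the one-row
per-sample report; `plot_coverage(call$profile, call$clusters)` shows the
coverage dip between the breakpoints, and `plot_deletion_arcs(tidy(call))`
draws the junction as a circos-style chord.

Method agreement between long-read and ddPCR heteroplasmy:

```r
pairs <- tibble::tibble(
  sample_id = c("S1", "S2", "S3", "S4"),
  lrs_pct   = c(63.91, 33.43, 25.25, 31.03),
  ddpcr_pct = c(73, 45, 40, 34)
)
bland_altman(pairs)
#> Bland-Altman agreement (n = 4)
#>   bias -9.60%  SD of differences 4.99
#>   limits of agreement [-19.37%, 0.18%]
pearson_r(pairs)
#> [1] 0.958
```

The long-read estimate runs systematically below ddPCR in SLSMD samples
(negative bias), while the two track each other tightly (r ≈ 0.96).

A shell front end wraps the same functions:

```sh
Rscript inst/scripts/mitodel.R detect --bam reads.sam --ref ref.fasta --out out/
Rscript inst/scripts/mitodel.R simulate --preset mmd --out fixtures/ --seed 7
```

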