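---
title: "Detecting and quantifying large-scale mtDNA deletions from long reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and quantifying large-scale mtDNA deletions from long reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitodel)
```

## The problem

The human mitochondrial genome is a 16,569 bp circle present in hundreds to
thousands of copies per cell. Pathogenic large-scale deletions — single
large-scale mtDNA deletions (SLSMD) and multiple mtDNA deletions (MMD) —
remove kilobase-scale arcs of that circle from a *fraction* of the
molecules; that fraction, the heteroplasmy, correlates with disease onset
and severity. Amplification-free long reads make both questions tractable
at once: a HiFi read from a deleted molecule aligns across the junction, so
the breakpoints are directly observable, and counting junction-bearing
reads against total molecule depth yields heteroplasmy without PCR bias.

`mitodel` implements that workflow: alignment ingestion, deletion-event
extraction, breakpoint clustering and sample classification, heteroplasmy
quantification, method-agreement statistics, and breakpoint-microhomology
analysis, together with a seeded simulator that serves as the test
substrate for all of it.

## Coordinate model

Positions are 1-based on a circle of length $L$ (default 16,569; position
$L+1 \equiv 1$). A deletion is the half-open arc $[b_5, b_3)$: $b_5$ is the
first deleted base and $b_3$ the first retained base, so the deleted length
is

$$d = (b_3 - b_5) \bmod L .$$

This convention is fixed by the best-known landmark: the common deletion at
breakpoints (8470, 13447) spans exactly 4977 bp. Deletion names are
rendered `m.{b5}_{b3-1}del{d}` — first and last deleted base inclusive —
because published labels for the same deletions mix end-inclusive and
end-exclusive habits; one convention is applied everywhere and documented
rather than guessed per sample. Origin-spanning deletions ($b_3 < b_5$) are
first-class: every interval operation (region membership, flank slicing,
cluster metric) wraps.

## Deletion evidence

Two kinds of alignment evidence produce events:

* **CIGAR `D` operations.** Long-read aligners with permissive gap
  penalties represent most mtDNA deletions as a `D` op inside one record.
  Each `D` whose length falls in the inclusive size window **500–15,000 bp**
  becomes an event. The window is the working definition of "large-scale":
  below it lie small indels (a different mutational class, called by SNV
  callers), above it a deletion would leave less than ~1.5 kb of genome.
* **Split alignments.** A junction can instead surface as two supplementary
  segments of one read. Segments adjacent in read coordinates (query gap
  ≤ 50 bp) whose reference gap falls in the window yield an event; the gap
  is measured on the circle, which also recovers origin-spanning junctions.
  Contiguous origin-split pairs (gap 0) are ordinary circular alignments,
  not deletions.

A read seen both ways at the same `(b5, b3)` counts once. The molecule
count `n_deletion_reads` is distinct read ids, not events: heteroplasmy is
a fraction of molecules, and a single molecule carrying two junctions is
still one deleted molecule. An optional `merge_gap` joins `D` ops separated
by ≤ 10 bp of alignment wobble; it defaults off because junction placement
in error-free HiFi alignments is already exact, and merging changes event
identity.

Ingestion keeps primary and supplementary records on the mitochondrial
contig with mapping quality ≥ 10 and always drops secondary records. The
contig restriction plus the mapq threshold is the package's only guard
against nuclear-embedded mtDNA segments (NUMTs); no homology masking is
attempted. Depth counts aligned bases only (`M`, `=`, `X`), so deletion
gaps contribute zero depth: the coverage dip between SLSMD breakpoints is
visible, and MT-RNR2 depth counts exactly the molecules that physically
cover MT-RNR2.

## Clustering and classification

Events are points in the $(b_5, b_3)$ plane, clustered with DBSCAN under a
Euclidean metric whose axes wrap at $L$ (breakpoints straddling the origin
must co-cluster). Defaults: $\varepsilon = 50$ bp, minPts $= 2$.
$\varepsilon$ is generous against HiFi breakpoint jitter of a few bases
while remaining far below the spacing of distinct junctions; minPts $= 2$
encodes "more than one read ⇒ recurrent". Both are exposed. Noise points
are kept as singleton clusters rather than discarded, because a deletion
seen in a single molecule still counts as a deletion species when
classifying the sample.

Classification: no events ⇒ `Negative`; a single recurrent cluster holding
everything ⇒ `SLSMD`; two or more clusters ⇒ `MMD`; a lone singleton
cluster ⇒ `LowEvidence` (insufficient to call a deletion syndrome, worth
flagging). Cluster representatives are per-coordinate medians, computed
after unwrapping members around the first member so that clusters near the
origin do not average to the far side of the circle. A sample with zero
observed deletion reads reports `Negative` even if prior clinical evidence
suggests deletions below the detection limit; overriding with external
knowledge is deliberately left to the caller.

## Heteroplasmy

$$\hat h = 100 \times \frac{n_{\text{del}}}{\overline{\text{cov}}(\text{MT-RNR2})}$$

The numerator counts deletion-bearing reads (molecules with evidence); the
denominator is mean MT-RNR2 depth, standing in for the total number of
molecules sequenced. MT-RNR2 is used because it is very rarely deleted, and
because it mirrors the reference probe of the clinical ddPCR assay
($[1 - \text{ND4}/\text{RNR2}] \times 100\%$), keeping the two estimates
structurally comparable. Estimates are reported at two decimals; full
precision is kept internally. The estimator can exceed 100% only on
pathological input and warns when it does. Its known biases: junctions very
near a read end are unobservable (a read must span the junction), and rare
deletions that remove MT-RNR2 itself inflate the denominator's meaning —
both limitations shared with the assays it mirrors.

Method agreement uses Pearson's $r$ (via `stats::cor`) and Bland–Altman
bias and limits of agreement $\text{bias} \pm 1.96\,s_d$. $s_d$ is the
*sample* standard deviation ($n-1$ divisor): with the four SLSMD cohort
pairs this is the only choice that reproduces the published limits
$[-19.37, 0.18]$ from the published per-sample values, which pins the
convention.

Benchmark metrics follow the fixed-denominator convention used for
variant-call comparisons on this genome: $TN = 16{,}569 - \text{calls}$
(the truth-set call count), percentages at two decimals, and any $0/0$
ratio reported as $0.00$ rather than NA, matching how empty classes are
tabulated in practice.

## Microhomology

For each unique junction (cluster representative) the two flanks are the
$2w$ bases centred on each breakpoint ($w = 20$, circular slicing).
Microhomology is the run of position-wise identical bases through the
junction: the forward run starting at the breakpoint base plus the backward
run ending just before it, capped at $2w$. "Perfect match" could also be
read as the longest common substring of the two flanks at any offset; that
reading inflates lengths on random 40-mers (a shared 4-mer occurs by chance
in most pairs), so the junction-anchored rule is the default and the
substring rule is available as `method = "substring"`. Deletions with
either breakend in the D-loop are excluded by default: the control region's
repeat structure and the origin make junction context there unreliable.
Catalogue comparisons (MITOMAP/MitoBreak-style TSV exports) run the same
scoring path, so sample-vs-catalogue histograms are directly comparable.
Published ≥1 bp-homology percentages for those databases depend on database
snapshots and are not reproduced here.

## The simulator

`simulate_sample()` emulates exactly the data structure the pipeline
consumes: a circular genome; a molecule population mixing intact circles
and deletion-bearing circles at configured fractions (the truth
heteroplasmy, exact at molecule level); fragments with lognormal lengths
(median ≈ 10 kb, truncated to [1 kb, molecule length]) placed uniformly on
each circular molecule; and perfect gapped alignments emitted as SAM.
Fragment class is drawn with probability proportional to fraction × molecule
length — shearing a longer molecule yields proportionally more fragments —
which is what makes the read-level heteroplasmy estimator converge to the
molecule-level truth.

One placement decision matters enough to spell out. Confining reads so that
no alignment crosses the reference origin looks attractive (every read is
one SAM record), but with ~10 kb reads on a 16.6 kb circle it concentrates
coverage mid-genome and starves the region near the coordinate start —
where MT-RNR2 sits — biasing the heteroplasmy denominator by double-digit
percentage points. Reads are therefore placed uniformly on the circle by
default, and a read crossing the origin is emitted as two hard-clipped
supplementary records, which the ingestion and split-pairing code handle
natively; `linear_only = TRUE` restores confined placement for simple
single-record fixtures. A junction and an origin crossing can co-occur in
one read; the junction then appears as a `D` op inside one of the two
segments.

What the simulator does *not* model: HiFi error profiles (homopolymer
indels, quality decay), alignment ambiguity at homologous junctions, NUMT
contamination, duplications, or replicate-level library effects.
Substitutions are available (never indels) and perturb only the emitted
sequences, not the alignments. Passing end-to-end tests therefore
demonstrates that the *logic* — event extraction, wrap arithmetic,
clustering, estimator algebra — is correct under clean alignments, not that
the pipeline is robust to aligner artefacts on degraded real data.

## Test problem sizes and tolerances

End-to-end recovery runs single-junction samples at planted heteroplasmy
5%, 25% and 65% and a five-junction MMD sample, each at 800× mean coverage
(≈1,300 molecules) — depths matching the middle of the cohort range — and
requires the estimate within three binomial standard errors of truth
(computed at the realised MT-RNR2 depth), breakpoints recovered exactly,
and the correct SLSMD/MMD/Negative class. The downsampling experiment uses
a 30% sample at 800×, the full 5–100% grid in 5% steps with 5 replicates
(100 re-analyses), and checks that replicate spread at ≥500× is below the
spread at ≤100× with a negative depth–spread trend across the grid — a
qualitative precision statement; exact SDs depend on the error-free read
model. Microhomology scoring is validated against a brute-force
run-length oracle on 1,000 random flank pairs and against planted homology
of 1–13 bp, the range observed in cohort MMD junctions. Desk-scale
arithmetic (heteroplasmy table rows, Bland–Altman limits, benchmark cells,
the 4977 bp gap) is asserted at printed precision.

## Known limitations

* Duplications and complex rearrangements are out of scope; only simple
  deletion arcs are modelled.
* Sensitivity at very low heteroplasmy is bounded by molecule sampling:
  below ~1 junction-spanning read per sample the caller necessarily
  reports `Negative` or `LowEvidence`.
* The mapq/contig NUMT guard is heuristic; no sequence-level masking.
* The mtDNA-content estimate (`2 × mt/n coverage`) assumes a diploid
  nuclear genome and unbiased sampling of both compartments.
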