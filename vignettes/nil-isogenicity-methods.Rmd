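---
title: "Characterizing near-isogenic line pairs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing near-isogenic line pairs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nilscan)
```

## The problem

A pair of near-isogenic lines (NILs) is designed to differ only inside
a target QTL region: one line homozygous for the donor allele, the
partner homozygous for the alternative, and an identical recombinant
background everywhere else. Reality is messier. Marker-assisted
selection (MAS) at two flanking markers drags along linked donor
segments (*linkage drag*), and whatever residual heterozygosity the
common ancestor still carried when the two lineages separated ends up
as unlinked non-isogenic blocks scattered through the genome. Any
inference about the QTL from contrasting the pair rests on knowing
where those blocks are.

nilscan takes chip-style biallelic SNP calls for the founder inbreds,
their F1, and the NIL pairs, and produces that map: a filtered marker
set, parent-of-origin genotypes, genome-distribution statistics,
non-isogenic block calls with publication-style summaries, a QTL
introgression check, and a linkage-drag measure. Because real data of
this kind are rarely redistributable, the package also ships a forward
simulator of the whole breeding scheme whose output carries exact
ground truth, so every stage can be validated quantitatively.

## Quality and pedigree filtering

Six ordered criteria remove SNPs that (1) failed in all samples,
(2) failed in either parent or the F1, (3) are unmapped or on the
unknown chromosome, (4) are heterozygous in a parent, (5) are
polymorphic between the parents without a heterozygous F1 call, or
(6) are monomorphic between the parents while a NIL carries the
alternative allele. Each excluded SNP is attributed to the *first*
criterion it violates, which reproduces sequential exclusion counts;
the retained set itself is the complement of the union of the six
predicates and therefore does not depend on the order (the suite
verifies this on random inputs). Failed calls are never reinterpreted
as null alleles: the chip chemistry cannot distinguish a deletion from
an experimental failure, so no inference is attached.

Replicate reference samples are merged before comparison: a call
failed in one replicate is imputed from the other, and discordant
non-failed calls raise a warning with the first replicate kept.
Seed-stock comparisons (`compareSamples()`) classify each SNP as
identical (homozygous or heterozygous), heterozygous in one sample
only, discordant homozygous, or discordant heterozygous;
`findDiscordantClusters()` reports maximal runs of discordant SNPs of
at least `minRun` SNPs (default 5 — the notion of "cluster" has no
standard quantitative definition, so the floor is explicit and
configurable).

## Genomic-distribution statistics

`testUniformAmongChromosomes()` tests SNP counts against physical
chromosome lengths with both the Pearson chi-square and the
likelihood-ratio G statistic on k−1 df. To localize which chromosomes
drive a rejection we decompose the overall test into k−1 orthogonal
1-df components by *sequential pooling* in ascending chromosome order:
component i tests chromosome i against the pooled chromosomes i+1..k,
with expectations renormalized to the pooled total. The G components
sum to the overall G exactly (to floating-point precision; asserted at
1e-9 in the suite), which is why G is the primary decomposition
statistic and Pearson components are reported only for reference. The
pooling order is a convention; a decomposition is reported per class
either way. Note one terminological wrinkle: a k-class test has k−1 df
and we produce k−1 components, i.e. "df" components, not "df − 1".

`testPmIndependence()` runs the overall 2×k independence test of
polymorphic/monomorphic counts by chromosome and one 2×2 test per
chromosome (that chromosome against the pooled rest), with the
direction of the PM-ratio deviation. Per-chromosome flags use plain
α = 0.05 — that choice reproduces the published per-chromosome
significance pattern from the printed table, and the p-values are far
from the boundary in every flagged case.

`scanBins()` divides each chromosome into complete fixed-width bins
(default 10 Mbp), drops SNPs in the incomplete terminal bin, tests
each bin against the remainder of its chromosome (1-df Pearson by
default; exact binomial as an option for sparse bins) and applies
Benjamini–Hochberg FDR control across all complete bins genome-wide
(one family; a per-chromosome family is available but non-default,
since the published count of significant bins treats the 200 bins as
one family). `summarizeTeloCentro()` summarizes where significant bins
fall: the telomeric set is the first and last five complete bins per
chromosome, the centromeric set the five bins centered on the
centromere-containing bin. `gapStatistics()` reports adjacent-gap
statistics with a nearest-rank 95th percentile
(`ceil(0.95 n)`) — deterministic, no interpolation ambiguity.

## Parent-of-origin encoding and trio checks

At every retained SNP polymorphic between the parents, calls map to
`BB` (parent-A homozygote), `HH` (parent-B homozygote), `BH` (the
parental heterozygote) or `FAIL`; any other allele combination is a
contract violation, since filter 6 should have removed it, and raises
an error naming SNP and sample. Heterozygous-parent SNPs never reach
encoding (filter 4), so trio inconsistencies of the het-parent type
can only arise when the trio is scored on NIL genotypes that carry
residual heterozygosity — which is exactly the interesting case, and
why `trioConsistency()` takes encoded NIL samples rather than founder
samples. Scored SNPs (called in all three samples) are *consistent*
when both parents are homozygous and the child carries the forced
genotype; the rest fall into four classes: child heterozygous with one
(case 1) or both (case 2) parents heterozygous, child homozygous with
contrasting homozygous parents (case 3, Mendelian-impossible), and
child homozygous with a heterozygous parent (case 4, expected when a
bulked DNA sample happens to be fixed). Case-3 SNPs inside a run of at
least `flagRunLength` (default 20) consistent SNPs are flagged as
probable child mis-calls — advisory only, never corrected, because the
evidence is circumstantial.

## Isogenicity, blocks, drag

`comparePair()` scores each polymorphic SNP isogenic (identical
non-failed codes), non-isogenic (with the genotype contrast, e.g.
`BB/HH` or `BB/BH`), or unknown (failed in either line).
`segmentBlocks()` builds maximal runs of non-isogenic SNPs per
chromosome. Unknown SNPs are transparent — they neither break a run
nor count toward its SNP total — because call failures are technical
and breaking blocks on them would fragment the summary statistics
unpredictably. An isogenic gap of at most `gapTolerance` SNPs
(default 0) does not break a run; the tolerance is per gap. Blocks
below `minSnps` (default 1, i.e. nothing suppressed) are flagged as
singletons rather than dropped, since isolated discordant SNPs carry
information about call quality. Contrast changes inside a block are
kept as sub-blocks. Block span is measured first-SNP to last-SNP; the
unobserved extension beyond the terminal SNPs is not imputed, so
reported spans are conservative by up to one marker gap per edge.

`pairBlockStatistics()` produces per-chromosome block count (NB), SNP
count (NS), total span (TS, Mbp) and chromosome fraction (CF), with
totals excluding the QTL chromosome as primary (the designed
introgression is not "residual" non-isogenicity) and including it as
the parenthetical convention; GF excluding uses the genome length
minus the QTL chromosome. When a QTL region is supplied, blocks on its
chromosome are intersected with the complement of the region, so a
drag block spanning the region splits into its flanking pieces.

`verifyQtlIntrogression()` demands `BB`/`HH` at every scored in-region
SNP and reports isogenic sub-segments of two or more consecutive
shared-genotype SNPs. `measureLinkageDrag()` extends outward from each
flank over QTL-concordant non-isogenic SNPs; further concordant blocks
within `joinGapMbp` (default 25 Mbp, sized to bridge the kind of
interrupted drag seen a few tens of Mbp from a flank) can be joined,
but joined extents are always reported separately from the contiguous
measure.

## The simulator

`runBreedingScheme()` forward-simulates the introgression program: an
F1 of two fully homozygous founders is selfed three times with MAS to
a residual heterozygous line (RHL-F4:5, heterozygous at the target
QTL), and independently selfed ten generations by single-seed descent
to the recurrent RIL; the RHL is then pseudo-backcrossed and
backcrossed to the RIL with MAS, selfed once with MAS, and the final
selfing fixes two sibling lines with contrasting homozygous genotypes
across the whole region.

Design choices that matter:

* **Crossovers** are Haldane: count per chromosome Poisson with mean
  the map length in Morgans, positions uniform on the genetic map, no
  interference. This is the simplest defensible model and has a
  closed-form two-point oracle, `r = (1 − e^{−2d})/2`, against which
  meiosis is tested. Interference would shift block-length
  distributions slightly but not the marker-level contracts.
* **Genomes are segment arithmetic**, not per-SNP vectors: a haplotype
  is a list of founder-origin segments, so meiosis costs O(crossovers)
  and true non-isogenic intervals between the final pair are exact in
  bp — the recovery benchmark compares marker-delimited blocks against
  breakpoint-exact truth.
* **MAS keeps intact heterozygotes.** Selection at the two flanking
  markers also requires both introgression haplotypes unbroken across
  the region; individuals carrying an interior recombination (double
  recombinants, invisible to two flanking markers alone) are
  discarded. This matches the genotype the scheme is designed to
  carry forward (the designed QTL genotypes presume no double
  recombination between the flanks) and guarantees the final fixation
  step can succeed. The recurrent RIL is likewise
  re-drawn until homozygous and non-recombinant across the region,
  the configuration under which flanking-marker MAS is coherent.
* **Selection mechanics**: first qualifying individual per brood
  (default 20), up to 50 broods, then a simulation error naming the
  failing generation. Brood sizes and selection intensities of the
  real program are unpublished; these are free parameters, not
  estimates.
* **Defaults are the study conditions**: ten chromosomes totalling
  2,046.5 Mbp; 50,000 panel SNPs, 35% polymorphic between the
  founders; telomere-enriched marker density (Beta(1/2, 1/2)
  positions, matching the gene-targeted design of maize chips); a
  linear genetic map at 0.7 cM/Mbp (≈1,433 cM genome-wide, a realistic
  maize total); per-call failure rate 0.0086 as observed in NIL
  samples; allele-call error rate 0.0005 with a 50/50 split between
  heterozygous and opposite-homozygous mis-calls (plausible chip
  behavior; the error model is plumbing, not an estimate). The
  chromosome-5 centromere is the annotated 101.3–108.4 Mbp interval;
  the other centromere placements are synthetic representative values
  and are labelled as such.
* **One master seed**; every stage derives its own stream via
  `deriveSeed()`, so stages are independently reproducible.

What the generator does **not** emulate: crossover interference, gene
conversion, segregation distortion, structural variation and CNV,
ascertainment bias of chip content toward particular germplasm, and
spatially correlated call failures. Passing the recovery benchmarks
therefore shows the pipeline is correct for well-behaved biallelic
markers under clean inheritance; it does not certify behavior under
structural variation or cluster-level calling artifacts.

## Numerical and formatting conventions

Coordinates are 1-based inclusive internally; BED export converts to
0-based half-open. Call tokens are unordered pairs canonicalized
alphabetically on input. Report percentages round half away from zero
to one decimal; span/fraction values below 1 print with two
significant figures so small entries (e.g. `0.15` Mbp, `0.09%`)
survive rounding. Uniform ("evenly spaced") panels place markers at
`round(seq(1, L, length.out = n))`, clamped inside the chromosome.
Unmapped panel SNPs inherit as if linked to the start of chromosome 1;
they exist only to exercise the unmapped-SNP filter path and never
reach analysis. QTL interval lengths are computed from flanking
positions, never taken from printed summaries (for one published
region the printed length, 57.66 Mbp, disagrees with its printed
positions, which give 57.63 Mbp).

## Validation strategy and problem sizes

The test suite validates each stage against an independent oracle:
meiosis against Poisson/Haldane closed forms (10,000 gametes);
selfing against the (1/2)^g heterozygosity decay (1,000 MAS-selected
lineages, 3 SE band); segmentation against a brute-force per-SNP walk
(1,000 random vectors); BH decisions against the literal step-up
definition (1,000 random p-vectors); the G decomposition against
longhand pooling (1,000 random inputs, 1e-9); the six filters against
independently coded predicates (100 random fixtures plus one
engineered 57,838-SNP fixture reproducing published per-step
exclusion counts); and the full pipeline against simulator ground
truth (20 replicates at the default 50k-SNP genome, requiring ≥95%
of true non-isogenic bases recovered, no block outside truth ± one
marker gap, and a passing QTL check in every replicate; observed
recovery is ≈98%, limited by the unobserved span between a true
breakpoint and the nearest polymorphic marker). These sizes keep the
whole suite under a few minutes while leaving all Monte-Carlo bands
comfortably tight.

## Known limitations

* Block spans are marker-delimited; with the default ≈117 kbp mean
  polymorphic spacing, each block edge is conservative by half a gap
  on average, and true intervals narrower than the local marker
  spacing are invisible.
* The NB/NS counting conventions (singleton handling, heterozygous
  boundaries, sub-blocks) are explicit parameters; other reasonable
  conventions would shift block counts by small integers.
* The trio operation scores a single cross individual; "sampling
  effect" heterozygosity of bulked DNA is visible as case-4 calls but
  no correction is attempted.
* The advisory mis-call flag depends on run length only; it does not
  model per-SNP error rates.
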