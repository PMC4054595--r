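---
title: "Permutation segmentation of tiling signal and macroRNA detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Permutation segmentation of tiling signal and macroRNA detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

tilestair detects pathway-controlled transcription in tiling-array-style
probe signal and aggregates the resulting fragments into macroRNA
candidates — very long (at least 10^4 nt), apparently continuously
transcribed regions of the kind seen downstream of STAT3, p53 and
cell-cycle activation. This vignette explains the models and procedures
the package implements, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the design
decisions taken where the published procedure leaves room.

## Window segmentation against a GC-binned permutation null

The platform reports one log2 intensity per 25-nt probe, tiled every
35 nt outside repeat-masked regions. Expression is assessed in 200-nt
windows: one window is anchored at each probe start, and a window's
members are the probes whose start lies inside it. Windows with fewer
than three members are not evaluated — the expression score (the
arithmetic mean after discarding exactly one maximal and one minimal
member value) is undefined below three probes, and such windows carry
almost no information anyway. Probe-anchored placement is our
discretization of "overlapping sliding windows": it puts a window
wherever data exist and makes per-probe permutation natural.

The null model permutes probe values across the whole probe set, but
only within GC-content bins (four quantile classes by default,
assigned by stable rank so ties split deterministically). Probe
affinity rises with GC content; if high-GC probes cluster in the
genome, an unbinned null mistakes affinity structure for transcription.
The suite contains a regression test in which GC-rich blocks plus a
strong affinity coefficient produce false calls under a one-bin null
and not under a four-bin null.

All window scores from all permutations are pooled into one null
sample. A pooled null reaches p-value resolution of
1/(permutations × windows) rather than 1/permutations, which is what
makes genome-scale runs affordable; the cost is that windows of
different probe counts share a null. Empirical p-values use the +1
pseudocount, `p = (1 + #{null >= obs}) / (1 + #null)`, never zero.
Significance is Benjamini–Hochberg-adjusted over all evaluated windows
(`q < 0.05` for expression). Significant windows overlapping by at
least one nucleotide are merged into TARs; bookended windows are not
merged, here and in every interval-merging step of the package.

Differential analysis scores per-probe intensity differences between
two conditions. Sequence effects cancel in the difference, so a single
GC class is the default, and the tail is two-sided on |score|. The
window direction is the sign of the summed differences (a zero-sum tie
breaks, arbitrarily but deterministically, to "up"); probes opposing
that direction are discarded and the score is the signed mean of the
rest. We read "converse behavior" relative to the window's own net
sign; the alternative reading (relative to the expression change of
the surrounding H interval) would need only a different direction
input to the same discard rule. Differential windows are eligible only
if they overlap an H interval — a significantly expressed region of at
least one contrasted condition — and the BH adjustment runs over the
eligible windows (`q < 0.005`). This eligibility restriction is not
cosmetic: it is what gives the differential test its power, because
the pooled difference null has a heavy tail (a shuffled window that
captures a single strongly differential probe and discards its
opposing companions scores as high as a genuinely differential
window), and restricting the multiple-testing burden to expressed
space compensates exactly where signal can exist.

`permutation_null()` materializes the pooled null for audit;
`permutation_test()` computes identical p-values in streaming form
(per-permutation exceedance counts against the sorted observed scores),
so 10^5-permutation runs need memory proportional to the number of
windows. The equivalence of the two routes is tested, as is agreement
with exhaustive enumeration of all probe orderings on small arrays.

## Bona fide non-coding filtering

Detected segments are reduced to bona fide non-coding intervals in
four fixed steps: (i) subtract nucleotides of known protein-coding and
pseudogene exons (UTRs included); (ii) subtract predicted
protein-coding segments (precomputed, P < 0.05); (iii) among
nucleotides the coding-potential screen could not evaluate — alignment
depth limits such screens — subtract protein-similarity hits
(e < 0.05); (iv) discard leftovers shorter than 17 nt, the size of the
smallest known human ncRNA species. Step (iii) is deliberately limited
to the unevaluated space: where the screen ran and found nothing,
similarity hits are not subtracted. The evidence layers arrive as BED
files; an explicitly empty layer is legal (the synthetic pipeline runs
with empty layers), a missing one is an error naming the layer.

Survivors are classified against protein-coding gene bodies:
intergenic (no overlap), intronic (fully inside, no coding-exon
overlap), otherwise exon-overlapping. Boundary straddlers with no exon
contact take the class covering the majority of their nucleotides,
ties going to intronic. The filter is shrinking and idempotent; both
properties are tested on randomized inputs.

## stairFinder

A macroRNA appears in tiling data not as one segment but as a dense
run of short segments broken by repeats and signal dropouts. Simple
gap-merging reproduces the same fragmentation at a coarser scale, so
stairFinder instead estimates a segment density: each segment
contributes a biweight kernel, K(u) = (15/16)(1 − u²)² for |u| ≤ 1,
placed at its center and weighted by its length, with bandwidth h
(default 100,000 nt, the value that best matched known annotation in
the original tuning). No 1/h normalization is applied because the
flooding step only uses density levels relative to the local peak. The
density is evaluated on a per-chromosome grid with step h/100 (1 kb at
the default bandwidth) — flooding tolerance is far below the boundary
precision of interest, and grid evaluation keeps the estimator linear
in data size.

Each strict local maximum of the gridded density (plateaus report
their midpoint) is flooded: between its flanking minima, the region
keeps the leftmost through rightmost grid positions whose density is
at least `level × peak`. Level 0 returns the flanking minima; level 1
collapses onto the peak; boundaries are nested monotonically in the
level. The default level is 0.5. Overlapping flooded regions are
combined, and each segment is assigned to the region containing its
center.

The published description names "coverage and silhouette" without
formulas; our concrete instantiation, isolated in `merge_and_score()`,
is: silhouette per segment s = (b − a)/max(a, b) with a the distance
from the segment center to its own region's midpoint and b the
distance to the nearest other region's midpoint (1 if no other region
exists), region silhouette the mean over members, and score =
covered nucleotides × max(silhouette, 0). The score therefore has
nucleotide units, and the curation threshold of 10,000 is commensurate
with the 10^4-nt macroRNA length bound. Regions are categorized by a
total cascade — P (matches a coding gene TSS-to-terminus within a
5,000-nt tolerance, our choice where the procedure is silent), ES
(TSS match, ends inside the gene), I (fully intronic), E (touches a
coding exon), EN (non-coding exons only), IG (else) — so partial,
exon-free gene-body straddlers fall through to IG.

## Overlap enrichment

The observed nucleotide overlap of a query set with an annotation is
compared to N = 100 background lists reproducing the query's interval
length multiset inside a sampling space (whole genome, or intergenic /
intronic space for queries restricted to those), excluding assembly
gaps and repeats. We place each background interval by direct weighted
sampling — uniform over all feasible placements in the
exclusion-subtracted space — rather than capped rejection sampling of
uniform starts; the target distribution is the same and the sampler
cannot stall, while a length that fits nowhere still raises an error
naming the length. Odds are overlap over non-overlap nucleotides;
the odds ratio divides observed odds by the mean background odds
(means taken cell-wise over the N lists); a zero in any of the four
cells engages the Haldane–Anscombe +0.5 correction with a flag.
Significance comes from `stats::fisher.test` on the rounded pooled
2×2 table (two-sided; conditional-MLE confidence interval), with
stars at p < 0.05 / 0.01 / 0.001 and no correction across annotation
sets. The suite cross-checks the p-values against an independent
hypergeometric enumeration for every table with total at most 40.

A caveat the tests make explicit: Fisher's test on nucleotide counts
treats nucleotides as independent. For interval-scale annotations the
counts are autocorrelated and the test is anti-conservative; the null
calibration test therefore uses point features, where the binomial
approximation is honest. Interpretation of stars on real interval
annotations should lean on the odds ratio and CI, not the raw p.

## Cross-platform validation and pairing

With an independent reference platform whose probes carry differential
flags, the tiling calls are swept over q in [10⁻⁴, 1] (20 log-spaced
points): TP and FP are the significant tiling nucleotides under
flagged and unflagged reference probes, P and N the flagged and
unflagged reference nucleotides, giving sensitivity TP/P, specificity
1 − FP/N and FDR = FP/(FP + TP). Nucleotides under no reference probe
are ignored; conflicts under overlapping probes resolve to flagged
(sensitivity-favoring, documented). Sensitivity is non-decreasing and
specificity non-increasing in q on any input — an invariant the suite
asserts — and with an error-free synthetic reference the curve equals
the generator's own truth accounting exactly.

The 3' decay profile maps each probe inside an oriented segment to a
relative coordinate in [0, 1] from the 5' anchor (minus-strand
segments mirrored) and averages z-scores per bin; continuously
transcribed regions decay towards 3', spliced multi-exon genes do not.

Proximal pairing matches each differential non-coding probe to the
nearest protein-coding gene regardless of strand (distance 0 when
overlapping; equidistant ties break to the probe's 5' side, an
arbitrary documented choice). A pair is retained only if the gene is
differential with an internally consistent exon fold-change sign, the
two lie on the same strand, and their directions oppose; every
different-strand pair in which both members change significantly is
excluded. That last rule is implemented literally as printed even
though it sits oddly beside strand-blind partner selection; a
documented switch (`antisense_policy = "retain_overlapping"`) offers
the plausible alternative of keeping antisense overlapping pairs, and
the literal rule stays the default.

## The synthetic-data generator

All tests and the acceptance script run on generated data with known
truth. The generator emulates: tiled probe layouts with repeat-masked
and assembly-gap holes (probes touching a mask are absent, as in real
designs); GC-dependent probe affinity, linear in a Beta(10,10) GC
fraction — the simplest confounder that makes GC binning consequential;
planted multi-exon coding genes and lncRNAs; expressed and
differential segments as additive log2 amplitudes; and macroRNAs with
a common start site, extent limited by elapsed time × polymerase speed
(the 80–275 kb/h range of polymerase II motivates the defaults; a
condition's elapsed induction time is configurable, `Inf` meaning
permanent induction and 0 meaning uninduced), and linear 3' signal
decay `amplitude × max(0, 1 − decay × distance_kb)`.

Defaults are 25-nt probes every 35 nt, baseline 6.0 log2 units, noise
sd 0.5, planted amplitude 3.0 (six noise sds), two conditions, and
scenario genomes of 1–8 Mb carrying roughly 1% expressed and at most
~1.5% differential sequence. The density matters: the pooled
difference null's tail scales with the genome-wide fraction of
strongly differential probes, so scenarios much denser than a real
survey (where differential nucleotides are well under 1% of probed
space) rob the q < 0.005 call of power. Our scenario sizes were chosen
to mirror that sparsity, and they keep the full suite in minutes on a
single core.

What the generator does not emulate — and what passing tests therefore
do not establish about real data: raw-intensity distributions (the
Gaussian-on-log2 choice is a stand-in, isolated in
`simulate_intensities()` for replacement), PM/MM probe pairs, spatial
array artifacts, cross-hybridization beyond the GC term,
quantile-normalization effects between arrays, replicate structure,
and any sequence-level realism (GC arrives precomputed; there is no
FASTA handling anywhere).

## Numerical choices and degenerate inputs

Coordinates are 0-based half-open everywhere internally and in BED
output; GFF3 converts on read. Empirical p-values never reach zero by
construction. Degenerate permutation nulls (constant signal, a window
spanning the whole array) are point masses and yield p = 1. Fully
tied GC vectors bin by stable rank. In `fisher_overlap_test`, a zero
row or column short-circuits to p = 1 with an undefined CI rather than
calling the exact test. Empty interval tables are legal inputs to
every interval operation and to the filter's evidence layers. The
pipeline driver validates every configuration parameter against its
domain before any stage runs, fans per-stage seeds out of one global
seed (`seed + stage index`) so stages can be rerun independently, and
treats run directories as write-once.

## Known limitations

The silhouette and score formulas are one concrete reading of a
verbally described measure; rankings are comparable within this
package only. The pooled null trades per-window exactness for
resolution; per-window nulls at 10^4 permutations would be hopelessly
coarse, but extremely heterogeneous window sizes could still distort
pooled p-values. Fisher p-values on interval-scale annotations are
anti-conservative (see above). Strand is carried but ignored
everywhere except proximal pairing, reflecting an unstranded platform.
The category cascade trusts annotation TSS/termini within a fixed
tolerance and does not attempt transcript assembly.
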