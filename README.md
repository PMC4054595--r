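# tilestair

Pathway activation (STAT3, p53, cell-cycle re-entry) triggers
transcription far outside annotated genes, including *macroRNAs*: very
long (≥ 10⁴ nt), apparently continuous transcripts that tiling
platforms report only as dense runs of short significant fragments.
tilestair is an R package for the computational side of such surveys:
it segments probe-level tiling signal into significantly expressed and
differentially expressed regions, strips them down to bona fide
non-coding intervals, aggregates fragment accumulations into macroRNA
candidates, and quantifies annotation overlaps and cross-platform
error rates. A synthetic-data generator with planted ground truth
makes every stage testable end to end without any external data.

## Methods at a glance

* **Segmentation.** 200-nt windows anchored at probe starts are scored
  by a min/max-trimmed mean (expression) or by the mean per-probe
  log-fold-change after discarding converse probes (differential,
  signed). Significance is empirical against a pooled permutation null
  in which probe values are shuffled only within GC-content bins
  (4 classes for expression, 1 for differences),
  `p = (1 + #{null ≥ obs}) / (1 + #null)`, Benjamini–Hochberg adjusted
  (q < 0.05 for TARs, q < 0.005 for DE-TARs). Differential windows are
  eligible only inside *H intervals* — regions expressed in at least
  one contrasted condition.
* **Bona fide non-coding filter.** Subtract coding/pseudogene exons,
  then predicted coding segments (RNAcode-style, precomputed), then
  protein-similarity hits where coding potential was unassessable,
  then drop intervals < 17 nt; classify survivors intergenic/intronic.
* **stairFinder.** Segment density
  `f(x) = Σᵢ lengthᵢ · K((x − centerᵢ)/h)` with the biweight kernel
  `K(u) = (15/16)(1 − u²)²`, bandwidth h = 100 kb; each density peak is
  flooded between its flanking minima down to `level × peak`
  (level = 0.5), overlapping regions merge, and each region gets
  score = covered nt × max(mean silhouette, 0) plus a genomic category
  (IG / E / EN / I / ES / P).
* **Enrichment.** Observed versus N = 100 randomized background lists
  with the query's length multiset, placed uniformly in the sampling
  space minus gaps and repeats;
  `OR = [ov/(n−ov)] / [mean(ov_bg)/mean(n_bg−ov_bg)]`, Fisher's exact
  test with 95% CI and significance stars.
* **Validation.** Against a reference platform: sensitivity TP/P,
  specificity 1 − FP/N, FDR = FP/(FP+TP) over a q sweep in [10⁻⁴, 1];
  3′ z-score decay profiles along oriented transcripts; proximal
  ncRNA–mRNA pairing under strand/direction retention rules.

## Worked example

The numbered scripts under `analysis/` run a complete survey on an
8-Mb synthetic genome with 13 planted expressed segments, 5
differential segments and one permanently induced 100-kb macroRNA
(amplitude 3.5 log2 units, 3′ decay, repeat-masked holes):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_segment.R
Rscript analysis/03_filter_noncoding.R
Rscript analysis/04_stairfinder.R
Rscript analysis/05_enrichment.R
Rscript analysis/06_validation.R
```

which prints, stage by stage:

```
probes: 192177 (25 nt every 35 nt outside the mask)
condition A: 20 TARs covering 51 kb (sensitivity 0.998, FDR 0.055)
condition B: 31 TARs covering 119 kb (sensitivity 0.996, FDR 0.017)
contrast B-A: 53 DE-TARs covering 110 kb (sensitivity 0.939, FDR 0.004)
bona fide non-coding: 100.0% of DE-TAR nucleotides survive
4 regions (4 macroRNA-sized); top: chr2:988000-1107000 score 79365 category IG
planted macroRNA chr2:1000000-1100000; boundary errors 12000 / 7000 nt (bandwidth 100000)
reference platform at q~0.0048: sensitivity 0.230, specificity 0.9990, FDR 0.056
macroRNA z-score decay: first bin 5.37 -> last bin 3.40
```

Sensitivity and FDR are nucleotide-level against the planted truth,
masked for repeat/gap space the platform cannot see. The top
stairFinder region recovers the planted macroRNA within a fraction of
the 100-kb bandwidth and is correctly categorized intergenic; the
reference-platform sensitivity of 0.23 reflects the 5% flag error
planted in that reference (scattered false flags that the tiling
analysis rightly declines to call), while its FDR estimate for the
tiling calls at q ≈ 0.005 is 0.056. Stage outputs (BED/TSV) land in
`results/`. `run_pipeline(default_config(seed))` runs the same chain
as one orchestrated, manifest-checksummed unit on a smaller scenario.

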