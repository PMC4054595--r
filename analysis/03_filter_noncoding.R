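# Reduce DE-TARs to bona fide non-coding intervals: subtract coding and
# pseudogene exons, predicted coding segments and protein-similarity
# hits (here: the synthetic genome's coding exons; the precomputed
# evidence layers are empty), drop leftovers under 17 nt, and classify
# the survivors as intergenic or intronic.

source(file.path("analysis", "00_scenario.R"))

sc <- study_scenario()
de <- read_bed(file.path(RESULTS_DIR, "de_tars.bed"))

evidence <- coding_evidence(
  coding_exons = coding_exons_of(sc$genome$annotation),
  pseudogene_exons = intervals(character(), numeric(), numeric()),
  rnacode_hits = intervals(character(), numeric(), numeric()),
  rnacode_covered = intervals(character(), numeric(), numeric()),
  tblastn_hits = intervals(character(), numeric(), numeric()))

bf <- bona_fide_filter(de, evidence, sc$genome$annotation, min_len = 17)
for (cls in c("intergenic", "intronic", "exon-overlapping")) {
  sub <- bf[bf$class == cls, , drop = FALSE]
  message(sprintf("%-16s %3d intervals, %7.0f nt", cls, nrow(sub),
                  if (nrow(sub)) sum(sub$end - sub$start) else 0))
}
message(sprintf("bona fide non-coding: %.1f%% of DE-TAR nucleotides survive",
                100 * covered_nucleotides(bf[, c("chrom", "start", "end")]) /
                  max(1, covered_nucleotides(de))))
write_bed(intervals(bf$chrom, bf$start, bf$end, name = bf$class),
          file.path(RESULTS_DIR, "bona_fide_noncoding.bed"))
message("wrote results/bona_fide_noncoding.bed")
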