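# Build the synthetic study: genome, tiled probes, planted truth and
# per-condition probe intensities. Writes the probe table and the truth
# tables that every later stage is judged against.

source(file.path("analysis", "00_scenario.R"))

sc <- study_scenario()

message(sprintf("genome: %d chromosomes, %.1f Mb, %d genes (%d coding), %.0f kb repeat-masked",
                length(sc$genome$chrom_sizes),
                sum(sc$genome$chrom_sizes) / 1e6,
                nrow(sc$genome$annotation$genes),
                sum(sc$genome$annotation$genes$coding),
                covered_nucleotides(sc$genome$annotation$repeats) / 1e3))
message(sprintf("probes: %d (25 nt every 35 nt outside the mask)",
                nrow(sc$probes)))
message(sprintf("truth: %d expressed segments, %d differential, %d macroRNA of %.0f kb",
                nrow(sc$truth$expressed), nrow(sc$truth$differential),
                nrow(sc$truth$macro), sc$truth$macro$length / 1e3))

write.table(sc$probes, file.path(RESULTS_DIR, "probes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
td <- sc$truth$differential
write_bed(intervals(td$chrom, td$start, td$end, name = td$contrast,
                    score = abs(td$effect)),
          file.path(RESULTS_DIR, "truth_differential.bed"))
te <- sc$truth$expressed
write_bed(intervals(te$chrom, te$start, te$end, name = te$condition,
                    score = te$amplitude),
          file.path(RESULTS_DIR, "truth_expressed.bed"))
message("wrote results/probes.tsv, results/truth_*.bed")
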