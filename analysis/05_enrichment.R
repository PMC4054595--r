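# Annotation-overlap enrichment of the DE-TARs against randomized
# backgrounds that preserve the DE-TAR length distribution and avoid
# repeats and assembly gaps (N = 100 lists); odds ratios with 95% CI
# and two-sided Fisher tests.

source(file.path("analysis", "00_scenario.R"))

sc <- study_scenario()
de <- read_bed(file.path(RESULTS_DIR, "de_tars.bed"))
ann <- sc$genome$annotation

space <- do.call(rbind, lapply(names(sc$genome$chrom_sizes), function(ch)
  intervals(ch, 0, sc$genome$chrom_sizes[[ch]])))
annotations <- list(
  coding_exons = coding_exons_of(ann),
  noncoding_exons = noncoding_exons_of(ann),
  gene_bodies = ann$genes[, c("chrom", "start", "end")],
  truth_differential = sc$truth$differential[, c("chrom", "start", "end")])

rep_ <- enrichment_report(de, annotations, space,
                          exclusions = rbind(ann$repeats, ann$gaps),
                          n_lists = 100, seed = SCENARIO_SEED + 20)
print(rep_[, c("annotation", "ov_obs", "ov_bg_mean", "odds_ratio",
               "log2_or", "p", "stars")], digits = 3)
write.table(rep_, file.path(RESULTS_DIR, "enrichment.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("wrote results/enrichment.tsv")
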