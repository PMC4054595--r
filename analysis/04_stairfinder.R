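# Detect macroRNA-like accumulations of DE-segments with stairFinder:
# length-weighted biweight kernel density (bandwidth 100 kb), peak
# flooding at 50% of the local peak, merging, coverage x silhouette
# scoring and genomic categorization.

source(file.path("analysis", "00_scenario.R"))

sc <- study_scenario()
de <- read_bed(file.path(RESULTS_DIR, "de_tars.bed"))

macro <- stairfinder(de, bandwidth = 1e5, level = 0.5,
                     annotation = sc$genome$annotation)
write.table(macro, file.path(RESULTS_DIR, "macro_regions.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

top <- macro[1, ]
message(sprintf("%d regions (%d macroRNA-sized); top: %s:%.0f-%.0f score %.0f category %s",
                nrow(macro), sum(macro$macro_sized), top$chrom, top$start,
                top$end, top$score, top$category))
mt <- sc$truth$macro
message(sprintf("planted macroRNA %s:%.0f-%.0f; boundary errors %.0f / %.0f nt (bandwidth 100000)",
                mt$chrom, mt$start_site, mt$start_site + mt$length,
                abs(top$start - mt$start_site),
                abs(top$end - (mt$start_site + mt$length))))
message("wrote results/macro_regions.tsv")
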