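# Shared study scenario for the numbered analysis drivers.
#
# An 8-Mb two-chromosome synthetic genome carrying coding genes, lncRNAs,
# a repeat mask and assembly gaps; eight planted expressed segments
# (amplitude 3.0 log2 units over a 0.5-sd noise floor, half of them
# differential between conditions A and B) and one 100-kb macroRNA
# induced in condition B with 3' signal decay. Everything derives from
# SCENARIO_SEED, so each driver can rebuild the same inputs.

library(tilestair)

SCENARIO_SEED <- 20260924L
RESULTS_DIR <- file.path("results")
dir.create(RESULTS_DIR, recursive = TRUE, showWarnings = FALSE)

study_scenario <- function(seed = SCENARIO_SEED) {
  genome <- generate_genome(c(chr1 = 2e6, chr2 = 6e6), n_genes = 20,
                            mean_gene_span = 12000, seed = seed)
  probes <- generate_probes(genome, seed = seed + 1)
  truth <- random_truth(genome, c("A", "B"), n_segments = 8,
                        frac_differential = 0.5,
                        len_range = c(5000, 9000), amplitude = 3.0,
                        seed = seed + 2)
  ## a permanently induced 100-kb macroRNA on chr2, decaying 3'-wards
  macro <- data.frame(chrom = "chr2", start_site = 1e6, length = 1e5,
                      strand = "+", speed_kb_h = 80, decay_per_kb = 0.004,
                      amplitude = 3.5)
  ## the macro interval is expressed in B (through the macro term, so
  ## the bookkeeping amplitude is 0) and differential for the contrast
  expressed <- rbind(truth$expressed,
                     data.frame(condition = "B", chrom = "chr2",
                                start = 1e6, end = 1.1e6, amplitude = 0))
  differential <- rbind(truth$differential,
                        data.frame(contrast = "B-A", condition_a = "A",
                                   condition_b = "B", chrom = "chr2",
                                   start = 1e6, end = 1.1e6, effect = 3.5))
  truth <- truth_set(expressed = expressed, differential = differential,
                     macro = macro)
  conds <- data.frame(condition = c("A", "B"), time_h = c(0, Inf))
  probes <- simulate_intensities(probes, truth, conds, baseline = 6,
                                 noise_sd = 0.5, gc_effect = 1,
                                 seed = seed + 3)
  list(genome = genome, probes = probes, truth = truth,
       conditions = conds,
       mask = rbind(genome$annotation$repeats, genome$annotation$gaps))
}
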