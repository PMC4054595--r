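test_that("genome generation is deterministic and honors the repeat fraction", {
  g1 <- generate_genome(c(chr1 = 2e5), seed = 1)
  g2 <- generate_genome(c(chr1 = 2e5), seed = 1)
  expect_identical(g1$annotation$genes, g2$annotation$genes)
  expect_identical(g1$annotation$repeats, g2$annotation$repeats)

  g0 <- generate_genome(c(chr1 = 2e5), repeat_fraction = 0, seed = 1)
  expect_equal(nrow(g0$annotation$repeats), 0L)
})

test_that("infeasible gene configurations error out", {
  expect_error(generate_genome(c(chr1 = 1e6), n_genes = 10,
                               mean_gene_span = 2e5, n_lncrnas = 0),
               "infeasible")
})

test_that("probe tiling matches direct construction", {
  ## 10-kb repeat-free chromosome, 25-nt probes every 35 nt: the starts
  ## are 0, 35, ..., the largest multiple of 35 with start + 25 <= 10000
  g <- generate_genome(c(chr1 = 1e4), n_genes = 1, mean_gene_span = 2000,
                       n_lncrnas = 0, repeat_fraction = 0,
                       gap_fraction = 0, seed = 1)
  p <- generate_probes(g, probe_length = 25, spacing = 35, seed = 1)
  expected_starts <- seq(0, 1e4 - 25, by = 35)
  expect_equal(p$start, expected_starts)
  expect_equal(nrow(p), length(expected_starts))
})

test_that("fully masked chromosomes yield no probes and gc is reproducible", {
  g <- generate_genome(c(chr1 = 1e4), n_genes = 1, mean_gene_span = 2000,
                       n_lncrnas = 0, repeat_fraction = 0,
                       gap_fraction = 0, seed = 1)
  g$annotation$repeats <- intervals("chr1", 0, 1e4)
  expect_equal(nrow(generate_probes(g, seed = 1)), 0L)

  g$annotation$repeats <- tilestair:::empty_intervals()
  p1 <- generate_probes(g, seed = 3)
  p2 <- generate_probes(g, seed = 3)
  expect_identical(p1$gc, p2$gc)
})

test_that("truth sets enforce their invariants", {
  ex <- data.frame(condition = "A", chrom = "chr1", start = 0, end = 1000,
                   amplitude = 2)
  bad_diff <- data.frame(contrast = "B-A", condition_a = "A",
                         condition_b = "B", chrom = "chr1",
                         start = 5000, end = 6000, effect = 2)
  expect_error(truth_set(ex, bad_diff), "not expressed")
  bad_macro <- data.frame(chrom = "chr1", start_site = 0, length = 5000,
                          strand = "+", speed_kb_h = 80,
                          decay_per_kb = 0.01, amplitude = 2)
  expect_error(truth_set(macro = bad_macro), "1e4")
})

test_that("null truth gives iid Gaussian intensities around the baseline", {
  g <- generate_genome(c(chr1 = 2e5), n_genes = 1, mean_gene_span = 2000,
                       n_lncrnas = 0, repeat_fraction = 0, seed = 1)
  p <- generate_probes(g, seed = 2)
  p <- simulate_intensities(p, truth_set(),
                            data.frame(condition = "A", time_h = Inf),
                            baseline = 6, noise_sd = 0.5, gc_effect = 0,
                            seed = 3)
  n <- nrow(p)
  expect_gt(n, 1000)
  expect_lt(abs(mean(p$A) - 6), 4 * 0.5 / sqrt(n))
  expect_lt(abs(sd(p$A) - 0.5), 0.05)
})

test_that("planted amplitude is recovered in the mean signal difference", {
  g <- generate_genome(c(chr1 = 2e5), n_genes = 1, mean_gene_span = 2000,
                       n_lncrnas = 0, repeat_fraction = 0, seed = 1)
  p <- generate_probes(g, seed = 2)
  tr <- truth_set(expressed = data.frame(
    condition = "A", chrom = "chr1", start = 50000, end = 60000,
    amplitude = 3.0))
  p <- simulate_intensities(p, tr, data.frame(condition = "A", time_h = Inf),
                            noise_sd = 0.5, seed = 3)
  inside <- p$start >= 50000 & p$start < 60000
  expect_gt(sum(inside), 200)
  se <- 0.5 * sqrt(1 / sum(inside) + 1 / sum(!inside))
  expect_lt(abs((mean(p$A[inside]) - mean(p$A[!inside])) - 3.0), 3 * se)
})

test_that("macroRNA signal respects polymerase reach and decays 3'-wards", {
  probes <- data.frame(probe_id = sprintf("p%03d", 1:5), chrom = "chr1",
                       start = c(0, 2e4, 5e4, 1e5, 1.5e5), length = 25,
                       gc = 0.5)
  macro <- data.frame(chrom = "chr1", start_site = 0, length = 2e5,
                      strand = "+", speed_kb_h = 80, decay_per_kb = 0.002,
                      amplitude = 4)
  conds <- data.frame(condition = c("one_h", "perm"), time_h = c(1, Inf))
  p <- simulate_intensities(probes, truth_set(macro = macro), conds,
                            baseline = 6, noise_sd = 1e-6, seed = 1)
  ## 1 h at 80 kb/h: polymerase has reached 80 kb, not 100 kb
  expect_gt(p$one_h[3] - 6, 3)            # 50 kb: covered
  expect_lt(abs(p$one_h[4] - 6), 0.01)    # 100 kb: not yet transcribed
  ## permanent induction: covered, and decaying with distance
  expect_gt(p$perm[4] - 6, 2)
  macro_term <- p$perm[1:5] - 6
  expect_true(all(diff(macro_term) <= 1e-6))
})

test_that("reference platform flags equal truth at flip rate 0 and reproduce", {
  g <- generate_genome(c(chr1 = 1e5), n_genes = 1, mean_gene_span = 2000,
                       n_lncrnas = 0, repeat_fraction = 0, seed = 1)
  p <- generate_probes(g, seed = 2)
  tr <- truth_set(
    expressed = data.frame(condition = "B", chrom = "chr1", start = 2e4,
                           end = 3e4, amplitude = 3),
    differential = data.frame(contrast = "B-A", condition_a = "A",
                              condition_b = "B", chrom = "chr1",
                              start = 2e4, end = 3e4, effect = 3))
  ref0 <- generate_reference_platform(tr, "B-A", p, flip_rate = 0, seed = 4)
  expect_identical(ref0$de, ref0$true_de)
  expect_true(any(ref0$de))
  ref1 <- generate_reference_platform(tr, "B-A", p, flip_rate = 0.3, seed = 4)
  ref2 <- generate_reference_platform(tr, "B-A", p, flip_rate = 0.3, seed = 4)
  expect_identical(ref1$de, ref2$de)
})
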