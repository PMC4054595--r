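test_that("non-specific probe filtering applies both criteria", {
  ## negative controls with mean 4, sd 0.2: background 4.6
  neg <- c(3.8, 4.0, 4.2, 4.0)
  bg <- mean(neg) + 3 * sd(neg)
  mat <- rbind(pass = c(5, 6, 7, 5, 3),
               low_iqr = rep(10, 5),
               few = c(5, 5, 5, 3, 3))
  keep <- probe_nonspecific_filter(mat, neg, min_samples = 4, iqr_min = 0.5)
  expect_equal(attr(keep, "background"), bg)
  expect_true(keep[["pass"]])
  expect_false(keep[["low_iqr"]])   # constant probe: IQR 0
  expect_false(keep[["few"]])       # only 3 samples above background
  expect_error(probe_nonspecific_filter(mat, numeric()), "negative-control")
})

test_that("the FDR curve implements the nucleotide-count definitions", {
  ## reference: a 100-nt DE probe at 0-100, a non-DE probe at 100-200;
  ## one significant window covering 20-120
  ref <- data.frame(chrom = "chr1", start = c(0, 100), length = 100,
                    de = c(TRUE, FALSE))
  win <- data.frame(chrom = "chr1", start = 20, end = 120, q = 1e-3)
  vc <- fdr_curve(win, ref, q_grid = c(1e-4, 0.01, 1))
  expect_equal(vc$TP, c(0, 80, 80))
  expect_equal(vc$FP, c(0, 20, 20))
  expect_equal(vc$P, rep(100, 3))
  expect_equal(vc$N, rep(100, 3))
  expect_equal(vc$fdr[2], 0.2)
  expect_equal(vc$sensitivity[2], 0.8)
  expect_equal(vc$specificity[2], 1 - 20 / 100)
  ## FP = 0 gives FDR 0
  win2 <- data.frame(chrom = "chr1", start = 0, end = 100, q = 1e-3)
  expect_equal(fdr_curve(win2, ref, q_grid = 1)$fdr, 0)
  expect_error(fdr_curve(win, ref[0, ]), "empty")
})

test_that("TP + FP equals the significant nucleotides under reference probes", {
  sc <- planted_scenario()
  ref <- generate_reference_platform(
    sc$truth, "B-A",
    data.frame(chrom = sc$probes$chrom, start = sc$probes$start,
               length = sc$probes$length),
    flip_rate = 0.1, seed = 31)
  vc <- fdr_curve(sc$dres$windows, ref)
  ref_iv <- merge_intervals(intervals(ref$chrom, ref$start,
                                      ref$start + ref$length))
  for (i in c(5, 10, 15, 20)) {
    qt <- vc$q[i]
    sig <- sc$dres$windows[!is.na(sc$dres$windows$q) &
                             sc$dres$windows$q < qt, ]
    expect_equal(vc$TP[i] + vc$FP[i],
                 overlap_nucleotides(sig[, c("chrom", "start", "end")],
                                     ref_iv))
  }
})

test_that("decay profiles are flat for constant z and recover planted decay", {
  segs <- intervals("chr1", c(0, 20000), c(10000, 32000), strand = "+")
  probes <- data.frame(chrom = "chr1", start = seq(0, 31999, by = 100))
  probes$z <- 2.5
  prof <- decay_profile(segs, probes, n_bins = 5)
  expect_equal(prof$mean_z, rep(2.5, 5))
  expect_equal(attr(prof, "n_segments"), 2L)
  expect_equal(decay_profile(segs, probes, n_bins = 1)$mean_z, 2.5)

  ## linear 3' decay planted by the generator term
  probes$z <- 3 * pmax(0, 1 - 0.9 * (probes$start %% 20000) / 20000)
  segs2 <- intervals("chr1", 0, 20000, strand = "+")
  prof2 <- decay_profile(segs2, probes, n_bins = 10)
  expect_true(all(diff(prof2$mean_z) < 0))

  ## minus-strand segments are mirrored before binning
  segs3 <- intervals("chr1", 0, 20000, strand = "-")
  prof3 <- decay_profile(segs3, probes, n_bins = 10)
  expect_true(all(diff(prof3$mean_z) > 0))
})

test_that("proximal pairing verdicts follow the strand and direction rules", {
  genes <- data.frame(gene_id = "g", chrom = "chr1", start = 10000,
                      end = 20000, strand = "+", de = TRUE,
                      direction = "down", sign_consistent = TRUE,
                      stringsAsFactors = FALSE)
  probe <- function(strand, direction)
    data.frame(probe_id = "p1", chrom = "chr1", pos = 25000,
               strand = strand, direction = direction,
               stringsAsFactors = FALSE)
  v <- function(strand, direction)
    proximal_pairs(probe(strand, direction), genes)$verdict
  expect_equal(v("+", "up"), "retained")      # same strand, opposite
  expect_equal(v("+", "down"), "excluded")    # same strand, same direction
  expect_equal(v("-", "up"), "excluded")      # different strand
  expect_equal(v("-", "down"), "excluded")
  genes_up <- transform(genes, direction = "up")
  expect_equal(proximal_pairs(probe("+", "down"), genes_up)$verdict,
               "retained")
  expect_equal(proximal_pairs(probe("-", "down"), genes_up)$verdict,
               "excluded")
  ## gene must be DE with internally consistent sign
  expect_equal(proximal_pairs(probe("+", "up"),
                              transform(genes, de = FALSE))$reason,
               "gene-not-differential")
  expect_equal(proximal_pairs(probe("+", "up"),
                              transform(genes, sign_consistent = FALSE))$reason,
               "gene-sign-inconsistent")
  ## permissive antisense switch retains only overlapping pairs
  pov <- data.frame(probe_id = "p2", chrom = "chr1", pos = 15000,
                    strand = "-", direction = "up")
  expect_equal(proximal_pairs(pov, genes)$verdict, "excluded")
  expect_equal(proximal_pairs(pov, genes,
                              antisense_policy = "retain_overlapping")$verdict,
               "retained")
})

test_that("nearest-gene choice is strand-blind with 5'-side tie-breaks", {
  genes <- data.frame(gene_id = c("left", "right"), chrom = "chr1",
                      start = c(0, 20000), end = c(10001, 30000),
                      strand = c("-", "+"), de = TRUE,
                      direction = "down", sign_consistent = TRUE,
                      stringsAsFactors = FALSE)
  ## probe at 15000 is exactly 5000 nt from both gene flanks:
  ## the tie resolves to the probe's 5' side
  p_plus <- data.frame(probe_id = "p", chrom = "chr1", pos = 15000,
                       strand = "+", direction = "up")
  expect_equal(proximal_pairs(p_plus, genes)$gene_id, "left")
  p_minus <- transform(p_plus, strand = "-")
  expect_equal(proximal_pairs(p_minus, genes)$gene_id, "right")
  p_far <- transform(p_plus, pos = 19000)
  expect_equal(proximal_pairs(p_far, genes)$gene_id, "right")
  ## no genes on the chromosome: unpaired
  p_alone <- transform(p_plus, chrom = "chr9")
  expect_equal(proximal_pairs(p_alone, genes)$verdict, "unpaired")
  ## input order never changes verdicts
  probes <- rbind(p_plus, p_far, p_alone)
  v1 <- proximal_pairs(probes, genes)
  v2 <- proximal_pairs(probes[c(3, 1, 2), ], genes)
  expect_equal(v1$verdict[c(3, 1, 2)], v2$verdict)
})
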