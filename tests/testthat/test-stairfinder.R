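make_profile <- function(dens, step = 1000, chrom = "chr1") {
  structure(setNames(list(list(pos = seq(0, by = step,
                                         length.out = length(dens)),
                               dens = dens)), chrom),
            class = "density_profile", bandwidth = 100 * step,
            grid_step = step)
}

test_that("the biweight kernel matches its closed form", {
  expect_equal(biweight_kernel(0), 15 / 16)
  expect_equal(biweight_kernel(c(-1, 1)), c(0, 0))
  expect_equal(biweight_kernel(0.5), (15 / 16) * 0.75^2)
  expect_equal(biweight_kernel(1.5), 0)
})

test_that("segment density is length-weighted and compactly supported", {
  seg <- intervals("chr1", 99500, 100500)  # length 1000, center 100000
  prof <- density_estimate(seg, bandwidth = 1e5, grid_step = 1000)
  pos <- prof$chr1$pos
  at <- function(x) prof$chr1$dens[match(x, pos)]
  expect_equal(at(1e5), 1000 * 15 / 16)
  expect_equal(at(0), 0)       # center - h
  expect_equal(at(2e5), 0)     # center + h
  ## two identical segments double the density everywhere
  prof2 <- density_estimate(rbind(seg, seg), 1e5, 1000)
  expect_equal(prof2$chr1$dens, 2 * prof$chr1$dens)
})

test_that("peaks and flanking minima are located on the grid", {
  ## unimodal profile: one peak, minima at the zero boundaries
  v <- c(0, 1, 3, 7, 3, 1, 0)
  pk <- find_peaks(make_profile(v))
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$peak_idx, 4L)
  expect_equal(c(pk$left_idx, pk$right_idx), c(1L, 7L))

  ## two separated segments: two peaks with a zero valley
  segs <- intervals("chr1", c(0, 8e5), c(1e4, 8.1e5))
  pk2 <- find_peaks(density_estimate(segs, 1e5, 1000))
  expect_equal(nrow(pk2), 2L)
  expect_equal(nrow(find_peaks(make_profile(rep(0, 10)))), 0L)
})

test_that("flooding matches the direct scan and its stated limits", {
  v <- c(0, 0.2, 0.6, 1.0, 0.7, 0.4, 0.1, 0)
  prof <- make_profile(v)
  pk <- find_peaks(prof)
  ## level 0.5: positions with density >= 0.5 are grid indices 3..5
  fl <- flood_boundaries(prof, pk[1, ], 0.5)
  expect_equal(fl$start, 2000)
  expect_equal(fl$end, 4000 + 1000)
  ## level 0 recovers the flanking minima
  fl0 <- flood_boundaries(prof, pk[1, ], 0)
  expect_equal(fl0$start, pk$left_pos)
  expect_equal(fl0$end, pk$right_pos + 1000)
  ## level 1 collapses onto the peak
  fl1 <- flood_boundaries(prof, pk[1, ], 1)
  expect_equal(fl1$start, pk$peak_pos)
  ## monotone nesting across levels
  prev <- fl0
  for (lev in c(0.25, 0.5, 0.75, 1)) {
    cur <- flood_boundaries(prof, pk[1, ], lev)
    expect_gte(cur$start, prev$start)
    expect_lte(cur$end, prev$end)
    expect_lte(cur$start, pk$peak_pos)  # always contains the peak
    expect_gte(cur$end, pk$peak_pos)
    prev <- cur
  }
})

test_that("single tight accumulations score as coverage with silhouette one", {
  segs <- intervals("chr1", seq(0, 19000, by = 1000) + 1,
                    seq(0, 19000, by = 1000) + 1000)
  out <- stairfinder(segs, bandwidth = 1e5, level = 0.5)
  expect_equal(nrow(out), 1L)
  expect_equal(out$silhouette, 1)
  covered <- overlap_nucleotides(segs, out[, c("chrom", "start", "end")])
  expect_equal(out$score, covered)
  expect_gt(out$score, 10000)  # above the curation threshold
  expect_true(out$macro_sized)
})

test_that("silhouettes approach one as cluster separation grows", {
  sil_at <- function(gap) {
    s1 <- intervals("chr1", c(0, 2000), c(1000, 3000))
    s2 <- intervals("chr1", gap + c(0, 2000), gap + c(1000, 3000))
    out <- stairfinder(rbind(s1, s2), bandwidth = 5000, level = 0.5)
    mean(out$silhouette)
  }
  sils <- vapply(c(5e4, 5e5, 5e6), sil_at, numeric(1))
  expect_true(all(diff(sils) > 0))
  expect_gt(sils[3], 0.99)
})

test_that("regions with no member segments score zero", {
  regions <- intervals("chr1", 5e5, 6e5)
  regions$peak_dens <- 1
  out <- merge_and_score(regions, intervals("chr1", 0, 1000))
  expect_equal(out$covered_nt, 0)
  expect_equal(out$score, 0)
})

test_that("scores are invariant under coordinate translation", {
  ## anchored away from the origin so the kernel support is not clipped
  segs <- intervals("chr1", 2e5 + seq(0, 45000, by = 5000),
                    2e5 + seq(0, 45000, by = 5000) + 2000)
  out1 <- stairfinder(segs, bandwidth = 5e4, level = 0.5)
  shifted <- segs; shifted$start <- segs$start + 7.3e6
  shifted$end <- segs$end + 7.3e6
  out2 <- stairfinder(shifted, bandwidth = 5e4, level = 0.5)
  expect_equal(out1$score, out2$score)
  expect_equal(out2$start - out1$start, rep(7.3e6, nrow(out1)))
})

test_that("the category cascade is total and matches its definitions", {
  ## plus-strand coding gene chr1:100000-200000 with exons at both ends,
  ## a non-coding gene at chr1:400000-410000
  genes <- data.frame(chrom = "chr1", start = c(1e5, 4e5),
                      end = c(2e5, 4.1e5), strand = "+",
                      gene_id = c("gc1", "gn1"), coding = c(TRUE, FALSE))
  exons <- data.frame(chrom = "chr1",
                      start = c(1e5, 1.98e5, 4e5),
                      end = c(1.02e5, 2e5, 4.1e5), strand = "+",
                      gene_id = c("gc1", "gc1", "gn1"),
                      coding = c(TRUE, TRUE, FALSE))
  ann <- annotation_set(genes = genes, exons = exons)
  cat_of <- function(s, e)
    categorize_macro(intervals("chr1", s, e), ann, tolerance = 5000)
  expect_equal(cat_of(6e5, 7e5), "IG")              # no gene-body overlap
  expect_equal(cat_of(1.01e5, 1.99e5), "P")         # TSS..terminus match
  expect_equal(cat_of(1.0e5, 1.5e5), "ES")          # TSS match, ends inside
  expect_equal(cat_of(1.2e5, 1.5e5), "I")           # intron interior
  expect_equal(cat_of(1.9e5, 2.1e5), "E")           # touches a coding exon
  expect_equal(cat_of(3.99e5, 4.2e5), "EN")         # non-coding exons only
  ## minus-strand gene: TSS sits at the right end
  genes2 <- data.frame(chrom = "chr1", start = 1e5, end = 2e5,
                       strand = "-", gene_id = "gm", coding = TRUE)
  exons2 <- data.frame(chrom = "chr1", start = 1e5, end = 1.01e5,
                       strand = "-", gene_id = "gm", coding = TRUE)
  ann2 <- annotation_set(genes = genes2, exons = exons2)
  expect_equal(categorize_macro(intervals("chr1", 1.5e5, 1.99e5), ann2,
                                5000), "ES")
})
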