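test_that("GC bins are rank-based quantile classes with stable ties", {
  expect_equal(assign_gc_bins(seq(0.1, 0.8, by = 0.1), 4),
               c(0L, 0L, 1L, 1L, 2L, 2L, 3L, 3L))
  expect_equal(assign_gc_bins(runif(10), 1), rep(0L, 10))
  ## fully tied gc: stable rank order splits deterministically
  expect_equal(assign_gc_bins(rep(0.5, 8), 4),
               c(0L, 0L, 1L, 1L, 2L, 2L, 3L, 3L))
  expect_error(assign_gc_bins(c(0.4, 0.5), 4), "exceeds")
})

test_that("window scores follow the trimming and converse-discard rules", {
  expect_equal(trimmed_mean_score(c(1, 2, 3, 4, 10)), 3)
  expect_equal(trimmed_mean_score(c(5, 5, 5)), 5)
  expect_true(is.na(trimmed_mean_score(7)))

  d1 <- differential_score(c(1.0, 0.8, -0.2))
  expect_equal(d1$score, 0.9)
  expect_equal(d1$direction, "up")
  d2 <- differential_score(c(-1, -1, 0.1))
  expect_equal(d2$score, -1)
  expect_equal(d2$direction, "down")
  ## zero-sum tie breaks to up
  d3 <- differential_score(c(0.5, -0.5))
  expect_equal(d3$direction, "up")
  expect_equal(d3$score, 0.5)
})

test_that("probe-anchored windows have contiguous membership", {
  probes <- data.frame(chrom = "chr1",
                       start = c(0, 50, 120, 190, 400), gc = 0.5)
  w <- make_windows(probes, window_size = 200, min_probes = 3)
  expect_equal(nrow(w), 5L)
  expect_equal(w$n, c(4L, 3L, 2L, 1L, 1L))
  expect_equal(w$valid, c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_error(make_windows(probes[c(2, 1), ], 200), "sorted")
})

test_that("degenerate nulls are point masses and p-values hit the pseudocount formula", {
  ## a window covering the whole array: trimmed mean is permutation-invariant
  probes <- data.frame(chrom = "chr1", start = c(0, 35, 70, 105), gc = 0.5)
  w <- make_windows(probes, window_size = 200, min_probes = 3)
  w <- w[1, ]
  y <- c(2, 9, 4, 1)
  null <- permutation_null(y, rep(0L, 4), w, 50, "expressed", seed = 1)
  expect_equal(length(unique(null)), 1L)
  pq <- empirical_q(trimmed_mean_score(y), null)
  expect_equal(pq$p_emp, 1)  # observed equals every null value

  ## constant intensities: point mass at the constant
  null2 <- permutation_null(rep(3, 4), rep(0L, 4), w, 20, "expressed",
                            seed = 1)
  expect_equal(unique(null2), 3)

  expect_equal(empirical_q(10, rnorm(999))$p_emp, 1 / 1000)
  p_mid <- empirical_q(0, seq(-1, 1, length.out = 999))$p_emp
  expect_lt(abs(p_mid - 0.5), 0.01)
})

test_that("BH-adjusted empirical q matches the hand computation", {
  ## null 1..99 and observed 100, 99, 98, 97 give exceedance counts
  ## 0..3, hence p = 0.01, 0.02, 0.03, 0.04; q_i = min_{j>=i} p_j m/j
  pq <- empirical_q(c(100, 99, 98, 97), as.numeric(1:99))
  expect_equal(pq$p_emp, c(0.01, 0.02, 0.03, 0.04))
  expect_equal(pq$q, rep(0.04, 4))
})

test_that("streaming permutation test equals the materialized null route", {
  set.seed(5)
  probes <- data.frame(chrom = "chr1", start = seq(0, 34 * 40, by = 40),
                       gc = runif(35))
  y <- rnorm(35)
  w <- make_windows(probes, window_size = 200, min_probes = 3)
  bins <- assign_gc_bins(probes$gc, 2)
  null <- permutation_null(y, bins, w, 80, "expressed", seed = 9)
  obs <- tilestair:::cpp_trimmed_scores(y, w$first[w$valid], w$last[w$valid])
  direct <- empirical_q(obs, null)
  stream <- permutation_test(y, bins, w, 80, "expressed", seed = 9)
  expect_equal(stream$p_emp, direct$p_emp)
  expect_equal(stream$q, direct$q)
})

test_that("sampled permutation p-values agree with exhaustive enumeration", {
  ## 6 probes, 2 valid windows of 3, one GC bin: 720 distinct orderings
  probes <- data.frame(chrom = "chr1", start = c(0, 40, 80, 300, 340, 380),
                       gc = 0.5)
  y <- c(4.1, 3.7, 4.4, 0.2, -0.5, 0.1)
  w <- make_windows(probes, window_size = 150, min_probes = 3)
  wv <- w[w$valid, ]
  p_ex <- exhaustive_p(y, wv$first, wv$last)
  stream <- permutation_test(y, rep(0L, 6), w, 4000, "expressed", seed = 2)
  mc_sd <- sqrt(p_ex * (1 - p_ex) / 4000)
  expect_true(all(abs(stream$p_emp - p_ex) <= 3 * mc_sd + 1e-9))
})

test_that("TARs merge overlapping significant windows only", {
  win <- data.frame(chrom = c("chr1", "chr1", "chr2", "chr1"),
                    start = c(0, 100, 0, 500), end = c(200, 300, 200, 700),
                    score = c(5, 6, 7, 8),
                    q = c(0.01, 0.01, 0.01, 0.2))
  tars <- call_tars(win, 0.05, "A")
  expect_equal(nrow(tars), 2L)
  t1 <- tars[tars$chrom == "chr1", ]
  expect_equal(c(t1$start, t1$end), c(0, 300))
  expect_equal(t1$score, 6)
  expect_equal(nrow(call_tars(win[win$q > 0.1, ], 0.05)), 0L)
})

test_that("DE-TAR calls honor H eligibility and direction stratification", {
  win <- data.frame(chrom = "chr1",
                    start = c(0, 100, 5000, 5100),
                    end = c(200, 300, 5200, 5300),
                    score = c(2, -2, 3, 3),
                    direction = c("up", "down", "up", "up"),
                    p_emp = c(1e-4, 1e-4, 1e-4, 1e-4))
  h <- intervals("chr1", 0, 400)  # only the first two windows eligible
  de <- call_de_tars(win, h, q_threshold = 0.005, contrast = "B-A")
  expect_equal(nrow(de), 2L)  # up and down kept apart despite overlap
  expect_setequal(de$direction, c("up", "down"))
  ## windows outside every H interval are never reported
  expect_false(any(de$start >= 5000))
  ## an H interval covering only one condition's segment still qualifies
  de2 <- call_de_tars(win, intervals("chr1", 5000, 5400), 0.005)
  expect_true(all(de2$start >= 5000))
  expect_error(call_de_tars(win, NULL), "H intervals")
})

test_that("lowering the q threshold never enlarges the TAR nucleotide set", {
  sc <- planted_scenario()
  w <- sc$resA$windows
  nts <- vapply(c(0.2, 0.05, 0.01, 0.001), function(qt)
    covered_nucleotides(call_tars(w, qt, "A")[, c("chrom", "start", "end")]),
    numeric(1))
  expect_true(all(diff(nts) <= 0))
  ## and the stricter set is contained in the looser one
  strict <- call_tars(w, 0.001, "A")
  loose <- call_tars(w, 0.05, "A")
  if (nrow(strict))
    expect_equal(overlap_nucleotides(strict, loose),
                 covered_nucleotides(strict[, c("chrom", "start", "end")]))
})

test_that("GC binning controls affinity-driven false positives", {
  ## spatially blocky GC plus a strong affinity effect, no expression:
  ## a one-bin null mistakes GC-rich blocks for signal, a four-bin null
  ## must not do worse
  set.seed(21)
  starts <- seq(0, 2e5 - 35, by = 35)
  block_hi <- (starts %/% 10000) %% 2 == 0
  gc <- ifelse(block_hi, rbeta(length(starts), 14, 6),
               rbeta(length(starts), 6, 14))
  probes <- data.frame(probe_id = as.character(seq_along(starts)),
                       chrom = "chr1", start = starts, length = 25, gc = gc)
  p <- simulate_intensities(probes, truth_set(),
                            data.frame(condition = "A", time_h = Inf),
                            noise_sd = 0.5, gc_effect = 4, seed = 22)
  res1 <- segment_expressed(p, "A", n_permutations = 60, gc_classes = 1,
                            seed = 23)
  res4 <- segment_expressed(p, "A", n_permutations = 60, gc_classes = 4,
                            seed = 23)
  fp1 <- sum(res1$windows$q < 0.05)
  fp4 <- sum(res4$windows$q < 0.05)
  expect_gt(fp1, 0)       # the confound really bites without binning
  expect_lt(fp4, fp1)
})
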