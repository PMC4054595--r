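#' Window-based permutation segmentation of tiling signal
#'
#' The segmentation stage scores fixed-width windows of probe signal and
#' assesses them against a pooled permutation null in which probe values
#' are shuffled only within GC-content bins, controlling the affinity
#' bias of high-GC probes. Significant windows (Benjamini-Hochberg
#' adjusted empirical p-values) are merged into transcriptionally active
#' regions (TARs); differential windows, restricted to regions expressed
#' in at least one condition (H intervals), become DE-TARs.
#'
#' @name segmentation
NULL

#' Assign probes to GC-content bins
#'
#' Bins are gc-quantile classes of near-equal size, assigned by stable
#' rank order so ties (including fully degenerate gc vectors) split
#' deterministically.
#'
#' @param gc numeric vector of per-probe GC fractions.
#' @param n_classes number of bins (>= 1); 1 puts all probes in one bin.
#' @return Integer bin labels in `0:(n_classes-1)`.
#' @examples
#' assign_gc_bins(seq(0.1, 0.8, by = 0.1), 4)
#' @export
assign_gc_bins <- function(gc, n_classes) {
  stopifnot(n_classes >= 1)
  if (n_classes > length(gc))
    stop("n_classes exceeds the number of probes")
  r <- rank(gc, ties.method = "first")
  as.integer(ceiling(r * n_classes / length(gc)) - 1L)
}

#' Trimmed-mean window score
#'
#' Arithmetic mean after removing exactly one maximal and one minimal
#' value. Returns `NA` for fewer than 3 values (such windows are
#' excluded from evaluation, not an error).
#'
#' @param values per-probe intensities within one window.
#' @return Scalar score, or `NA` if the window is invalid.
#' @examples
#' trimmed_mean_score(c(1, 2, 3, 4, 10))  # 3
#' @export
trimmed_mean_score <- function(values) {
  if (length(values) < 3) return(NA_real_)
  cpp_trimmed_scores(as.numeric(values), 1L, length(values))
}

#' Differential window score
#'
#' The window direction is the sign of the summed per-probe differences
#' (a zero-sum tie breaks to "up"); probes whose difference opposes that
#' direction are discarded and the score is the signed mean of the
#' retained differences.
#'
#' @param log_diffs per-probe intensity differences within one window.
#' @return List with `score` (signed mean) and `direction`
#'   (`"up"`/`"down"`).
#' @examples
#' differential_score(c(1, 0.8, -0.2))  # up, 0.9
#' @export
differential_score <- function(log_diffs) {
  res <- cpp_diff_scores(as.numeric(log_diffs), 1L, length(log_diffs))
  list(score = res$score[1],
       direction = if (res$direction[1] > 0) "up" else "down")
}

#' Build probe-anchored windows
#'
#' One window of `window_size` nt is anchored at each probe start;
#' members are the probes whose start lies inside the window. Probes
#' must be position-sorted per chromosome (as [generate_probes()]
#' returns them); windows with fewer than `min_probes` members are
#' marked invalid and excluded from scoring.
#'
#' @param probes probe table (`chrom`, `start`).
#' @param window_size window width in nt.
#' @param min_probes minimal member count for a window to be evaluated.
#' @return `data.frame(chrom, start, end, first, last, n, valid)` where
#'   `first`/`last` are 1-based indices into the sorted probe table.
#' @export
make_windows <- function(probes, window_size = 200, min_probes = 3) {
  stopifnot(window_size >= 1)
  o <- order(probes$chrom, probes$start)
  if (any(o != seq_along(o)))
    stop("probes must be sorted by chromosome and start")
  out <- NULL
  offset <- 0L
  for (chrom in unique(probes$chrom)) {
    s <- probes$start[probes$chrom == chrom]
    m <- length(s)
    last <- findInterval(s + window_size - 0.5, s)
    out <- rbind(out, data.frame(
      chrom = chrom, start = s, end = s + window_size,
      first = offset + seq_len(m), last = offset + last,
      stringsAsFactors = FALSE))
    offset <- offset + m
  }
  out$n <- out$last - out$first + 1L
  out$valid <- out$n >= min_probes
  rownames(out) <- NULL
  out
}

window_scores <- function(y, windows, type = c("expressed", "differential")) {
  type <- match.arg(type)
  if (type == "expressed") {
    list(score = cpp_trimmed_scores(y, windows$first, windows$last),
         direction = NULL)
  } else {
    res <- cpp_diff_scores(y, windows$first, windows$last)
    list(score = res$score, direction = res$direction)
  }
}

shuffle_within_bins <- function(y, bin_index) {
  yp <- y
  for (idx in bin_index)
    yp[idx] <- y[idx[sample.int(length(idx))]]
  yp
}

#' Materialized pooled permutation null
#'
#' Shuffles probe values uniformly within GC bins across the whole
#' probe set and recomputes all valid window scores per permutation; the
#' pooled null is the multiset of all permuted window scores. Intended
#' for small inputs and audits - [permutation_test()] computes the same
#' p-values in streaming form with O(#windows) memory.
#'
#' @param y per-probe values (intensities or differences), in sorted
#'   probe order.
#' @param gc_bins integer bin label per probe (see [assign_gc_bins()]).
#' @param windows window table from [make_windows()].
#' @param n_permutations number of permutations (>= 1).
#' @param type `"expressed"` (trimmed mean) or `"differential"`.
#' @param seed integer seed.
#' @return Numeric vector of length `n_permutations * #valid windows`.
#' @export
permutation_null <- function(y, gc_bins, windows, n_permutations,
                             type = c("expressed", "differential"),
                             seed = 1) {
  stopifnot(n_permutations >= 1)
  type <- match.arg(type)
  wv <- windows[windows$valid, , drop = FALSE]
  bin_index <- split(seq_along(y), gc_bins)
  withr_seed(seed, {
    out <- vector("list", n_permutations)
    for (p in seq_len(n_permutations)) {
      yp <- shuffle_within_bins(y, bin_index)
      out[[p]] <- window_scores(yp, wv, type)$score
    }
    unlist(out)
  })
}

#' Empirical p-values and BH adjustment against a null sample
#'
#' `p_emp = (1 + #\{null >= observed\}) / (1 + #null)` (upper tail, with
#' the +1 pseudocount); for two-sided scores the tail is
#' `|null| >= |observed|`. q-values are Benjamini-Hochberg adjusted over
#' all evaluated windows.
#'
#' @param observed observed window scores.
#' @param null null score sample (pooled over windows and permutations).
#' @param two_sided compare absolute values (differential scores).
#' @return `data.frame(p_emp, q)` aligned with `observed`.
#' @export
empirical_q <- function(observed, null, two_sided = FALSE) {
  stopifnot(length(null) > 0)
  o <- if (two_sided) abs(observed) else observed
  nn <- if (two_sided) abs(null) else null
  sn <- sort(nn)
  cnt_ge <- length(sn) - findInterval(o, sn, left.open = TRUE)
  p <- (1 + cnt_ge) / (1 + length(sn))
  data.frame(p_emp = p, q = p.adjust(p, method = "BH"))
}

#' Streaming GC-binned permutation test for all windows
#'
#' Equivalent to [permutation_null()] + [empirical_q()] but accumulates
#' per-window exceedance counts against the pooled null permutation by
#' permutation, so 10^5-permutation runs need O(#windows) memory.
#'
#' @inheritParams permutation_null
#' @param two_sided use the `|null| >= |observed|` tail.
#' @return `windows` (valid rows only) with `score`, `direction` (for
#'   differential scores), `p_emp` and `q` columns.
#' @export
permutation_test <- function(y, gc_bins, windows, n_permutations,
                             type = c("expressed", "differential"),
                             two_sided = (type == "differential"),
                             seed = 1) {
  stopifnot(n_permutations >= 1)
  type <- match.arg(type)
  wv <- windows[windows$valid, , drop = FALSE]
  obs <- window_scores(y, wv, type)
  wv$score <- obs$score
  if (!is.null(obs$direction))
    wv$direction <- ifelse(obs$direction > 0, "up", "down")
  o <- if (two_sided) abs(wv$score) else wv$score
  so <- sort(o)
  rnk <- match(o, so)  # scores -> positions in sorted obs (ties: first)
  bin_index <- split(seq_along(y), gc_bins)
  cnt_sorted <- numeric(length(so))
  total <- 0
  withr_seed(seed, {
    for (p in seq_len(n_permutations)) {
      yp <- shuffle_within_bins(y, bin_index)
      s <- window_scores(yp, wv, type)$score
      if (two_sided) s <- abs(s)
      ss <- sort(s)
      ## for each sorted obs value, how many permuted scores are >= it
      cnt_sorted <- cnt_sorted +
        (length(ss) - findInterval(so, ss, left.open = TRUE))
      total <- total + length(ss)
    }
  })
  ## equal obs values share a count; map back via the sorted positions
  cnt <- cnt_sorted[match(o, so)]
  wv$p_emp <- (1 + cnt) / (1 + total)
  wv$q <- p.adjust(wv$p_emp, method = "BH")
  rownames(wv) <- NULL
  wv
}

#' Merge significant windows into TARs
#'
#' Windows with `q` below the threshold are merged when they overlap by
#' at least one nucleotide (bookended windows stay separate); each TAR
#' records the condition and the maximum member window score.
#'
#' @param windows scored window table (from [permutation_test()]).
#' @param q_threshold significance threshold on the BH-adjusted q.
#' @param condition label stored with each TAR.
#' @return Segment `data.frame(chrom, start, end, kind, condition,
#'   score)`.
#' @export
call_tars <- function(windows, q_threshold = 0.05, condition = "cond") {
  sig <- windows[windows$q < q_threshold, , drop = FALSE]
  if (!nrow(sig))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), kind = character(),
                      condition = character(), score = numeric()))
  merged <- merge_intervals(sig)
  merged$kind <- "TAR"
  merged$condition <- condition
  merged$score <- vapply(seq_len(nrow(merged)), function(i) {
    inside <- sig$chrom == merged$chrom[i] &
      sig$start < merged$end[i] & sig$end > merged$start[i]
    max(sig$score[inside])
  }, numeric(1))
  merged
}

#' Merge significant differential windows into DE-TARs
#'
#' Only windows overlapping the union of the contrast's H intervals
#' (significantly expressed segments of either condition) are eligible;
#' q-values are recomputed by BH over the eligible windows. Merging is
#' direction-stratified: abutting up- and down-windows yield separate
#' DE-TARs.
#'
#' @param windows scored differential window table with `direction`.
#' @param h_intervals interval `data.frame` of H intervals (union over
#'   the contrast's conditions); required.
#' @param q_threshold significance threshold (default 0.005).
#' @param contrast label stored with each DE-TAR.
#' @return Segment `data.frame(chrom, start, end, kind, contrast,
#'   direction, score)`.
#' @export
call_de_tars <- function(windows, h_intervals, q_threshold = 0.005,
                         contrast = "contrast") {
  if (is.null(h_intervals))
    stop("contrast lacks H intervals: differential windows can only be called inside significantly expressed regions")
  h_intervals <- validate_intervals(h_intervals)
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), kind = character(),
                      contrast = character(), direction = character(),
                      score = numeric())
  if (!nrow(windows)) return(empty)
  elig <- if (nrow(h_intervals)) {
    GenomicRanges::countOverlaps(
      iv_to_gr(windows[, c("chrom", "start", "end")]),
      iv_to_gr(h_intervals), ignore.strand = TRUE) > 0
  } else rep(FALSE, nrow(windows))
  we <- windows[elig, , drop = FALSE]
  if (!nrow(we)) return(empty)
  we$q <- p.adjust(we$p_emp, method = "BH")
  sig <- we[we$q < q_threshold, , drop = FALSE]
  if (!nrow(sig)) return(empty)
  out <- NULL
  for (dir in unique(sig$direction)) {
    sd_ <- sig[sig$direction == dir, , drop = FALSE]
    merged <- merge_intervals(sd_)
    merged$kind <- "DE-TAR"
    merged$contrast <- contrast
    merged$direction <- dir
    merged$score <- vapply(seq_len(nrow(merged)), function(i) {
      inside <- sd_$chrom == merged$chrom[i] &
        sd_$start < merged$end[i] & sd_$end > merged$start[i]
      sd_$score[inside][which.max(abs(sd_$score[inside]))]
    }, numeric(1))
    out <- rbind(out, merged)
  }
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect significantly expressed regions (TARs) in one condition
#'
#' End-to-end expression segmentation: probe-anchored windows, trimmed
#' mean scores, GC-binned pooled permutation null, BH-adjusted empirical
#' q-values, merge of significant windows.
#'
#' @param probes probe table with an intensity column named `condition`.
#' @param condition name of the intensity column to segment.
#' @param window_size window width (nt; default 200).
#' @param min_probes minimal probes per window (default 3).
#' @param n_permutations GC-controlled permutations (default 10000).
#' @param gc_classes number of GC bins (default 4).
#' @param q_threshold significance threshold (default 0.05).
#' @param seed integer seed.
#' @return List with `windows` (scored table) and `tars` (segments).
#' @export
segment_expressed <- function(probes, condition, window_size = 200,
                              min_probes = 3, n_permutations = 10000,
                              gc_classes = 4, q_threshold = 0.05, seed = 1) {
  stopifnot(condition %in% names(probes))
  windows <- make_windows(probes, window_size, min_probes)
  bins <- assign_gc_bins(probes$gc, gc_classes)
  scored <- permutation_test(probes[[condition]], bins, windows,
                             n_permutations, type = "expressed",
                             two_sided = FALSE, seed = seed)
  list(windows = scored,
       tars = call_tars(scored, q_threshold, condition))
}

#' Detect differentially expressed regions (DE-TARs) for a contrast
#'
#' Scores per-probe intensity differences (`condition_b` minus
#' `condition_a`) with the converse-probe-discarding differential score,
#' builds a difference-shuffle null (sequence effects cancel in the
#' difference, so a single GC class is the default), and restricts calls
#' to windows overlapping the union of both conditions' H intervals.
#'
#' @param probes probe table with intensity columns for both conditions.
#' @param condition_a,condition_b the contrasted intensity columns.
#' @param h_intervals named list with one interval `data.frame` per
#'   condition (or an already-merged interval `data.frame`); both
#'   conditions must be present when a list is given.
#' @param window_size,min_probes,n_permutations,gc_classes,seed as in
#'   [segment_expressed()]; defaults 200, 3, 1e5, 1.
#' @param q_threshold significance threshold (default 0.005).
#' @return List with `windows` (scored, eligible-restricted q) and
#'   `de_tars` (direction-stratified segments).
#' @export
segment_differential <- function(probes, condition_a, condition_b,
                                 h_intervals, window_size = 200,
                                 min_probes = 3, n_permutations = 100000,
                                 gc_classes = 1, q_threshold = 0.005,
                                 seed = 1) {
  stopifnot(condition_a %in% names(probes), condition_b %in% names(probes))
  if (is.data.frame(h_intervals)) {
    h_union <- merge_intervals(h_intervals)
  } else {
    miss <- setdiff(c(condition_a, condition_b), names(h_intervals))
    if (length(miss))
      stop("contrast lacks H intervals for condition(s): ",
           paste(miss, collapse = ", "))
    h_union <- merge_intervals(rbind(
      h_intervals[[condition_a]][, c("chrom", "start", "end")],
      h_intervals[[condition_b]][, c("chrom", "start", "end")]))
  }
  d <- probes[[condition_b]] - probes[[condition_a]]
  windows <- make_windows(probes, window_size, min_probes)
  bins <- assign_gc_bins(probes$gc, gc_classes)
  scored <- permutation_test(d, bins, windows, n_permutations,
                             type = "differential", two_sided = TRUE,
                             seed = seed)
  contrast <- paste0(condition_b, "-", condition_a)
  de <- call_de_tars(scored, h_union, q_threshold, contrast)
  ## expose the H-restricted q in the window table (NA outside H):
  ## BH runs over eligible windows only, as in call_de_tars
  elig <- if (nrow(h_union)) {
    GenomicRanges::countOverlaps(
      iv_to_gr(scored[, c("chrom", "start", "end")]),
      iv_to_gr(h_union), ignore.strand = TRUE) > 0
  } else rep(FALSE, nrow(scored))
  scored$q <- NA_real_
  scored$q[elig] <- p.adjust(scored$p_emp[elig], method = "BH")
  list(windows = scored, de_tars = de)
}

#' Nucleotide-level sensitivity and FDR of called segments against truth
#'
#' @param called,truth interval `data.frame`s (called segments, true
#'   segments).
#' @param mask optional interval `data.frame` of nucleotides invisible
#'   to the platform (repeat mask, assembly gaps); subtracted from both
#'   sides before counting, since no probe can report on them.
#' @return List with `sensitivity` (true nt recovered / true nt) and
#'   `fdr` (called nt outside truth / called nt).
#' @export
segment_recovery <- function(called, truth, mask = NULL) {
  called <- merge_intervals(called)
  truth <- merge_intervals(truth)
  if (!is.null(mask) && nrow(mask)) {
    called <- subtract_intervals(called, mask)
    truth <- subtract_intervals(truth, mask)
  }
  tp <- overlap_nucleotides(called, truth)
  n_called <- covered_nucleotides(called)
  n_true <- covered_nucleotides(truth)
  list(sensitivity = if (n_true > 0) tp / n_true else NA_real_,
       fdr = if (n_called > 0) (n_called - tp) / n_called else NA_real_)
}
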