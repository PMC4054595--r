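#' Cross-platform validation, decay profiling and proximal pairing
#'
#' @name validation-module
NULL

#' Non-specific probe filtering against negative controls
#'
#' Background expression is the mean plus three standard deviations of
#' the negative-control intensities. A probe is retained iff its
#' intensity exceeds that background in at least `min_samples` samples
#' and its interquartile range across all samples exceeds `iqr_min`.
#'
#' @param intensities numeric matrix, probes x samples.
#' @param negative_controls numeric vector (or matrix) of
#'   negative-control spot intensities; must be non-empty.
#' @param min_samples minimal number of above-background samples
#'   (default 4).
#' @param iqr_min minimal interquartile range (default 0.5).
#' @return Logical vector: probe retained. Attribute `background`
#'   carries the background level used.
#' @export
probe_nonspecific_filter <- function(intensities, negative_controls,
                                     min_samples = 4, iqr_min = 0.5) {
  if (length(negative_controls) == 0)
    stop("at least one negative-control intensity is required")
  intensities <- as.matrix(intensities)
  bg <- mean(negative_controls) + 3 * sd(as.numeric(negative_controls))
  expressed <- rowSums(intensities > bg) >= min_samples
  iqr <- apply(intensities, 1, IQR)
  keep <- expressed & iqr > iqr_min
  attr(keep, "background") <- bg
  keep
}

#' Cross-platform FDR/sensitivity/specificity over a q sweep
#'
#' For each threshold `q` of the sweep, the tiling windows with
#' adjusted q below it are merged; TP is the number of their
#' nucleotides covered by reference probes flagged differentially
#' expressed, FP the number covered by non-flagged reference probes
#' (nucleotides under no reference probe are ignored; nucleotides under
#' conflicting overlapping probes count once, resolved as DE). P and N
#' are the total nucleotides of flagged and non-flagged reference
#' probes. Sensitivity = TP/P, specificity = 1 - FP/N,
#' FDR = FP/(FP+TP).
#'
#' @param windows scored window table with `q` (e.g. from
#'   [segment_differential()]).
#' @param reference reference probe table (`chrom`, `start`, `length`,
#'   logical `de`), e.g. from [generate_reference_platform()]; must be
#'   non-empty.
#' @param q_grid thresholds; default 20 log-spaced points over
#'   `[1e-4, 1]`.
#' @return `data.frame(q, TP, FP, P, N, sensitivity, specificity, fdr)`.
#' @export
fdr_curve <- function(windows, reference,
                      q_grid = 10^seq(-4, 0, length.out = 20)) {
  if (is.null(reference) || nrow(reference) == 0)
    stop("reference probe table is empty")
  ref_iv <- intervals(reference$chrom, reference$start,
                      reference$start + reference$length)
  pos_nt <- merge_intervals(ref_iv[reference$de, , drop = FALSE])
  neg_all <- merge_intervals(ref_iv[!reference$de, , drop = FALSE])
  neg_nt <- subtract_intervals(neg_all, pos_nt)  # conflicts resolved as DE
  P <- sum(interval_widths(pos_nt))
  N <- sum(interval_widths(neg_nt))
  rows <- lapply(q_grid, function(qt) {
    sig <- windows[!is.na(windows$q) & windows$q < qt, , drop = FALSE]
    tp <- overlap_nucleotides(sig, pos_nt)
    fp <- overlap_nucleotides(sig, neg_nt)
    data.frame(q = qt, TP = tp, FP = fp, P = P, N = N,
               sensitivity = if (P > 0) tp / P else NA_real_,
               specificity = if (N > 0) 1 - fp / N else NA_real_,
               fdr = if (tp + fp > 0) fp / (fp + tp) else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Signal decay profile along normalized transcript coordinates
#'
#' Each probe inside a segment is mapped to the relative coordinate
#' `(pos - start) / length` measured from the segment's 5' anchor
#' (strand `-` segments are mirrored); per-bin mean z-scores across all
#' segments summarize the 5' to 3' signal trend. Segments containing no
#' probes are skipped.
#'
#' @param segments interval `data.frame` with a `strand` column (the
#'   5' anchor orientation).
#' @param probes probe table with `chrom`, `start` and a `z` column
#'   (z-scores).
#' @param n_bins number of equal-width bins over `[0, 1]`.
#' @return `data.frame(bin, mid, mean_z, n_probes)`; attribute
#'   `n_segments` counts segments contributing probes.
#' @export
decay_profile <- function(segments, probes, n_bins = 20) {
  segments <- validate_intervals(segments)
  stopifnot("z" %in% names(probes), n_bins >= 1)
  rel <- numeric(); z <- numeric(); used <- 0L
  for (i in seq_len(nrow(segments))) {
    s <- segments[i, ]
    inside <- probes$chrom == s$chrom & probes$start >= s$start &
      probes$start < s$end
    if (!any(inside)) next
    used <- used + 1L
    r <- (probes$start[inside] - s$start) / (s$end - s$start)
    if (!is.null(s$strand) && identical(s$strand, "-")) r <- 1 - r
    rel <- c(rel, r); z <- c(z, probes$z[inside])
  }
  bin <- pmin(n_bins, floor(rel * n_bins) + 1L)
  out <- data.frame(bin = seq_len(n_bins),
                    mid = (seq_len(n_bins) - 0.5) / n_bins,
                    mean_z = vapply(seq_len(n_bins), function(b) {
                      v <- z[bin == b]
                      if (length(v)) mean(v) else NA_real_
                    }, numeric(1)),
                    n_probes = vapply(seq_len(n_bins), function(b)
                      sum(bin == b), integer(1)))
  attr(out, "n_segments") <- used
  out
}

#' Pair differential non-coding probes with their nearest coding gene
#'
#' The partner is the protein-coding gene in closest genomic proximity
#' regardless of strand (distance 0 when overlapping; equidistant ties
#' break towards the probe's 5' side). A pair is retained only if the
#' gene is differentially expressed with an internally consistent
#' fold-change sign across its exon probes AND probe and gene lie on
#' the same strand with opposite directions of change; all
#' different-strand pairs where both members change significantly are
#' excluded (the literal rule; set
#' `antisense_policy = "retain_overlapping"` for the permissive
#' alternative that keeps antisense overlapping pairs).
#'
#' @param nc_probes `data.frame(probe_id, chrom, pos, strand,
#'   direction)` of significantly differential non-coding probes
#'   (`direction` in `"up"`/`"down"`).
#' @param genes `data.frame(gene_id, chrom, start, end, strand, de,
#'   direction, sign_consistent)`.
#' @param antisense_policy `"exclude"` (literal rule) or
#'   `"retain_overlapping"`.
#' @return `data.frame(probe_id, gene_id, distance, verdict, reason)`;
#'   probes on chromosomes without genes are reported unpaired.
#' @export
proximal_pairs <- function(nc_probes, genes,
                           antisense_policy = c("exclude",
                                                "retain_overlapping")) {
  antisense_policy <- match.arg(antisense_policy)
  rows <- lapply(seq_len(nrow(nc_probes)), function(i) {
    p <- nc_probes[i, ]
    g <- genes[genes$chrom == p$chrom, , drop = FALSE]
    if (!nrow(g))
      return(data.frame(probe_id = p$probe_id, gene_id = NA_character_,
                        distance = NA_real_, verdict = "unpaired",
                        reason = "no-gene-on-chromosome",
                        stringsAsFactors = FALSE))
    dist <- pmax(0, pmax(g$start - p$pos, p$pos - (g$end - 1)))
    cand <- which(dist == min(dist))
    if (length(cand) > 1) {
      ## tie: prefer the gene on the probe's 5' side
      upstream <- if (identical(p$strand, "-"))
        g$start[cand] > p$pos else g$end[cand] <= p$pos
      if (any(upstream)) cand <- cand[upstream]
      cand <- cand[1]
    }
    g <- g[cand, ]
    mk <- function(verdict, reason)
      data.frame(probe_id = p$probe_id, gene_id = g$gene_id,
                 distance = dist[cand], verdict = verdict,
                 reason = reason, stringsAsFactors = FALSE)
    if (!isTRUE(g$de)) return(mk("excluded", "gene-not-differential"))
    if (!isTRUE(g$sign_consistent))
      return(mk("excluded", "gene-sign-inconsistent"))
    same_strand <- identical(p$strand, g$strand)
    if (!same_strand) {
      if (antisense_policy == "retain_overlapping" && dist[cand] == 0)
        return(mk("retained", "antisense-overlapping"))
      return(mk("excluded", "different-strand"))
    }
    if (identical(p$direction, g$direction))
      return(mk("excluded", "same-direction-same-strand"))
    mk("retained", "opposite-direction-same-strand")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
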