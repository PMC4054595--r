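#' stairFinder: macroRNA detection by kernel-density flooding
#'
#' Very long, apparently continuous transcripts (macroRNAs, >= 1e4 nt)
#' appear in tiling data not as single segments but as dense local
#' accumulations of short (DE-)segments interrupted by repeats and
#' signal dropouts. stairFinder estimates a segment density along each
#' chromosome - each segment contributes a biweight kernel at its
#' center, weighted by its length - then turns every density peak into
#' an accumulation region by "flooding": the region extends between the
#' peak's flanking minima as far as the density stays above
#' `level * peak`. Overlapping regions are combined, scored by covered
#' nucleotides times the (clamped) mean silhouette of their member
#' segments, and placed in a genomic-context category.
#'
#' @name stairfinder-module
NULL

#' Biweight (quartic) kernel
#'
#' `K(u) = (15/16) (1 - u^2)^2` for `|u| <= 1`, else 0.
#'
#' @param u numeric vector of dimensionless distances.
#' @return Kernel values.
#' @examples
#' biweight_kernel(c(0, 0.5, 1))
#' @export
biweight_kernel <- function(u) {
  ifelse(abs(u) <= 1, (15 / 16) * (1 - u^2)^2, 0)
}

#' Length-weighted segment density profile
#'
#' `f(x) = sum_i length_i * K((x - center_i)/h)`, evaluated on a regular
#' per-chromosome grid. No `1/h` normalization is applied: flooding only
#' uses levels relative to the local peak.
#'
#' @param segments interval `data.frame`.
#' @param bandwidth kernel bandwidth `h` in nt (default 100000).
#' @param grid_step grid spacing in nt (default `bandwidth/100`).
#' @return List of class `density_profile`: per chromosome a list with
#'   `pos` (grid positions, nt) and `dens`; attributes `bandwidth` and
#'   `grid_step`.
#' @export
density_estimate <- function(segments, bandwidth = 1e5,
                             grid_step = bandwidth / 100) {
  stopifnot(bandwidth > 0, grid_step >= 1)
  segments <- validate_intervals(segments)
  profiles <- list()
  for (chrom in unique(segments$chrom)) {
    s <- segments[segments$chrom == chrom, , drop = FALSE]
    centers <- (s$start + s$end) / 2
    weights <- s$end - s$start
    lo <- grid_step * floor(max(0, min(centers) - bandwidth) / grid_step)
    hi <- grid_step * ceiling((max(centers) + bandwidth) / grid_step)
    pos <- seq(lo, hi, by = grid_step)
    dens <- numeric(length(pos))
    for (i in seq_along(centers)) {
      lo_i <- max(1L, ceiling((centers[i] - bandwidth - lo) / grid_step) + 1L)
      hi_i <- min(length(pos),
                  floor((centers[i] + bandwidth - lo) / grid_step) + 1L)
      if (lo_i > hi_i) next
      idx <- lo_i:hi_i
      dens[idx] <- dens[idx] +
        weights[i] * biweight_kernel((pos[idx] - centers[i]) / bandwidth)
    }
    profiles[[chrom]] <- list(pos = pos, dens = dens)
  }
  structure(profiles, class = "density_profile",
            bandwidth = bandwidth, grid_step = grid_step)
}

#' Find density peaks and their flanking minima
#'
#' Strict local maxima of the gridded density (plateaus report their
#' midpoint, and only positive densities qualify); each peak's flanking
#' minima are the nearest positions attaining the minimal density
#' between it and the neighboring peak (or the profile end).
#'
#' @param profile a `density_profile`.
#' @return `data.frame(chrom, peak_idx, peak_pos, peak_dens, left_idx,
#'   left_pos, right_idx, right_pos)`.
#' @export
find_peaks <- function(profile) {
  out <- NULL
  for (chrom in names(profile)) {
    v <- profile[[chrom]]$dens
    pos <- profile[[chrom]]$pos
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    k <- length(r$values)
    peak_idx <- integer()
    for (j in seq_len(k)) {
      if (r$values[j] <= 0) next
      left_ok <- j == 1L || r$values[j - 1L] < r$values[j]
      right_ok <- j == k || r$values[j + 1L] < r$values[j]
      if (left_ok && right_ok)
        peak_idx <- c(peak_idx, (starts[j] + ends[j]) %/% 2L)
    }
    if (!length(peak_idx)) next
    n_pk <- length(peak_idx)
    rows <- lapply(seq_len(n_pk), function(j) {
      p <- peak_idx[j]
      lo <- if (j == 1L) 1L else peak_idx[j - 1L]
      hi <- if (j == n_pk) length(v) else peak_idx[j + 1L]
      seg_l <- v[lo:p]
      li <- lo + max(which(seg_l == min(seg_l))) - 1L  # nearest to peak
      seg_r <- v[p:hi]
      ri <- p + min(which(seg_r == min(seg_r))) - 1L
      data.frame(chrom = chrom, peak_idx = p, peak_pos = pos[p],
                 peak_dens = v[p], left_idx = li, left_pos = pos[li],
                 right_idx = ri, right_pos = pos[ri],
                 stringsAsFactors = FALSE)
    })
    out <- rbind(out, do.call(rbind, rows))
  }
  if (is.null(out))
    out <- data.frame(chrom = character(), peak_idx = integer(),
                      peak_pos = numeric(), peak_dens = numeric(),
                      left_idx = integer(), left_pos = numeric(),
                      right_idx = integer(), right_pos = numeric())
  rownames(out) <- NULL
  out
}

#' Flood a peak to its accumulation boundaries
#'
#' Between the peak's flanking minima, the boundaries are the leftmost
#' and rightmost grid positions whose density is at least
#' `level * peak` (boundary inclusive). `level = 0` returns the flanking
#' minima themselves; `level = 1` collapses to the peak position(s).
#'
#' @param profile a `density_profile`.
#' @param peak one row of [find_peaks()] output.
#' @param level flooding level parameter in `[0, 1]`.
#' @return Interval `data.frame` (one row) in nt coordinates; the
#'   half-open end is one grid step past the rightmost qualifying
#'   position. Carries `peak_pos` and `peak_dens` columns.
#' @export
flood_boundaries <- function(profile, peak, level = 0.5) {
  stopifnot(level >= 0, level <= 1)
  v <- profile[[peak$chrom]]$dens
  pos <- profile[[peak$chrom]]$pos
  step <- attr(profile, "grid_step")
  rng <- peak$left_idx:peak$right_idx
  thr <- level * peak$peak_dens
  ok <- rng[v[rng] >= thr]
  l <- min(ok); r <- max(ok)
  out <- intervals(peak$chrom, pos[l], pos[r] + step)
  out$peak_pos <- peak$peak_pos
  out$peak_dens <- peak$peak_dens
  out
}

#' Combine flooded regions, assign segments, and score
#'
#' Overlapping flooded regions are combined; each segment is assigned
#' to the region containing its center. A segment's silhouette is
#' `(b - a) / max(a, b)` with `a` the distance from its center to its
#' own region's midpoint and `b` the distance to the nearest other
#' region's midpoint (1 if only one region exists). The region score is
#' covered nucleotides (member segments intersected with the region)
#' times the mean silhouette clamped at 0.
#'
#' @param regions flooded regions (rows of [flood_boundaries()] output).
#' @param segments the segment set the density was estimated from.
#' @param annotation optional [annotation_set()] for categorization.
#' @param tolerance TSS/terminus matching tolerance in nt (default
#'   5000) for the P and ES categories.
#' @param min_length region length (nt) above which a region is flagged
#'   as macroRNA-sized (default 1e4).
#' @return `data.frame(chrom, start, end, peak_dens, n_segments,
#'   covered_nt, silhouette, score, category, macro_sized)`.
#' @export
merge_and_score <- function(regions, segments, annotation = NULL,
                            tolerance = 5000, min_length = 1e4) {
  segments <- validate_intervals(segments)
  merged <- merge_intervals(regions)
  if (!nrow(merged))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), peak_dens = numeric(),
                      n_segments = integer(), covered_nt = numeric(),
                      silhouette = numeric(), score = numeric(),
                      category = character(), macro_sized = logical()))
  merged$peak_dens <- vapply(seq_len(nrow(merged)), function(i) {
    inside <- regions$chrom == merged$chrom[i] &
      regions$start < merged$end[i] & regions$end > merged$start[i]
    max(regions$peak_dens[inside])
  }, numeric(1))
  mids <- (merged$start + merged$end) / 2
  centers <- (segments$start + segments$end) / 2
  ## assign each segment to the region containing its center
  assign <- rep(NA_integer_, nrow(segments))
  for (i in seq_len(nrow(merged))) {
    hit <- segments$chrom == merged$chrom[i] &
      centers >= merged$start[i] & centers < merged$end[i]
    assign[hit] <- i
  }
  sil <- rep(NA_real_, nrow(segments))
  for (j in which(!is.na(assign))) {
    a <- abs(centers[j] - mids[assign[j]])
    others <- which(seq_len(nrow(merged)) != assign[j] &
                      merged$chrom == segments$chrom[j])
    if (nrow(merged) == 1L || !length(others)) { sil[j] <- 1; next }
    b <- min(abs(centers[j] - mids[others]))
    sil[j] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  merged$n_segments <- vapply(seq_len(nrow(merged)), function(i)
    sum(assign == i, na.rm = TRUE), integer(1))
  merged$covered_nt <- vapply(seq_len(nrow(merged)), function(i) {
    memb <- which(assign == i)
    if (!length(memb)) return(0)
    overlap_nucleotides(segments[memb, c("chrom", "start", "end")],
                        merged[i, c("chrom", "start", "end")])
  }, numeric(1))
  merged$silhouette <- vapply(seq_len(nrow(merged)), function(i) {
    s <- sil[assign == i & !is.na(assign)]
    if (!length(s)) NA_real_ else mean(s)
  }, numeric(1))
  merged$score <- merged$covered_nt *
    pmax(ifelse(is.na(merged$silhouette), 0, merged$silhouette), 0)
  merged$category <- if (is.null(annotation)) NA_character_ else
    vapply(seq_len(nrow(merged)), function(i)
      categorize_macro(merged[i, ], annotation, tolerance), character(1))
  merged$macro_sized <- (merged$end - merged$start) >= min_length
  rownames(merged) <- NULL
  merged
}

#' Genomic-context category of a macroRNA region
#'
#' Decision cascade over the six categories: `P` (presumed primary
#' transcript: region start matches a coding gene's TSS and region end
#' that gene's terminus, both within `tolerance`), `ES` (joint start
#' with a coding gene but ends inside it), `I` (fully inside one gene
#' body, no exon overlap), `E` (overlaps >= 1 coding exon), `EN`
#' (overlaps non-coding exons only), `IG` (intergenic). The cascade is
#' total: regions with only partial, exon-free gene-body overlap fall
#' through to `IG`.
#'
#' @param region one-row interval `data.frame`.
#' @param annotation an [annotation_set()].
#' @param tolerance TSS/terminus matching tolerance (nt).
#' @return One of `"P"`, `"ES"`, `"I"`, `"E"`, `"EN"`, `"IG"`.
#' @export
categorize_macro <- function(region, annotation, tolerance = 5000) {
  stopifnot(inherits(annotation, "annotation_set"))
  iv <- region[1, c("chrom", "start", "end")]
  genes <- coding_gene_bodies(annotation)
  ep <- gene_endpoints(genes)
  ep <- ep[ep$chrom == iv$chrom, , drop = FALSE]
  if (nrow(ep)) {
    ## the region endpoint on the gene's 5' side must match the TSS
    r_tss <- ifelse(ep$strand == "-", iv$end, iv$start)
    r_term <- ifelse(ep$strand == "-", iv$start, iv$end)
    tss_match <- abs(r_tss - ep$tss) <= tolerance
    term_match <- abs(r_term - ep$terminus) <= tolerance
    if (any(tss_match & term_match)) return("P")
    end_inside <- r_term > ep$start & r_term < ep$end
    if (any(tss_match & end_inside)) return("ES")
  }
  bodies <- merge_intervals(genes)
  cex <- merge_intervals(coding_exons_of(annotation))
  ncex <- merge_intervals(noncoding_exons_of(annotation))
  w <- iv$end - iv$start
  ov_body <- overlap_nucleotides(iv, bodies)
  ov_cex <- overlap_nucleotides(iv, cex)
  ov_ncex <- overlap_nucleotides(iv, ncex)
  if (ov_body == w && ov_cex == 0 && ov_ncex == 0) return("I")
  if (ov_cex > 0) return("E")
  if (ov_ncex > 0) return("EN")
  "IG"
}

#' Run the full stairFinder detector
#'
#' Density estimation, peak finding, flooding, merging and scoring in
#' one call.
#'
#' @param segments interval `data.frame` of (DE-)segments.
#' @param bandwidth kernel bandwidth in nt (default 100000).
#' @param level flooding level in `[0, 1]` (default 0.5).
#' @param grid_step grid spacing (default `bandwidth/100`).
#' @param annotation optional [annotation_set()] for categories.
#' @param tolerance TSS/terminus tolerance (nt, default 5000).
#' @param min_length macroRNA size flag threshold (nt, default 1e4).
#' @return Scored region table (see [merge_and_score()]), ordered by
#'   decreasing score.
#' @export
stairfinder <- function(segments, bandwidth = 1e5, level = 0.5,
                        grid_step = bandwidth / 100, annotation = NULL,
                        tolerance = 5000, min_length = 1e4) {
  segments <- validate_intervals(segments)
  if (!nrow(segments))
    return(merge_and_score(empty_intervals(), segments, annotation,
                           tolerance, min_length))
  profile <- density_estimate(segments, bandwidth, grid_step)
  peaks <- find_peaks(profile)
  if (!nrow(peaks))
    return(merge_and_score(empty_intervals(), segments, annotation,
                           tolerance, min_length))
  flooded <- do.call(rbind, lapply(seq_len(nrow(peaks)), function(i)
    flood_boundaries(profile, peaks[i, ], level)))
  out <- merge_and_score(flooded, segments, annotation, tolerance,
                         min_length)
  out[order(-out$score), , drop = FALSE]
}
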