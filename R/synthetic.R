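#' Synthetic tiling-array genomes with planted ground truth
#'
#' The generator emulates the signal structure of a whole-genome tiling
#' experiment: a repeat-masked genome carrying multi-exon coding genes
#' and lncRNAs, probes tiled across the non-repeat space with
#' GC-dependent affinity, planted expressed and differential segments,
#' and planted macroRNAs whose extent is limited by polymerase speed and
#' whose signal decays towards the 3' end. Everything is a pure function
#' of (config, seed).
#'
#' @param chrom_sizes named numeric vector of chromosome lengths (nt).
#' @param n_genes number of protein-coding genes to plant.
#' @param mean_gene_span mean genomic span of a gene (nt).
#' @param exons_per_gene exons per coding gene.
#' @param n_lncrnas number of non-coding genes to plant.
#' @param repeat_fraction fraction of the genome covered by the repeat
#'   mask, in `[0, 1)`.
#' @param gap_fraction fraction covered by assembly gaps.
#' @param seed integer seed; fixed seed gives identical genomes.
#' @return A list of class `synthetic_genome` with `chrom_sizes` and an
#'   [annotation_set()] (genes, exons, repeats, gaps).
#' @export
generate_genome <- function(chrom_sizes, n_genes = 8, mean_gene_span = 2e4,
                            exons_per_gene = 4, n_lncrnas = 2,
                            repeat_fraction = 0.15, gap_fraction = 0.005,
                            seed = 1) {
  stopifnot(repeat_fraction >= 0, repeat_fraction < 1,
            gap_fraction >= 0, gap_fraction < 1,
            all(chrom_sizes > 0))
  if (is.null(names(chrom_sizes)))
    names(chrom_sizes) <- paste0("chr", seq_along(chrom_sizes))
  total <- sum(chrom_sizes)
  n_all <- n_genes + n_lncrnas
  if (n_all * mean_gene_span > total)
    stop(sprintf("infeasible config: %d genes of mean span %g nt exceed genome size %g nt",
                 n_all, mean_gene_span, total))

  withr_seed(seed, {
    ## allocate genes to chromosomes proportional to size, then lay each
    ## chromosome's genes end to end with uniformly partitioned gaps
    spans <- pmax(1000, round(mean_gene_span *
                                stats::rgamma(n_all, shape = 6, rate = 6)))
    ## rescale so the draw stays feasible for small genomes
    if (sum(spans) > 0.9 * total)
      spans <- pmax(1000, floor(spans * 0.9 * total / sum(spans)))
    coding <- c(rep(TRUE, n_genes), rep(FALSE, n_lncrnas))
    ord <- sample.int(n_all)
    spans <- spans[ord]; coding <- coding[ord]
    chrom_of <- sample(names(chrom_sizes), n_all, replace = TRUE,
                       prob = chrom_sizes / total)
    ## retry allocation if some chromosome overflows
    for (tries in 1:50) {
      load <- tapply(spans, factor(chrom_of, levels = names(chrom_sizes)), sum)
      load[is.na(load)] <- 0
      if (all(load <= 0.95 * chrom_sizes)) break
      chrom_of <- sample(names(chrom_sizes), n_all, replace = TRUE,
                         prob = chrom_sizes / total)
    }
    load <- tapply(spans, factor(chrom_of, levels = names(chrom_sizes)), sum)
    load[is.na(load)] <- 0
    if (any(load > chrom_sizes))
      stop("infeasible config: planted genes do not fit on the chromosomes")

    genes <- NULL
    exons <- NULL
    gid <- 0L
    for (chrom in names(chrom_sizes)) {
      idx <- which(chrom_of == chrom)
      if (!length(idx)) next
      free <- chrom_sizes[[chrom]] - sum(spans[idx])
      cuts <- sort(runif(length(idx)))
      gaps <- floor(diff(c(0, cuts, 1)) * free)
      pos <- 0
      for (k in seq_along(idx)) {
        pos <- pos + gaps[k]
        i <- idx[k]
        gid <- gid + 1L
        g_start <- pos; g_end <- pos + spans[i]
        strand <- sample(c("+", "-"), 1)
        id <- sprintf("gene%03d", gid)
        genes <- rbind(genes, data.frame(
          chrom = chrom, start = g_start, end = g_end, strand = strand,
          gene_id = id, coding = coding[i], stringsAsFactors = FALSE))
        k_ex <- if (coding[i]) exons_per_gene else sample(1:2, 1)
        exons <- rbind(exons, gene_exons(chrom, g_start, g_end, strand,
                                         id, k_ex, coding[i]))
        pos <- g_end
      }
    }
    repeats <- random_mask(chrom_sizes, repeat_fraction, mean_len = 800)
    gaps_iv <- random_mask(chrom_sizes, gap_fraction, mean_len = 2000)
    structure(list(chrom_sizes = chrom_sizes,
                   annotation = annotation_set(genes = genes, exons = exons,
                                               repeats = repeats,
                                               gaps = gaps_iv,
                                               name = "synthetic")),
              class = "synthetic_genome")
  })
}

## split a gene span into alternating exon/intron blocks (k exons)
gene_exons <- function(chrom, g_start, g_end, strand, gene_id, k, coding) {
  span <- g_end - g_start
  if (k == 1L || span < 2L * k)
    return(data.frame(chrom = chrom, start = g_start, end = g_end,
                      strand = strand, gene_id = gene_id, coding = coding,
                      stringsAsFactors = FALSE))
  nblk <- 2L * k - 1L
  cuts <- sort(sample.int(span - 1L, nblk - 1L))
  bounds <- c(0, cuts, span) + g_start
  odd <- seq(1L, nblk, by = 2L)
  data.frame(chrom = chrom, start = bounds[odd], end = bounds[odd + 1L],
             strand = strand, gene_id = gene_id, coding = coding,
             stringsAsFactors = FALSE)
}

## random interval mask covering ~fraction of each chromosome
random_mask <- function(chrom_sizes, fraction, mean_len) {
  if (fraction <= 0) return(empty_intervals())
  out <- empty_intervals()
  for (chrom in names(chrom_sizes)) {
    L <- chrom_sizes[[chrom]]
    target <- fraction * L
    acc <- empty_intervals()
    covered <- 0
    for (i in 1:10000) {
      if (covered >= target) break
      len <- max(50, round(stats::rexp(1, 1 / mean_len)))
      s <- floor(runif(1, 0, max(1, L - len)))
      acc <- merge_intervals(rbind(acc, intervals(chrom, s, min(L, s + len))))
      covered <- sum(interval_widths(acc))
    }
    out <- rbind(out, acc)
  }
  merge_intervals(out)
}

## run code under a fixed RNG state without disturbing the caller's
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Tile probes across the non-repeat space of a synthetic genome
#'
#' Probes of `probe_length` nt are laid at fixed `spacing` from position
#' 0 of each chromosome; probes overlapping the repeat mask or an
#' assembly gap by any nucleotide are dropped (those positions are
#' missing from a real tiling design). GC fractions are drawn per probe
#' from a Beta distribution.
#'
#' @param genome a `synthetic_genome`.
#' @param probe_length probe length in nt (default 25).
#' @param spacing distance between consecutive probe starts (default 35).
#' @param gc_shape two Beta shape parameters for the GC draw.
#' @param seed integer seed.
#' @return `data.frame` with `probe_id, chrom, start, length, gc`,
#'   sorted by chromosome and start.
#' @export
generate_probes <- function(genome, probe_length = 25, spacing = 35,
                            gc_shape = c(10, 10), seed = 1) {
  stopifnot(inherits(genome, "synthetic_genome"), spacing >= 1,
            probe_length >= 1)
  mask <- merge_intervals(rbind(genome$annotation$repeats,
                                genome$annotation$gaps))
  out <- NULL
  for (chrom in names(genome$chrom_sizes)) {
    L <- genome$chrom_sizes[[chrom]]
    if (L < probe_length) next
    starts <- seq(0, L - probe_length, by = spacing)
    iv <- intervals(chrom, starts, starts + probe_length)
    if (nrow(mask)) {
      hit <- GenomicRanges::countOverlaps(iv_to_gr(iv),
                                          iv_to_gr(mask),
                                          ignore.strand = TRUE) > 0
      iv <- iv[!hit, , drop = FALSE]
    }
    if (nrow(iv))
      out <- rbind(out, data.frame(chrom = chrom, start = iv$start,
                                   stringsAsFactors = FALSE))
  }
  if (is.null(out))
    return(data.frame(probe_id = character(), chrom = character(),
                      start = numeric(), length = numeric(), gc = numeric()))
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  n <- nrow(out)
  gc <- withr_seed(seed, rbeta(n, gc_shape[1], gc_shape[2]))
  data.frame(probe_id = sprintf("p%07d", seq_len(n)),
             chrom = out$chrom, start = out$start,
             length = probe_length, gc = gc,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Assemble a planted ground-truth set
#'
#' @param expressed `data.frame(condition, chrom, start, end, amplitude)`:
#'   additive log2 amplitude inside the segment for that condition.
#' @param differential `data.frame(contrast, condition_a, condition_b,
#'   chrom, start, end, effect)`: signed planted difference
#'   (condition_b minus condition_a). Every differential segment must lie
#'   inside the expressed segments of at least one of its two conditions.
#' @param macro `data.frame(chrom, start_site, length, strand,
#'   speed_kb_h, decay_per_kb, amplitude)`: macroRNAs elongating from
#'   `start_site` in the strand direction at `speed_kb_h`, with signal
#'   decaying linearly by `decay_per_kb` per kb from the start; length
#'   must be at least 1e4 nt.
#' @return List of class `truth_set`.
#' @export
truth_set <- function(expressed = NULL, differential = NULL, macro = NULL) {
  if (is.null(expressed))
    expressed <- data.frame(condition = character(), chrom = character(),
                            start = numeric(), end = numeric(),
                            amplitude = numeric())
  if (is.null(differential))
    differential <- data.frame(contrast = character(),
                               condition_a = character(),
                               condition_b = character(),
                               chrom = character(), start = numeric(),
                               end = numeric(), effect = numeric())
  if (is.null(macro))
    macro <- data.frame(chrom = character(), start_site = numeric(),
                        length = numeric(), strand = character(),
                        speed_kb_h = numeric(), decay_per_kb = numeric(),
                        amplitude = numeric())
  if (nrow(expressed)) validate_intervals(expressed)
  if (nrow(differential)) {
    validate_intervals(differential)
    for (i in seq_len(nrow(differential))) {
      d <- differential[i, ]
      ok <- FALSE
      for (cond in c(d$condition_a, d$condition_b)) {
        ex <- expressed[expressed$condition == cond, , drop = FALSE]
        if (nrow(ex) &&
            overlap_nucleotides(d[, c("chrom", "start", "end")], ex) ==
              d$end - d$start) { ok <- TRUE; break }
      }
      if (!ok)
        stop(sprintf("differential segment %s:%g-%g is not expressed in either condition of its contrast",
                     d$chrom, d$start, d$end))
    }
  }
  if (nrow(macro) && any(macro$length < 1e4))
    stop("planted macroRNAs must be at least 1e4 nt long")
  structure(list(expressed = expressed, differential = differential,
                 macro = macro), class = "truth_set")
}

#' Simulate per-probe log2 intensities under a planted truth
#'
#' Per condition, intensity = baseline + GC affinity term + planted
#' segment amplitude (probe start inside the segment) + macroRNA term +
#' Gaussian noise. The macroRNA term for a probe at distance `d` nt from
#' the macro start is `amplitude * max(0, 1 - decay_per_kb * d/1000)`
#' and is present only where the polymerase has arrived, i.e. where
#' `elapsed_h * speed_kb_h * 1000 >= d` (and `d < length`).
#'
#' @param probes probe table from [generate_probes()].
#' @param truth a [truth_set()].
#' @param conditions `data.frame(condition, time_h)`: elapsed induction
#'   time per condition; `Inf` means permanent induction, 0 means the
#'   macro is absent.
#' @param baseline baseline log2 intensity.
#' @param noise_sd Gaussian noise standard deviation (log2 units), > 0.
#' @param gc_effect linear GC affinity coefficient (log2 units per unit
#'   gc, centred at the mean gc).
#' @param seed integer seed.
#' @return `probes` with one additional numeric column per condition.
#' @export
simulate_intensities <- function(probes, truth, conditions,
                                 baseline = 6.0, noise_sd = 0.5,
                                 gc_effect = 0, seed = 1) {
  stopifnot(inherits(truth, "truth_set"), noise_sd > 0,
            all(c("condition", "time_h") %in% names(conditions)))
  n <- nrow(probes)
  gc_term <- if (n) gc_effect * (probes$gc - mean(probes$gc)) else numeric()
  out <- probes
  withr_seed(seed, {
    for (k in seq_len(nrow(conditions))) {
      cond <- conditions$condition[k]
      time_h <- conditions$time_h[k]
      mu <- rep(baseline, n) + gc_term
      ex <- truth$expressed[truth$expressed$condition == cond, , drop = FALSE]
      for (i in seq_len(nrow(ex))) {
        inside <- probes$chrom == ex$chrom[i] &
          probes$start >= ex$start[i] & probes$start < ex$end[i]
        mu[inside] <- mu[inside] + ex$amplitude[i]
      }
      ## differential truth is bookkeeping: planted differences arise
      ## from condition-specific expressed amplitudes, not a separate term
      mm <- truth$macro
      for (i in seq_len(nrow(mm))) {
        d <- if (mm$strand[i] == "-") mm$start_site[i] - probes$start
             else probes$start - mm$start_site[i]
        reach <- time_h * mm$speed_kb_h[i] * 1000
        inside <- probes$chrom == mm$chrom[i] & d >= 0 & d < mm$length[i] &
          d <= reach
        mu[inside] <- mu[inside] + mm$amplitude[i] *
          pmax(0, 1 - mm$decay_per_kb[i] * d[inside] / 1000)
      }
      out[[cond]] <- mu + rnorm(n, 0, noise_sd)
    }
  })
  out
}

#' Simulate a reference-platform probe table with known differential flags
#'
#' Emulates an independent custom array used to estimate the tiling
#' pipeline's FDR: each reference probe is flagged differentially
#' expressed with probability `1 - flip_rate` if it overlaps a true
#' differential segment of the contrast, and with probability
#' `flip_rate` otherwise.
#'
#' @param truth a [truth_set()].
#' @param contrast contrast label selecting the truth's differential
#'   segments.
#' @param probes probe table (`chrom`, `start`, `length`).
#' @param flip_rate flag error probability, in `[0, 0.5)`.
#' @param seed integer seed.
#' @return `data.frame(probe_id, chrom, start, length, de, true_de)`.
#' @export
generate_reference_platform <- function(truth, contrast, probes,
                                        flip_rate = 0, seed = 1) {
  stopifnot(inherits(truth, "truth_set"),
            flip_rate >= 0, flip_rate < 0.5)
  dd <- truth$differential[truth$differential$contrast == contrast, ,
                           drop = FALSE]
  piv <- intervals(probes$chrom, probes$start, probes$start + probes$length)
  true_de <- if (nrow(dd)) {
    GenomicRanges::countOverlaps(iv_to_gr(piv), iv_to_gr(dd),
                                 ignore.strand = TRUE) > 0
  } else rep(FALSE, nrow(probes))
  flip <- withr_seed(seed, runif(nrow(probes)) < flip_rate)
  data.frame(probe_id = if ("probe_id" %in% names(probes)) probes$probe_id
             else sprintf("r%07d", seq_len(nrow(probes))),
             chrom = probes$chrom, start = probes$start,
             length = probes$length,
             de = xor(true_de, flip), true_de = true_de,
             stringsAsFactors = FALSE)
}

#' Plant a random, internally consistent truth set on a genome
#'
#' Expressed segments are placed uniformly (disjointly) along the
#' genome; a fraction of them is made differential between the two
#' conditions of `contrast` by planting the segment in only one
#' condition with a signed effect.
#'
#' @param genome a `synthetic_genome`.
#' @param conditions character vector of exactly two condition names.
#' @param n_segments number of expressed segments.
#' @param frac_differential fraction of segments that are differential.
#' @param len_range segment length range (nt).
#' @param amplitude planted expression amplitude (log2 units).
#' @param seed integer seed.
#' @return A [truth_set()].
#' @export
random_truth <- function(genome, conditions = c("A", "B"), n_segments = 10,
                         frac_differential = 0.5, len_range = c(4000, 12000),
                         amplitude = 3.0, seed = 1) {
  stopifnot(length(conditions) == 2)
  space <- do.call(rbind, lapply(names(genome$chrom_sizes), function(ch)
    intervals(ch, 0, genome$chrom_sizes[[ch]])))
  withr_seed(seed, {
    lens <- round(runif(n_segments, len_range[1], len_range[2]))
    segs <- place_random_intervals(space, lens, disjoint = TRUE,
                                   min_gap = 5000)
    is_diff <- seq_len(n_segments) <= round(frac_differential * n_segments)
    sign_eff <- sample(c(-1, 1), n_segments, replace = TRUE)
    expressed <- NULL; differential <- NULL
    contrast <- paste0(conditions[2], "-", conditions[1])
    for (i in seq_len(n_segments)) {
      if (!is_diff[i]) {
        expressed <- rbind(expressed,
          data.frame(condition = conditions, chrom = segs$chrom[i],
                     start = segs$start[i], end = segs$end[i],
                     amplitude = amplitude, stringsAsFactors = FALSE))
      } else {
        cond_on <- if (sign_eff[i] > 0) conditions[2] else conditions[1]
        expressed <- rbind(expressed,
          data.frame(condition = cond_on, chrom = segs$chrom[i],
                     start = segs$start[i], end = segs$end[i],
                     amplitude = amplitude, stringsAsFactors = FALSE))
        differential <- rbind(differential,
          data.frame(contrast = contrast, condition_a = conditions[1],
                     condition_b = conditions[2], chrom = segs$chrom[i],
                     start = segs$start[i], end = segs$end[i],
                     effect = sign_eff[i] * amplitude,
                     stringsAsFactors = FALSE))
      }
    }
    truth_set(expressed = expressed, differential = differential)
  })
}

## Uniform placement of intervals of given lengths within `space`,
## optionally mutually disjoint. Errors if a length fits nowhere.
## Uses the caller's RNG state.
place_random_intervals <- function(space, lengths, disjoint = FALSE,
                                   min_gap = 0) {
  space <- merge_intervals(space)
  out <- empty_intervals()
  for (L in lengths) {
    w <- interval_widths(space)
    ok <- which(w >= L)
    if (!length(ok))
      stop(sprintf("no feasible placement for an interval of length %g nt", L))
    slots <- w[ok] - L + 1
    pick <- ok[sample.int(length(ok), 1, prob = slots)]
    off <- floor(runif(1, 0, space$end[pick] - space$start[pick] - L + 1))
    s <- space$start[pick] + off
    out <- rbind(out, intervals(space$chrom[pick], s, s + L))
    if (disjoint)
      space <- subtract_intervals(space,
        intervals(space$chrom[pick], max(0, s - min_gap), s + L + min_gap))
  }
  out
}
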