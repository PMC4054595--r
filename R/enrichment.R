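#' Annotation-overlap enrichment against randomized backgrounds
#'
#' The observed nucleotide overlap of a query segment set with an
#' annotation is compared to N randomized background lists that
#' preserve the query's interval length multiset and avoid assembly
#' gaps and repeats. Odds are overlap versus non-overlap nucleotides;
#' the odds ratio divides the observed odds by the mean background
#' odds; significance comes from Fisher's exact test on the pooled
#' 2x2 nucleotide table.
#'
#' @name enrichment-module
NULL

#' Sample randomized background interval lists
#'
#' Each list contains exactly the query's multiset of interval lengths.
#' Every background interval lies inside the sampling space minus the
#' exclusions, uniformly over all feasible placements. Intervals within
#' one list may overlap each other (the observed query is used merged,
#' backgrounds mirror the query's length distribution only).
#'
#' @param query interval `data.frame` whose lengths are reproduced.
#' @param space sampling space (e.g. whole genome, or intergenic /
#'   intronic space for queries restricted to those).
#' @param exclusions intervals never overlapped (assembly gaps,
#'   repeats); may be empty.
#' @param n_lists number of background lists N (default 100).
#' @param seed integer seed.
#' @return List of `n_lists` interval `data.frame`s.
#' @export
sample_background <- function(query, space, exclusions = NULL,
                              n_lists = 100, seed = 1) {
  stopifnot(n_lists >= 1)
  query <- validate_intervals(query)
  if (is.null(exclusions)) exclusions <- empty_intervals()
  allowed <- subtract_intervals(merge_intervals(space), exclusions)
  lengths <- query$end - query$start
  withr_seed(seed, {
    lapply(seq_len(n_lists), function(i)
      place_random_intervals(allowed, lengths, disjoint = FALSE))
  })
}

#' Odds ratio of observed versus background overlap
#'
#' `odds_obs = ov_obs / (n_obs - ov_obs)`;
#' `odds_bg = mean_i(ov_bg_i) / mean_i(n_bg_i - ov_bg_i)`;
#' `odds_ratio = odds_obs / odds_bg`. If any of the four cells
#' (observed overlap / non-overlap, mean background overlap /
#' non-overlap) is zero, the Haldane-Anscombe correction adds 0.5 to
#' all four and the result is flagged.
#'
#' @param ov_obs overlapping nucleotides of the query.
#' @param n_obs total unique query nucleotides (> 0).
#' @param ov_bg,n_bg numeric vectors: per-background-list overlapping
#'   and total nucleotides.
#' @return List with `odds_obs`, `odds_bg`, `odds_ratio`, the four
#'   (possibly corrected) `cells`, and `zero_cell`.
#' @export
odds_ratio_stats <- function(ov_obs, n_obs, ov_bg, n_bg) {
  stopifnot(n_obs > 0, length(ov_bg) == length(n_bg), length(ov_bg) >= 1,
            ov_obs >= 0, ov_obs <= n_obs, all(ov_bg >= 0),
            all(ov_bg <= n_bg))
  cells <- c(ov_obs = ov_obs, rest_obs = n_obs - ov_obs,
             ov_bg = mean(ov_bg), rest_bg = mean(n_bg - ov_bg))
  zero_cell <- any(cells == 0)
  if (zero_cell) cells <- cells + 0.5
  odds_obs <- cells[["ov_obs"]] / cells[["rest_obs"]]
  odds_bg <- cells[["ov_bg"]] / cells[["rest_bg"]]
  list(odds_obs = odds_obs, odds_bg = odds_bg,
       odds_ratio = odds_obs / odds_bg, cells = cells,
       zero_cell = zero_cell)
}

#' Fisher's exact test on the pooled overlap table
#'
#' Two-sided exact test on
#' `[[ov_obs, n_obs - ov_obs], [ov_bg, n_bg - ov_bg]]` with the
#' background cells the rounded means over the N lists; the p-value
#' sums hypergeometric probabilities not exceeding that of the
#' observed table, and the 95% CI for the odds ratio comes from the
#' conditional-likelihood inversion of [stats::fisher.test()].
#' Degenerate margins (an all-zero row or column) give `p = 1` and an
#' undefined CI.
#'
#' @param ov_obs,n_obs observed overlap / total nucleotides.
#' @param ov_bg,n_bg background cell values (means over lists; rounded
#'   internally).
#' @return List with `p`, `ci95` (length 2), `method`.
#' @export
fisher_overlap_test <- function(ov_obs, n_obs, ov_bg, n_bg) {
  tab <- matrix(round(c(ov_obs, n_obs - ov_obs, ov_bg, n_bg - ov_bg)),
                nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(p = 1, ci95 = c(NA_real_, NA_real_),
                method = "degenerate-margin"))
  ft <- fisher.test(tab, conf.int = TRUE, conf.level = 0.95)
  list(p = ft$p.value, ci95 = as.numeric(ft$conf.int),
       method = "fisher-exact-conditional-mle")
}

significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                                  ifelse(p < 0.05, "*", "")))
}

#' Per-annotation overlap enrichment report
#'
#' Computes observed and background overlaps, odds ratios with 95% CI,
#' Fisher p-values and significance stars (`*** p<0.001`, `** p<0.01`,
#' `* p<0.05`) for a query segment set against a collection of named
#' annotation interval sets. One shared set of background lists is used
#' for all annotations.
#'
#' @param query interval `data.frame` (merged internally).
#' @param annotations named list of interval `data.frame`s.
#' @param space sampling space for backgrounds.
#' @param exclusions intervals excluded from background placement.
#' @param n_lists number of background lists (default 100).
#' @param seed integer seed.
#' @return `data.frame` with one row per annotation: `annotation,
#'   ov_obs, n_obs, ov_bg_mean, n_bg_mean, odds_ratio, log2_or, ci_lo,
#'   ci_hi, p, stars, zero_cell`.
#' @export
enrichment_report <- function(query, annotations, space,
                              exclusions = NULL, n_lists = 100, seed = 1) {
  stopifnot(length(names(annotations)) == length(annotations))
  q <- merge_intervals(query)
  n_obs <- sum(interval_widths(q))
  bg <- sample_background(q, space, exclusions, n_lists, seed)
  n_bg <- vapply(bg, covered_nucleotides, numeric(1))
  rows <- lapply(names(annotations), function(nm) {
    ann <- merge_intervals(annotations[[nm]])
    ov_obs <- overlap_nucleotides(q, ann)
    ov_bg <- vapply(bg, function(b) overlap_nucleotides(b, ann),
                    numeric(1))
    os <- odds_ratio_stats(ov_obs, n_obs, ov_bg, n_bg)
    ft <- fisher_overlap_test(ov_obs, n_obs, mean(ov_bg),
                              mean(n_bg))
    data.frame(annotation = nm, ov_obs = ov_obs, n_obs = n_obs,
               ov_bg_mean = mean(ov_bg), n_bg_mean = mean(n_bg),
               odds_ratio = os$odds_ratio,
               log2_or = log2(os$odds_ratio),
               ci_lo = ft$ci95[1], ci_hi = ft$ci95[2],
               p = ft$p, stars = significance_stars(ft$p),
               zero_cell = os$zero_cell, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
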