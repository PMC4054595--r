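#' Coding-evidence layers for the bona fide non-coding filter
#'
#' Bundles the interval layers consumed by [bona_fide_filter()]. Every
#' layer must be passed explicitly; an empty interval table is a legal
#' "no evidence" layer (so fully synthetic runs work), but a missing
#' one is an error naming the layer. `rnacode_hits` must lie inside
#' `rnacode_covered` (a protein-coding call requires an evaluable
#' alignment).
#'
#' @param coding_exons exons of known protein-coding transcript
#'   isoforms (UTRs included).
#' @param pseudogene_exons known pseudogene exons.
#' @param rnacode_hits precomputed protein-coding segments (P < 0.05).
#' @param rnacode_covered regions the coding-potential screen could
#'   evaluate at all.
#' @param tblastn_hits precomputed protein-similarity hits (e < 0.05).
#' @return List of class `coding_evidence`.
#' @export
coding_evidence <- function(coding_exons, pseudogene_exons, rnacode_hits,
                            rnacode_covered, tblastn_hits) {
  layers <- list(coding_exons = coding_exons,
                 pseudogene_exons = pseudogene_exons,
                 rnacode_hits = rnacode_hits,
                 rnacode_covered = rnacode_covered,
                 tblastn_hits = tblastn_hits)
  for (nm in names(layers)) {
    if (is.null(layers[[nm]]) || missing_arg_null(layers[[nm]]))
      stop("missing coding-evidence layer: ", nm,
           " (pass an empty interval table for 'no evidence')")
    layers[[nm]] <- validate_intervals(layers[[nm]])
  }
  hits_nt <- covered_nucleotides(layers$rnacode_hits)
  if (hits_nt > 0 &&
      overlap_nucleotides(layers$rnacode_hits, layers$rnacode_covered) <
        hits_nt)
    stop("rnacode_hits extend outside rnacode_covered")
  structure(layers, class = "coding_evidence")
}

missing_arg_null <- function(x) is.null(x)

#' Reduce segments to bona fide non-coding intervals
#'
#' Applies, in order: (i) subtract nucleotides of protein-coding and
#' pseudogene exons; (ii) subtract predicted protein-coding segments;
#' (iii) among nucleotides the coding-potential screen could not
#' evaluate, subtract protein-similarity hits; (iv) discard remaining
#' intervals shorter than `min_len` (default 17 nt - the smallest known
#' human ncRNA species are 17-18 nt). Survivors are classified as
#' intergenic or intronic relative to the gene annotation.
#'
#' @param segments interval `data.frame` (TARs or DE-TARs); merged
#'   internally.
#' @param evidence a [coding_evidence()].
#' @param annotation an [annotation_set()] providing gene bodies and
#'   exons for the intergenic/intronic classification.
#' @param min_len minimal surviving interval length (nt, >= 1).
#' @return Interval `data.frame` with a `class` column
#'   (`"intergenic"`/`"intronic"`).
#' @export
bona_fide_filter <- function(segments, evidence, annotation, min_len = 17) {
  stopifnot(inherits(evidence, "coding_evidence"),
            inherits(annotation, "annotation_set"), min_len >= 1)
  x <- merge_intervals(segments)
  if (!nrow(x)) return(cbind(x, data.frame(class = character())))
  ## (i) known coding and pseudogene exons
  x <- subtract_intervals(x, rbind(
    evidence$coding_exons[, c("chrom", "start", "end")],
    evidence$pseudogene_exons[, c("chrom", "start", "end")]))
  ## (ii) predicted protein-coding segments
  x <- subtract_intervals(x, evidence$rnacode_hits)
  ## (iii) protein similarity, only where coding potential was unassessable
  tb_uncovered <- subtract_intervals(evidence$tblastn_hits,
                                     evidence$rnacode_covered)
  x <- subtract_intervals(x, tb_uncovered)
  ## (iv) minimum length
  if (nrow(x)) x <- x[x$end - x$start >= min_len, , drop = FALSE]
  rownames(x) <- NULL
  if (!nrow(x)) return(cbind(x, data.frame(class = character())))
  x$class <- classify_relative_to_genes(x, annotation)
  x
}

#' Classify intervals relative to protein-coding genes
#'
#' Intergenic: no protein-coding gene-body overlap. Intronic: inside a
#' gene body with no protein-coding exon overlap. Intervals touching a
#' protein-coding exon are `"exon-overlapping"`. Gene-boundary
#' straddlers (gene-body overlap, no exon overlap, partially
#' intergenic) take the class covering the majority of their
#' nucleotides; ties go to intronic.
#'
#' @param x interval `data.frame`.
#' @param annotation an [annotation_set()].
#' @return Character vector (`"intergenic"`, `"intronic"`,
#'   `"exon-overlapping"`), one per row of `x`.
#' @export
classify_relative_to_genes <- function(x, annotation) {
  x <- validate_intervals(x)
  if (!nrow(x)) return(character())
  bodies <- merge_intervals(coding_gene_bodies(annotation))
  cexons <- merge_intervals(coding_exons_of(annotation))
  vapply(seq_len(nrow(x)), function(i) {
    iv <- x[i, c("chrom", "start", "end")]
    w <- iv$end - iv$start
    ov_body <- overlap_nucleotides(iv, bodies)
    if (ov_body == 0) return("intergenic")
    if (overlap_nucleotides(iv, cexons) > 0) return("exon-overlapping")
    if (ov_body == w) return("intronic")
    ## straddler: majority nucleotide class, ties -> intronic
    if (ov_body >= w - ov_body) "intronic" else "intergenic"
  }, character(1))
}
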