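#' Genomic interval tables
#'
#' Intervals throughout the package are plain `data.frame`s in BED
#' convention: 0-based, half-open `[start, end)` coordinates with columns
#' `chrom`, `start`, `end` and optionally `strand`, `name`, `score`.
#' Interval algebra is delegated to GenomicRanges/IRanges internally;
#' these helpers convert at the boundary so file I/O and user-facing
#' tables stay in BED coordinates bit-exactly.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer-like 0-based half-open coordinates.
#' @param strand optional strand vector (`"+"`, `"-"`, `"*"`).
#' @param ... further equal-length columns (e.g. `name`, `score`).
#' @return A validated interval `data.frame`.
#' @examples
#' intervals("chr1", 0, 100)
#' @export
intervals <- function(chrom, start, end, strand = NULL, ...) {
  x <- data.frame(chrom = as.character(chrom),
                  start = as.numeric(start),
                  end = as.numeric(end),
                  stringsAsFactors = FALSE)
  if (!is.null(strand)) x$strand <- as.character(strand)
  extra <- list(...)
  for (nm in names(extra)) x[[nm]] <- extra[[nm]]
  validate_intervals(x)
}

#' Validate an interval table
#'
#' Checks the `[start, end)` convention: `start >= 0` and `end > start`
#' for every record. Errors name the first offending record.
#'
#' @param x interval `data.frame`.
#' @return `x`, invisibly unchanged (rows in input order).
#' @export
validate_intervals <- function(x) {
  stopifnot(is.data.frame(x))
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("interval table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(x)) {
    bad <- which(!(x$start >= 0 & x$end > x$start))
    if (length(bad)) {
      i <- bad[1L]
      stop(sprintf("malformed interval at record %d: %s:%s-%s (need start >= 0, end > start)",
                   i, x$chrom[i], format(x$start[i]), format(x$end[i])))
    }
  }
  x
}

empty_intervals <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             stringsAsFactors = FALSE)
}

## ---- GRanges bridge (1-based closed <-> 0-based half-open) ----

iv_to_gr <- function(x) {
  x <- validate_intervals(x)
  strand <- if ("strand" %in% names(x)) {
    s <- x$strand
    s[!s %in% c("+", "-")] <- "*"
    s
  } else "*"
  GenomicRanges::GRanges(seqnames = x$chrom,
                         ranges = IRanges::IRanges(start = x$start + 1,
                                                   end = x$end),
                         strand = strand)
}

gr_to_iv <- function(gr) {
  if (length(gr) == 0L) return(empty_intervals())
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = as.numeric(GenomicRanges::start(gr)) - 1,
                    end = as.numeric(GenomicRanges::end(gr)),
                    stringsAsFactors = FALSE)
  s <- as.character(GenomicRanges::strand(gr))
  if (any(s != "*")) out$strand <- s
  rownames(out) <- NULL
  out
}

sort_intervals <- function(x) {
  x <- validate_intervals(x)
  x[order(x$chrom, x$start, x$end), , drop = FALSE]
}

#' Merge overlapping intervals
#'
#' Intervals overlapping by at least one nucleotide are merged into
#' maximal disjoint intervals; bookended intervals (`end == start` of the
#' next) are deliberately left separate, matching the overlap semantics
#' used when significant windows are summarized to segments. Strand is
#' ignored.
#'
#' @param x interval `data.frame`.
#' @return Sorted, disjoint interval `data.frame` covering the same
#'   nucleotides as `x`.
#' @examples
#' merge_intervals(intervals("chr1", c(0, 50), c(100, 150)))
#' @export
merge_intervals <- function(x) {
  x <- validate_intervals(x)
  if (!nrow(x)) return(empty_intervals())
  gr <- GenomicRanges::reduce(iv_to_gr(x), min.gapwidth = 0L,
                              ignore.strand = TRUE)
  gr_to_iv(GenomicRanges::sort(gr, ignore.strand = TRUE))
}

#' Subtract one interval set from another
#'
#' Returns the nucleotides of `a` not covered by `b`, as maximal
#' intervals (strand-blind coverage semantics).
#'
#' @param a,b interval `data.frame`s.
#' @return Interval `data.frame`.
#' @examples
#' subtract_intervals(intervals("chr1", 0, 100), intervals("chr1", 40, 60))
#' @export
subtract_intervals <- function(a, b) {
  a <- validate_intervals(a); b <- validate_intervals(b)
  if (!nrow(a)) return(empty_intervals())
  if (!nrow(b)) return(merge_intervals(a))
  ## suppressed warning: disjoint seqlevel sets are a legitimate input
  gr <- suppressWarnings(
    GenomicRanges::setdiff(iv_to_gr(a), iv_to_gr(b), ignore.strand = TRUE))
  gr_to_iv(GenomicRanges::sort(gr, ignore.strand = TRUE))
}

intersect_intervals <- function(a, b) {
  a <- validate_intervals(a); b <- validate_intervals(b)
  if (!nrow(a) || !nrow(b)) return(empty_intervals())
  gr <- suppressWarnings(
    GenomicRanges::intersect(iv_to_gr(a), iv_to_gr(b),
                             ignore.strand = TRUE))
  gr_to_iv(GenomicRanges::sort(gr, ignore.strand = TRUE))
}

#' Count nucleotides of overlap between two interval sets
#'
#' Coverage-based: both sides are merged first, so no nucleotide is
#' counted twice.
#'
#' @param a,b interval `data.frame`s.
#' @return Number of nucleotides covered by both `a` and `b`.
#' @examples
#' overlap_nucleotides(intervals("chr1", 0, 100), intervals("chr1", 50, 150))
#' @export
overlap_nucleotides <- function(a, b) {
  sum(interval_widths(intersect_intervals(a, b)))
}

interval_widths <- function(x) {
  x <- validate_intervals(x)
  if (!nrow(x)) return(numeric())
  x$end - x$start
}

#' Total unique nucleotides covered by an interval set
#' @param x interval `data.frame`.
#' @return Number of covered nucleotides (after merging).
#' @export
covered_nucleotides <- function(x) sum(interval_widths(merge_intervals(x)))

## ---- file I/O ----

#' Read / write BED files
#'
#' Thin wrappers over rtracklayer keeping the package's 0-based
#' half-open `data.frame` convention. `write_bed` emits BED3 unless
#' `name`/`score`/`strand` columns are present (then BED6).
#'
#' @param path file path.
#' @param x interval `data.frame` for writing.
#' @return `read_bed` returns an interval `data.frame` (with `name`,
#'   `score`, `strand` columns when present in the file).
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import.bed(path)
  out <- gr_to_iv(gr)
  if (length(gr)) {
    md <- S4Vectors::mcols(gr)
    if (!is.null(md$name)) out$name <- as.character(md$name)
    if (!is.null(md$score)) out$score <- as.numeric(md$score)
  }
  out
}

#' @rdname read_bed
#' @export
write_bed <- function(x, path) {
  x <- validate_intervals(x)
  if (!nrow(x)) { file.create(path); return(invisible(path)) }
  gr <- iv_to_gr(x)
  if ("name" %in% names(x)) S4Vectors::mcols(gr)$name <- as.character(x$name)
  if ("score" %in% names(x)) S4Vectors::mcols(gr)$score <- as.numeric(x$score)
  rtracklayer::export.bed(gr, path)
  invisible(path)
}

#' Read a two-column chromosome-sizes file
#' @param path TSV with columns chromosome name and length.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  tab <- read.table(path, sep = "\t", header = FALSE,
                    col.names = c("chrom", "size"),
                    colClasses = c("character", "numeric"))
  setNames(tab$size, tab$chrom)
}

#' Read gene models from GFF3 into an annotation set
#'
#' Imports `gene`, `exon` and `CDS` features; a gene is called coding if
#' it has at least one CDS feature (resolved through exon/transcript
#' parents). Coordinates are converted to the package's 0-based
#' half-open convention on read.
#'
#' @param path GFF3 file.
#' @param name label for the annotation source.
#' @return An `annotation_set` (see [annotation_set()]).
#' @export
read_gff_genes <- function(path, name = basename(path)) {
  gr <- rtracklayer::import.gff3(path)
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  first_parent <- function(p) {
    vapply(p, function(v) if (length(v)) as.character(v[[1]]) else NA_character_,
           character(1))
  }
  ids <- as.character(md$ID)
  parents <- if (!is.null(md$Parent)) first_parent(md$Parent) else
    rep(NA_character_, length(gr))
  ## map any feature to its top-level gene id
  to_gene <- function(id) {
    seen <- character()
    while (!is.na(id) && id %in% ids) {
      i <- match(id, ids)
      if (type[i] == "gene") return(id)
      if (id %in% seen) return(NA_character_)
      seen <- c(seen, id)
      id <- parents[i]
    }
    NA_character_
  }
  feat_gene <- vapply(seq_along(gr), function(i) {
    if (type[i] == "gene") ids[i] else to_gene(parents[i])
  }, character(1))

  gi <- type == "gene"
  genes <- gr_to_iv(gr[gi])
  genes$strand <- as.character(GenomicRanges::strand(gr[gi]))
  genes$gene_id <- ids[gi]
  cds_genes <- unique(feat_gene[type == "CDS"])
  genes$coding <- genes$gene_id %in% cds_genes

  ei <- type == "exon"
  exons <- gr_to_iv(gr[ei])
  if (nrow(exons)) {
    exons$strand <- as.character(GenomicRanges::strand(gr[ei]))
    exons$gene_id <- feat_gene[ei]
    exons$coding <- exons$gene_id %in% cds_genes
  } else {
    exons <- data.frame(chrom = character(), start = numeric(),
                        end = numeric(), strand = character(),
                        gene_id = character(), coding = logical())
  }
  annotation_set(genes = genes, exons = exons, name = name)
}

#' Construct an annotation set
#'
#' Bundles gene bodies, exons and optional repeat/assembly-gap masks.
#' `genes` needs columns `chrom,start,end,strand,gene_id,coding`;
#' `exons` the same plus membership via `gene_id`.
#'
#' @param genes,exons interval `data.frame`s as described.
#' @param repeats,gaps optional plain interval `data.frame`s.
#' @param name label of the annotation source.
#' @return List of class `annotation_set`.
#' @export
annotation_set <- function(genes, exons, repeats = NULL, gaps = NULL,
                           name = "annotation") {
  genes <- validate_intervals(genes)
  exons <- if (nrow(exons)) validate_intervals(exons) else exons
  stopifnot(all(c("gene_id", "coding", "strand") %in% names(genes)))
  if (nrow(exons)) stopifnot(all(c("gene_id", "coding") %in% names(exons)))
  if (is.null(repeats)) repeats <- empty_intervals()
  if (is.null(gaps)) gaps <- empty_intervals()
  structure(list(name = name,
                 genes = sort_intervals(genes),
                 exons = if (nrow(exons)) sort_intervals(exons) else exons,
                 repeats = merge_intervals(repeats),
                 gaps = merge_intervals(gaps)),
            class = "annotation_set")
}

#' Annotation accessors
#'
#' Convenience extractors over an [annotation_set()]: protein-coding
#' gene bodies, protein-coding exons and non-coding exons.
#'
#' @param ann an [annotation_set()].
#' @return Interval `data.frame`s.
#' @export
coding_gene_bodies <- function(ann) {
  ann$genes[ann$genes$coding, , drop = FALSE]
}

#' @rdname coding_gene_bodies
#' @export
coding_exons_of <- function(ann) {
  if (!nrow(ann$exons)) return(empty_intervals())
  ann$exons[ann$exons$coding, , drop = FALSE]
}

#' @rdname coding_gene_bodies
#' @export
noncoding_exons_of <- function(ann) {
  if (!nrow(ann$exons)) return(empty_intervals())
  ann$exons[!ann$exons$coding, , drop = FALSE]
}

## 5' start (TSS) and 3' terminus per gene, strand-aware
gene_endpoints <- function(genes) {
  tss <- ifelse(genes$strand == "-", genes$end, genes$start)
  term <- ifelse(genes$strand == "-", genes$start, genes$end)
  data.frame(chrom = genes$chrom, gene_id = genes$gene_id,
             strand = genes$strand, tss = tss, terminus = term,
             start = genes$start, end = genes$end,
             coding = genes$coding, stringsAsFactors = FALSE)
}
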