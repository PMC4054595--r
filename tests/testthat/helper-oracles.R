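# Independent oracles and shared fixtures for the test suite.

## all permutations of 1..n as a matrix (rows = permutations); n <= 8
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- NULL
  for (k in seq_len(n)) {
    block <- cbind(k, ifelse(sub >= k, sub + 1L, sub))
    out <- rbind(out, block)
  }
  unname(out)
}

## exhaustive pooled-null empirical p-values by enumerating every
## permutation of y (single GC bin), for the given window index ranges
exhaustive_p <- function(y, first, last, type = "expressed") {
  score_fun <- function(v) {
    if (type == "expressed")
      tilestair:::cpp_trimmed_scores(v, as.integer(first), as.integer(last))
    else abs(tilestair:::cpp_diff_scores(v, as.integer(first),
                                         as.integer(last))$score)
  }
  obs <- score_fun(y)
  perms <- all_permutations(length(y))
  null <- as.numeric(apply(perms, 1, function(ix) score_fun(y[ix])))
  vapply(obs, function(o) (1 + sum(null >= o)) / (1 + length(null)),
         numeric(1))
}

## two-sided Fisher p by exhaustive hypergeometric enumeration
fisher_p_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

## random non-degenerate interval table for property tests
random_interval_set <- function(n, max_pos = 10000, chroms = c("chr1", "chr2")) {
  s <- sample.int(max_pos, n, replace = TRUE) - 1L
  w <- sample.int(500, n, replace = TRUE)
  intervals(sample(chroms, n, replace = TRUE), s, s + w)
}

## a tiny two-gene annotation used across filter/categorize tests:
## coding gene1 chr1:1000-5000 (+, exons 1000-1500 and 4500-5000),
## non-coding gene2 chr1:8000-9000 (+, one exon)
toy_annotation <- function() {
  genes <- data.frame(chrom = "chr1", start = c(1000, 8000),
                      end = c(5000, 9000), strand = "+",
                      gene_id = c("gene1", "gene2"),
                      coding = c(TRUE, FALSE), stringsAsFactors = FALSE)
  exons <- data.frame(chrom = "chr1",
                      start = c(1000, 4500, 8000),
                      end = c(1500, 5000, 9000), strand = "+",
                      gene_id = c("gene1", "gene1", "gene2"),
                      coding = c(TRUE, TRUE, FALSE),
                      stringsAsFactors = FALSE)
  annotation_set(genes = genes, exons = exons)
}

empty_evidence <- function() {
  e <- tilestair:::empty_intervals()
  coding_evidence(coding_exons = e, pseudogene_exons = e,
                  rnacode_hits = e, rnacode_covered = e, tblastn_hits = e)
}

## shared planted scenario (built once per test run): 3-Mb genome,
## ~1% expressed per condition at the generator's default amplitude
## (3.0 log2 units = 6 x noise sd, comfortably above the 4-sd regime)
.scenario_cache <- new.env(parent = emptyenv())
planted_scenario <- function() {
  if (!is.null(.scenario_cache$sc)) return(.scenario_cache$sc)
  noise_sd <- 0.5
  genome <- generate_genome(c(chr1 = 1.5e6, chr2 = 1.5e6), n_genes = 14,
                            mean_gene_span = 12000, seed = 11)
  probes <- generate_probes(genome, seed = 12)
  truth <- random_truth(genome, c("A", "B"), n_segments = 8,
                        frac_differential = 0.5,
                        len_range = c(5000, 9000),
                        amplitude = 3.0, seed = 13)
  conds <- data.frame(condition = c("A", "B"), time_h = Inf)
  probes <- simulate_intensities(probes, truth, conds,
                                 noise_sd = noise_sd, gc_effect = 1,
                                 seed = 14)
  resA <- segment_expressed(probes, "A", n_permutations = 60, seed = 15)
  resB <- segment_expressed(probes, "B", n_permutations = 60, seed = 15)
  dres <- segment_differential(probes, "A", "B",
                               list(A = resA$tars, B = resB$tars),
                               n_permutations = 400, seed = 16)
  sc <- list(genome = genome, probes = probes, truth = truth,
             noise_sd = noise_sd, resA = resA, resB = resB, dres = dres,
             mask = rbind(genome$annotation$repeats,
                          genome$annotation$gaps))
  .scenario_cache$sc <- sc
  sc
}
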