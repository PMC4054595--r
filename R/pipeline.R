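#' Default pipeline configuration
#'
#' Stage parameters default to the values used throughout the package:
#' 200-nt windows, q<0.05 expression / q<0.005 differential thresholds,
#' 10,000 / 100,000 permutations with 4 / 1 GC classes, 17-nt minimum
#' bona fide interval, stairFinder bandwidth 100,000 at 50% flooding
#' with the 1e4-nt macroRNA size flag, and 100 background lists for the
#' enrichment stage. The synthetic scenario is sized for a quick
#' end-to-end run.
#'
#' @param seed global seed; per-stage seeds are derived as
#'   `seed + stage index` so stages are independently rerunnable.
#' @return Nested configuration list.
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    genome = list(chrom_sizes = c(chr1 = 1e6), n_genes = 8,
                  mean_gene_span = 10000, exons_per_gene = 3,
                  n_lncrnas = 2, repeat_fraction = 0.1,
                  gap_fraction = 0.005),
    probes = list(probe_length = 25, spacing = 35),
    truth = list(n_segments = 5, frac_differential = 0.6,
                 len_range = c(2000, 4000), amplitude = 3.0),
    signal = list(baseline = 6.0, noise_sd = 0.5, gc_effect = 1.0,
                  conditions = c("A", "B")),
    segmentation = list(window_size = 200, min_probes = 3,
                        q_expressed = 0.05, q_differential = 0.005,
                        permutations_expressed = 10000,
                        permutations_differential = 100000,
                        gc_classes_expressed = 4,
                        gc_classes_differential = 1),
    filter = list(min_len = 17),
    stairfinder = list(bandwidth = 1e5, level = 0.5, grid_step = 1000,
                       min_length = 1e4, tolerance = 5000),
    enrichment = list(n_backgrounds = 100),
    validation = list(flip_rate = 0, n_decay_bins = 10)
  )
}

#' Validate a pipeline configuration
#'
#' Checks every parameter against its documented domain; errors before
#' any stage runs.
#'
#' @param config configuration list (see [default_config()]).
#' @return `config`, invisibly.
#' @export
validate_config <- function(config) {
  chk <- function(ok, what) if (!ok) stop("invalid config: ", what)
  s <- config$segmentation
  chk(s$q_expressed > 0 && s$q_expressed <= 1, "q_expressed must be in (0, 1]")
  chk(s$q_differential > 0 && s$q_differential <= 1,
      "q_differential must be in (0, 1]")
  chk(s$window_size >= 1, "window_size must be >= 1")
  chk(s$min_probes >= 1, "min_probes must be >= 1")
  chk(s$permutations_expressed >= 1 && s$permutations_differential >= 1,
      "permutation counts must be >= 1")
  chk(s$gc_classes_expressed >= 1 && s$gc_classes_differential >= 1,
      "GC class counts must be >= 1")
  chk(config$genome$repeat_fraction >= 0 &&
        config$genome$repeat_fraction < 1,
      "repeat_fraction must be in [0, 1)")
  chk(config$probes$spacing >= 1, "probe spacing must be >= 1")
  chk(config$filter$min_len >= 1, "filter min_len must be >= 1")
  st <- config$stairfinder
  chk(st$bandwidth > 0, "stairfinder bandwidth must be > 0")
  chk(st$level >= 0 && st$level <= 1, "flooding level must be in [0, 1]")
  chk(config$enrichment$n_backgrounds >= 1, "n_backgrounds must be >= 1")
  chk(config$validation$flip_rate >= 0 && config$validation$flip_rate < 0.5,
      "flip_rate must be in [0, 0.5)")
  invisible(config)
}

#' Read / write a pipeline configuration as YAML
#' @param config configuration list; `path` file path.
#' @return `read_config` returns the configuration list.
#' @export
write_config <- function(config, path) {
  ## named vectors go out as YAML maps so names survive the round trip
  config$genome$chrom_sizes <- as.list(config$genome$chrom_sizes)
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config
#' @param path YAML file path.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$genome$chrom_sizes <- unlist(cfg$genome$chrom_sizes)
  cfg$truth$len_range <- unlist(cfg$truth$len_range)
  cfg
}

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full pipeline on a synthetic scenario
#'
#' simulate -> segment -> filter -> stairfinder -> enrich -> validate,
#' writing each stage's outputs (BED/TSV) into a write-once run
#' directory together with a JSON manifest recording parameters,
#' per-stage seeds and file checksums. Rerunning with the same
#' configuration reproduces identical checksums.
#'
#' @param config configuration list (validated first).
#' @param outdir run directory; created, must not already contain a
#'   manifest.
#' @return Invisibly, a list with the stage results and the manifest.
#' @export
run_pipeline <- function(config = default_config(), outdir) {
  validate_config(config)
  if (dir.exists(outdir) && file.exists(file.path(outdir, "manifest.json")))
    stop("run directory already contains a manifest (write-once): ", outdir)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  stage_seed <- function(i) seed + i
  manifest <- list(package = "tilestair",
                   version = as.character(utils::packageVersion("tilestair")),
                   seed = seed, stages = list())
  log_stage <- function(name, i, files, counts) {
    manifest$stages[[name]] <<- list(
      index = i, seed = stage_seed(i), counts = counts,
      files = lapply(files, function(f)
        list(path = basename(f),
             md5 = unname(tools::md5sum(f)))))
  }

  ## 1. simulate
  g <- config$genome
  genome <- generate_genome(g$chrom_sizes, g$n_genes, g$mean_gene_span,
                            g$exons_per_gene, g$n_lncrnas,
                            g$repeat_fraction, g$gap_fraction,
                            seed = stage_seed(1))
  probes <- generate_probes(genome, config$probes$probe_length,
                            config$probes$spacing, seed = stage_seed(1))
  conds <- config$signal$conditions
  truth <- random_truth(genome, conds, config$truth$n_segments,
                        config$truth$frac_differential,
                        config$truth$len_range, config$truth$amplitude,
                        seed = stage_seed(1))
  cond_tab <- data.frame(condition = conds, time_h = Inf)
  probes <- simulate_intensities(probes, truth, cond_tab,
                                 config$signal$baseline,
                                 config$signal$noise_sd,
                                 config$signal$gc_effect,
                                 seed = stage_seed(1))
  f_probes <- file.path(outdir, "probes.tsv")
  write_tsv(probes, f_probes)
  f_truth <- file.path(outdir, "truth_differential.bed")
  td <- truth$differential
  write_bed(intervals(td$chrom, td$start, td$end,
                      name = td$contrast, score = abs(td$effect)),
            f_truth)
  log_stage("simulate", 1, list(f_probes, f_truth),
            list(probes = nrow(probes),
                 expressed_segments = nrow(truth$expressed),
                 differential_segments = nrow(td)))

  ## 2. segment
  sg <- config$segmentation
  h_list <- list(); tar_files <- list()
  n_sig <- 0
  for (cond in conds) {
    res <- segment_expressed(probes, cond, sg$window_size, sg$min_probes,
                             sg$permutations_expressed,
                             sg$gc_classes_expressed, sg$q_expressed,
                             seed = stage_seed(2))
    h_list[[cond]] <- res$tars
    n_sig <- n_sig + sum(res$windows$q < sg$q_expressed)
    f <- file.path(outdir, paste0("tars_", cond, ".bed"))
    if (nrow(res$tars))
      write_bed(intervals(res$tars$chrom, res$tars$start, res$tars$end,
                          name = res$tars$condition,
                          score = round(res$tars$score * 1000)), f)
    else write_bed(empty_intervals(), f)
    tar_files[[cond]] <- f
  }
  dres <- segment_differential(probes, conds[1], conds[2], h_list,
                               sg$window_size, sg$min_probes,
                               sg$permutations_differential,
                               sg$gc_classes_differential,
                               sg$q_differential, seed = stage_seed(2))
  f_de <- file.path(outdir, "de_tars.bed")
  de <- dres$de_tars
  if (nrow(de))
    write_bed(intervals(de$chrom, de$start, de$end,
                        name = paste0(de$contrast, ":", de$direction),
                        score = round(abs(de$score) * 1000)), f_de)
  else write_bed(empty_intervals(), f_de)
  f_win <- file.path(outdir, "de_windows.tsv")
  write_tsv(dres$windows, f_win)
  log_stage("segment", 2, c(unname(tar_files), list(f_de, f_win)),
            list(significant_windows = n_sig,
                 tars = sum(vapply(h_list, nrow, integer(1))),
                 de_tars = nrow(de)))

  ## 3. filter
  evidence <- coding_evidence(
    coding_exons = coding_exons_of(genome$annotation),
    pseudogene_exons = empty_intervals(),
    rnacode_hits = empty_intervals(),
    rnacode_covered = empty_intervals(),
    tblastn_hits = empty_intervals())
  bf <- bona_fide_filter(de, evidence, genome$annotation,
                         config$filter$min_len)
  f_bf <- file.path(outdir, "bona_fide_noncoding.bed")
  if (nrow(bf))
    write_bed(intervals(bf$chrom, bf$start, bf$end, name = bf$class), f_bf)
  else write_bed(empty_intervals(), f_bf)
  log_stage("filter", 3, list(f_bf),
            list(bona_fide_intervals = nrow(bf),
                 bona_fide_nt = covered_nucleotides(
                   if (nrow(bf)) bf[, c("chrom", "start", "end")]
                   else empty_intervals())))

  ## 4. stairfinder
  st <- config$stairfinder
  macro <- if (nrow(de))
    stairfinder(de, st$bandwidth, st$level, st$grid_step,
                genome$annotation, st$tolerance, st$min_length)
  else stairfinder(empty_intervals())
  f_macro <- file.path(outdir, "macro_regions.tsv")
  write_tsv(macro, f_macro)
  log_stage("stairfinder", 4, list(f_macro),
            list(regions = nrow(macro),
                 macro_sized = sum(macro$macro_sized)))

  ## 5. enrich
  ann <- genome$annotation
  space <- do.call(rbind, lapply(names(genome$chrom_sizes), function(ch)
    intervals(ch, 0, genome$chrom_sizes[[ch]])))
  annotations <- list(coding_exons = coding_exons_of(ann),
                      noncoding_exons = noncoding_exons_of(ann),
                      gene_bodies = ann$genes[, c("chrom", "start", "end")])
  enr <- if (nrow(de))
    enrichment_report(de, annotations, space,
                      exclusions = rbind(ann$repeats, ann$gaps),
                      n_lists = config$enrichment$n_backgrounds,
                      seed = stage_seed(5))
  else data.frame()
  f_enr <- file.path(outdir, "enrichment.tsv")
  write_tsv(enr, f_enr)
  log_stage("enrich", 5, list(f_enr), list(annotations = nrow(enr)))

  ## 6. validate
  contrast <- paste0(conds[2], "-", conds[1])
  ref <- generate_reference_platform(
    truth, contrast,
    data.frame(chrom = probes$chrom, start = probes$start,
               length = probes$length, probe_id = probes$probe_id),
    config$validation$flip_rate, seed = stage_seed(6))
  vc <- fdr_curve(dres$windows, ref)
  f_fdr <- file.path(outdir, "fdr_curve.tsv")
  write_tsv(vc, f_fdr)
  log_stage("validate", 6, list(f_fdr),
            list(reference_probes = nrow(ref),
                 reference_de_probes = sum(ref$de)))

  f_manifest <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, f_manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(genome = genome, probes = probes, truth = truth,
                 h_intervals = h_list, de_tars = de, bona_fide = bf,
                 macro = macro, enrichment = enr, fdr = vc,
                 manifest = manifest))
}
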