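# End-to-end orchestration: reference map -> alignment filter -> variant QC
# -> haplotypes -> detection -> coverage filter -> liftover -> landscape.

#' Pipeline configuration
#'
#' Bundles the input paths and every module parameter (the standard pipeline
#' defaults: MAPQ 60, cluster span 10 / max 3, window flank 3, minimum 5
#' represented variants, threshold 4/6, coverage multipliers 0.25/2, 1 Mb
#' windows, sex chromosomes excluded).
#'
#' @param reference Original (uncompressed) reference FASTA.
#' @param bam Coordinate-sorted BAM aligned to the homopolymer-compressed
#'   reference.
#' @param vcf Phased VCF on the compressed reference.
#' @param out_dir Output directory.
#' @param min_mapq,cluster_span,cluster_max,window_flank,min_represented,
#'   threshold,low_mult,high_mult,window_size,exclude Module parameters; see
#'   the respective functions.
#' @param qual_threshold Optional fixed variant-quality threshold; when NULL
#'   it is estimated with [find_quality_cutoff()].
#' @param seed Seed recorded for provenance.
#' @return A validated list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(reference, bam, vcf, out_dir,
                            min_mapq = 60L, cluster_span = 10L,
                            cluster_max = 3L, window_flank = 3L,
                            min_represented = 5L, threshold = 4 / 6,
                            low_mult = 0.25, high_mult = 2.0,
                            window_size = 1e6,
                            exclude = c("X", "Y", "chrX", "chrY"),
                            qual_threshold = NULL, seed = 1L) {
  cfg <- list(reference = reference, bam = bam, vcf = vcf, out_dir = out_dir,
              min_mapq = as.integer(min_mapq),
              cluster_span = as.integer(cluster_span),
              cluster_max = as.integer(cluster_max),
              window_flank = as.integer(window_flank),
              min_represented = as.integer(min_represented),
              threshold = threshold, low_mult = low_mult,
              high_mult = high_mult, window_size = window_size,
              exclude = exclude, qual_threshold = qual_threshold,
              seed = as.integer(seed))
  if (!is.numeric(cfg$threshold) || cfg$threshold <= 0 || cfg$threshold > 1)
    stop("threshold must lie in (0, 1]")
  if (cfg$min_represented < 1L || cfg$window_flank < 1L)
    stop("window_flank and min_represented must be >= 1")
  if (cfg$low_mult < 0 || cfg$high_mult < cfg$low_mult)
    stop("coverage multipliers must satisfy 0 <= low_mult <= high_mult")
  for (f in c("reference", "bam", "vcf"))
    if (!file.exists(cfg[[f]])) stop("input not found (", f, "): ", cfg[[f]])
  structure(cfg, class = "pipeline_config")
}

#' Run the full crossover-detection pipeline
#'
#' Stages, in order: build the compressed/original position map from the
#' reference; filter alignments; estimate the variant-quality threshold and
#' filter the VCF; load phased haplotypes; detect crossovers; filter by
#' coverage; lift switch intervals to original coordinates; build and plot
#' the 1 Mb recombination landscape.  Every stage logs its input/output
#' counts; the resolved configuration is written for provenance.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the result objects and output paths
#'   (\code{events_tsv}, \code{events_bed}, \code{landscape_tsv},
#'   \code{landscape_png}, \code{log}, \code{config_json}).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "pipeline.log")
  logf <- file(log_path, "w")
  on.exit(close(logf))
  t0_all <- Sys.time()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    msg <- sprintf("[%s] %s (%.2fs)", name, attr(res, "log_line"),
                   as.numeric(difftime(Sys.time(), t0, units = "secs")))
    writeLines(msg, logf); message(msg)
    res
  }
  with_log <- function(x, line) { attr(x, "log_line") <- line; x }

  map <- stage("compress-map", {
    m <- build_position_map(config$reference)
    with_log(m, sprintf("%d chromosome(s), %s -> %s bases",
                        length(m), sum(attr(m, "original_lengths")),
                        sum(attr(m, "compressed_lengths"))))
  })
  bam_f <- file.path(config$out_dir, "filtered.bam")
  aln <- stage("filter-bam", {
    counts <- filter_alignments(config$bam, bam_f, min_mapq = config$min_mapq)
    with_log(read_alignments(bam_f),
             sprintf("kept %d, removed %d alignment(s)",
                     counts["kept"], counts["removed"]))
  })
  vcf_f <- file.path(config$out_dir, "filtered.vcf.gz")
  haps <- stage("filter-vcf+load-haps", {
    v <- vcfR::read.vcfR(config$vcf, verbose = FALSE)
    qual <- suppressWarnings(as.numeric(v@fix[, "QUAL"]))
    thr <- if (!is.null(config$qual_threshold)) config$qual_threshold
           else find_quality_cutoff(qual[is.finite(qual)])
    counts <- filter_variants(config$vcf, vcf_f, threshold = thr,
                              span = config$cluster_span,
                              max_in_span = config$cluster_max)
    h <- load_haplotypes(vcf_f)
    with_log(h, sprintf("quality threshold %.1f; kept %d / removed %d variant(s); %d phased site(s)",
                        thr, counts["kept"], counts["removed"], nrow(h)))
  })
  scan <- stage("detect", {
    s <- detect_crossovers(aln, haps, window_flank = config$window_flank,
                           min_represented = config$min_represented,
                           threshold = config$threshold, position_map = map)
    with_log(s, sprintf("%d read(s) scanned, %d recombinant, %d switch call(s)",
                        nrow(s$reads), sum(s$reads$recombinant), nrow(s$calls)))
  })
  kept <- stage("filter-coverage", {
    prof <- compute_depth(aln)
    f <- filter_by_coverage(scan, prof, low_mult = config$low_mult,
                            high_mult = config$high_mult)
    with_log(f$kept, sprintf("median depth %s; kept %d, removed %d call(s)",
                             format(prof$genome_median), nrow(f$kept),
                             nrow(f$removed)))
  })
  land <- stage("landscape", {
    sizes <- attr(map, "original_lengths")
    l <- build_landscape(kept, sizes, window_size = config$window_size,
                         exclude = config$exclude)
    with_log(l, sprintf("%d window(s), %d event(s) binned", nrow(l),
                        sum(l$count)))
  })
  out <- list(events_tsv = file.path(config$out_dir, "events.tsv"),
              events_bed = file.path(config$out_dir, "events.bed"),
              landscape_tsv = file.path(config$out_dir, "landscape.tsv"),
              landscape_png = file.path(config$out_dir, "landscape.png"),
              log = log_path,
              config_json = file.path(config$out_dir, "config.json"))
  write_crossover_calls(kept, out$events_tsv, out$events_bed)
  write.table(land, out$landscape_tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (nrow(land) && sum(land$count) > 0) plot_landscape(land, out$landscape_png)
  cfg <- unclass(config)
  jsonlite::write_json(cfg[!vapply(cfg, is.null, TRUE)], out$config_json,
                       auto_unbox = TRUE, pretty = TRUE)
  writeLines(sprintf("[done] total %.2fs",
                     as.numeric(difftime(Sys.time(), t0_all, units = "secs"))),
             logf)
  invisible(c(list(map = map, haplotypes = haps, scan = scan, kept = kept,
                   landscape = land), out))
}
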