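# Synthetic gamete-pool simulator and validation harness.
#
# The simulator works directly in homopolymer-compressed coordinate space:
# the compressed reference is drawn with no adjacent duplicate bases, each
# compressed position carries a geometric original run length (so the
# original reference, the position map and original chromosome sizes are
# exact by construction), and reads are emitted pre-aligned with truthful
# CIGARs against the compressed reference.  Heterozygous SNVs are placed
# only at structure-preserving positions (run length 1, alternate allele
# different from both neighbours) so both haplotypes share one compressed
# coordinate system.  Indel errors are elevated at positions whose original
# run length is >= 2, mimicking the residual homopolymer error mode.

#' Simulation configuration
#'
#' @param genome_length Original (uncompressed) genome length in bases.
#' @param n_chromosomes Number of equally sized chromosomes.
#' @param snv_spacing Mean original bases per heterozygous SNV (the standard
#'   validation densities are 100/200/300).
#' @param depth Mean alignment coverage of the compressed genome.
#' @param read_length_mean,read_length_sd Compressed read length (about
#'   20 kb / 4 kb before compression at the default mean run length 1.4).
#' @param recomb_fraction Fraction of reads carrying one crossover.
#' @param p_sub,p_ins,p_del Per-base substitution / insertion / deletion
#'   probabilities in compressed space.
#' @param hp_indel_mult Indel-probability multiplier at positions whose
#'   original homopolymer run length is >= 2.
#' @param mean_run_length Mean geometric homopolymer run length of the
#'   reference.
#' @param decoy_low_frac Low-quality decoy variants as a fraction of true
#'   sites (removed by the quality threshold).
#' @param decoy_clusters_per_mb High-quality clustered decoys (groups of four
#'   within ten bases, removed by the clustered-variant rule).
#' @param unphased_frac,indel_frac Unphased-het / indel records as fractions
#'   of true sites (removed at haplotype loading / SNV filtering).
#' @param seed Integer seed driving all randomness.
#' @return A validated list of class \code{sim_config}.
#' @export
sim_config <- function(genome_length = 5e6, n_chromosomes = 1L,
                       snv_spacing = 100, depth = 30,
                       read_length_mean = 15000, read_length_sd = 3000,
                       recomb_fraction = 0.1,
                       p_sub = 0.02, p_ins = 0.02, p_del = 0.03,
                       hp_indel_mult = 3, mean_run_length = 1.4,
                       decoy_low_frac = 0.1, decoy_clusters_per_mb = 4,
                       unphased_frac = 0.02, indel_frac = 0.02,
                       seed = 1L) {
  cfg <- list(genome_length = genome_length, n_chromosomes = as.integer(n_chromosomes),
              snv_spacing = snv_spacing, depth = depth,
              read_length_mean = read_length_mean, read_length_sd = read_length_sd,
              recomb_fraction = recomb_fraction,
              p_sub = p_sub, p_ins = p_ins, p_del = p_del,
              hp_indel_mult = hp_indel_mult, mean_run_length = mean_run_length,
              decoy_low_frac = decoy_low_frac,
              decoy_clusters_per_mb = decoy_clusters_per_mb,
              unphased_frac = unphased_frac, indel_frac = indel_frac,
              seed = as.integer(seed))
  rates <- c(cfg$recomb_fraction, cfg$p_sub, cfg$p_ins, cfg$p_del,
             cfg$decoy_low_frac, cfg$unphased_frac, cfg$indel_frac)
  if (any(rates < 0) || any(rates[1:4] > 1)) stop("rates must lie in [0, 1]")
  if (cfg$snv_spacing <= 0 || cfg$depth <= 0 || cfg$genome_length <= 0)
    stop("snv_spacing, depth and genome_length must be positive")
  if (cfg$snv_spacing >= cfg$genome_length)
    stop("snv_spacing must be smaller than the genome length")
  if (cfg$mean_run_length < 1) stop("mean_run_length must be >= 1")
  if (cfg$hp_indel_mult < 1) stop("hp_indel_mult must be >= 1")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("sim_config: %g bp genome (%d chrom), 1 SNV per %g bp, ",
                     "depth %gx, reads %g+/-%g (compressed), recomb %.3g\n",
                     "  errors: sub %.3g ins %.3g del %.3g (x%g in ",
                     "homopolymers), seed %d\n"),
              x$genome_length, x$n_chromosomes, x$snv_spacing, x$depth,
              x$read_length_mean, x$read_length_sd, x$recomb_fraction,
              x$p_sub, x$p_ins, x$p_del, x$hp_indel_mult, x$seed))
  invisible(x)
}

.BASES <- c("A", "C", "G", "T")

# compressed sequence with no adjacent duplicates, as integer codes 0..3
.rand_comp_codes <- function(n) {
  if (n == 0L) return(integer(0))
  (sample.int(4L, 1L) - 1L + c(0L, cumsum(sample.int(3L, n - 1L, replace = TRUE)))) %% 4L
}

#' Simulate a diploid genome, haplotype pair and phased variants
#'
#' Draws a reference with geometric homopolymer run lengths, places
#' heterozygous SNVs with near-exponential spacing (mean \code{snv_spacing}
#' original bases), assigns each site's reference/alternate allele to a
#' random haplotype, and builds the matching phased VCF record table.  The
#' VCF additionally carries the QC decoys described in [sim_config()], so a
#' full run exercises the variant-QC rules.
#'
#' @param config A [sim_config()].
#' @return Object of class \code{gamete_sim}: list with \code{config},
#'   \code{chroms} (per chromosome: compressed reference, the two haplotype
#'   sequences, run lengths, homopolymer flags, original length),
#'   \code{sites} (true heterozygous sites, 0-based compressed positions),
#'   \code{vcf} (all VCF records incl. decoys) and \code{map}
#'   (a \code{position_map}).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chrom_names <- paste0("chr", seq_len(config$n_chromosomes))
  target_orig <- config$genome_length / config$n_chromosomes
  q <- 1 - 1 / config$mean_run_length   # geometric continuation probability
  chroms <- list()
  sites_all <- list()
  vcf_all <- list()
  for (ch in chrom_names) {
    lc <- max(10L, as.integer(round(target_orig / config$mean_run_length)))
    codes <- .rand_comp_codes(lc)
    rl <- 1L + stats::rgeom(lc, prob = 1 - q)
    comp <- paste(.BASES[codes + 1L], collapse = "")
    orig_len <- sum(rl)
    hp <- rl >= 2L
    # --- true heterozygous sites (structure-preserving placement) ---
    n_snv <- stats::rpois(1L, orig_len / config$snv_spacing)
    eligible <- which(rl == 1L)
    eligible <- eligible[eligible > 1L & eligible < lc]
    n_snv <- min(n_snv, length(eligible))
    posc <- sort(sample(eligible, n_snv))        # 1-based compressed
    # structure preservation also needs sites >= 2 compressed bases apart
    # (adjacent substituted alleles could otherwise merge into one run)
    posc <- posc[c(TRUE, diff(posc) >= 2L)]
    n_snv <- length(posc)
    refc <- codes[posc]
    leftc <- codes[posc - 1L]
    rightc <- codes[posc + 1L]
    alt <- vapply(seq_len(n_snv), function(i) {
      ok <- setdiff(0:3, c(refc[i], leftc[i], rightc[i]))
      if (length(ok) == 1L) ok else sample(ok, 1L)
    }, 0L)
    a_is_ref <- runif(n_snv) < 0.5
    hap_a <- ifelse(a_is_ref, refc, alt)
    hap_b <- ifelse(a_is_ref, alt, refc)
    codes_a <- codes; codes_a[posc] <- hap_a
    codes_b <- codes; codes_b[posc] <- hap_b
    sites <- data.frame(chrom = ch, pos = posc - 1L,
                        ref = .BASES[refc + 1L], alt = .BASES[alt + 1L],
                        hap_a = .BASES[hap_a + 1L], hap_b = .BASES[hap_b + 1L],
                        stringsAsFactors = FALSE)
    # --- VCF records: true sites + QC decoys ---
    vcf <- data.frame(chrom = ch, pos1 = posc, ref = sites$ref, alt = sites$alt,
                      qual = rnorm(n_snv, 700, 50),
                      gt = ifelse(a_is_ref, "0|1", "1|0"),
                      type = "true", stringsAsFactors = FALSE)
    free <- setdiff(seq_len(lc - 1L), posc)
    n_low <- round(config$decoy_low_frac * n_snv)
    if (n_low > 0L && length(free) >= n_low) {
      p <- sort(sample(free, n_low))
      free <- setdiff(free, p)
      vcf <- rbind(vcf, data.frame(
        chrom = ch, pos1 = p, ref = .BASES[codes[p] + 1L],
        alt = vapply(codes[p], function(r) .BASES[sample(setdiff(0:3, r), 1L) + 1L], ""),
        qual = pmax(1, rnorm(n_low, 100, 30)),
        gt = sample(c("0|1", "1|0"), n_low, replace = TRUE),
        type = "decoy_low", stringsAsFactors = FALSE))
    }
    n_cl <- round(config$decoy_clusters_per_mb * orig_len / 1e6)
    if (n_cl > 0L) {
      anchors <- sample(seq_len(max(1L, lc - 12L)), n_cl)
      p <- sort(unique(as.vector(outer(anchors, c(0L, 3L, 6L, 9L), `+`))))
      p <- setdiff(p, vcf$pos1)
      vcf <- rbind(vcf, data.frame(
        chrom = ch, pos1 = p, ref = .BASES[codes[p] + 1L],
        alt = vapply(codes[p], function(r) .BASES[sample(setdiff(0:3, r), 1L) + 1L], ""),
        qual = rnorm(length(p), 700, 50),
        gt = sample(c("0|1", "1|0"), length(p), replace = TRUE),
        type = "decoy_cluster", stringsAsFactors = FALSE))
    }
    n_unph <- round(config$unphased_frac * n_snv)
    if (n_unph > 0L && length(free) >= n_unph) {
      p <- sort(sample(free, n_unph))
      free <- setdiff(free, p)
      vcf <- rbind(vcf, data.frame(
        chrom = ch, pos1 = p, ref = .BASES[codes[p] + 1L],
        alt = vapply(codes[p], function(r) .BASES[sample(setdiff(0:3, r), 1L) + 1L], ""),
        qual = rnorm(n_unph, 700, 50), gt = "0/1",
        type = "unphased", stringsAsFactors = FALSE))
    }
    n_ind <- round(config$indel_frac * n_snv)
    if (n_ind > 0L && length(free) >= n_ind) {
      p <- sort(sample(free, n_ind))
      vcf <- rbind(vcf, data.frame(
        chrom = ch, pos1 = p,
        ref = paste0(.BASES[codes[p] + 1L], .BASES[codes[pmin(p + 1L, lc)] + 1L]),
        alt = .BASES[codes[p] + 1L],
        qual = rnorm(n_ind, 700, 50),
        gt = sample(c("0|1", "1|0"), n_ind, replace = TRUE),
        type = "indel", stringsAsFactors = FALSE))
    }
    vcf <- vcf[!duplicated(vcf$pos1), , drop = FALSE]
    vcf <- vcf[order(vcf$pos1), , drop = FALSE]
    chroms[[ch]] <- list(comp_ref = comp,
                         hap_a_seq = paste(.BASES[codes_a + 1L], collapse = ""),
                         hap_b_seq = paste(.BASES[codes_b + 1L], collapse = ""),
                         run_lengths = rl, hp_flag = hp, orig_length = orig_len)
    sites_all[[ch]] <- sites
    vcf_all[[ch]] <- vcf
  }
  map <- structure(
    lapply(chroms, function(x) {
      rl <- x$run_lengths
      list(run_starts = cumsum(c(0L, rl[-length(rl)])), run_lengths = rl)
    }),
    class = "position_map",
    original_lengths = setNames(vapply(chroms, function(x) x$orig_length, 0L),
                                chrom_names),
    compressed_lengths = setNames(vapply(chroms, function(x)
      length(x$run_lengths), 0L), chrom_names))
  structure(list(config = config, chroms = chroms,
                 sites = do.call(rbind, c(sites_all, make.row.names = FALSE)),
                 vcf = do.call(rbind, c(vcf_all, make.row.names = FALSE)),
                 map = map),
            class = "gamete_sim")
}

#' @export
print.gamete_sim <- function(x, ...) {
  cat(sprintf("gamete_sim: %d chromosome(s), %d heterozygous site(s), %d VCF record(s)\n",
              length(x$chroms), nrow(x$sites), nrow(x$vcf)))
  invisible(x)
}

#' True haplotype table of a simulated genome
#' @param sim A \code{gamete_sim}.
#' @return A [haplotype_table()] built from the true sites (one phase set per
#'   chromosome).
#' @export
sim_truth_haplotypes <- function(sim) {
  haplotype_table(sim$sites$chrom, sim$sites$pos, sim$sites$hap_a,
                  sim$sites$hap_b, phase_set = sim$sites$chrom)
}

#' Simulate a gamete-pool read set
#'
#' Draws reads from haplotype A, haplotype B and — with probability
#' \code{recomb_fraction} — recombinant templates switching haplotype at a
#' uniform-random internal breakpoint, injects substitution/indel errors with
#' the homopolymer multiplier, and emits the alignments pre-aligned (correct
#' positions and CIGARs on the compressed reference).
#'
#' @param sim A \code{gamete_sim} from [simulate_genome()].
#' @param depth Mean coverage (default: the config value).
#' @param seed Seed for the read draw (default \code{config$seed + 1};
#'   run separate depth cells with distinct seeds).
#' @param error_free If TRUE, all error rates are forced to zero.
#' @return Object of class \code{gamete_pool}: list with \code{aln}
#'   (alignment table, coordinate-sorted), \code{truth} (per-read:
#'   \code{read_id}, \code{chrom}, \code{start}, \code{length},
#'   \code{recombinant}, \code{bp_comp} — 0-based compressed breakpoint
#'   coordinate or NA — and \code{source_first}), and \code{ref_lengths}.
#' @export
simulate_reads <- function(sim, depth = NULL, seed = NULL, error_free = FALSE) {
  stopifnot(inherits(sim, "gamete_sim"))
  cfg <- sim$config
  if (is.null(depth)) depth <- cfg$depth
  if (is.null(seed)) seed <- cfg$seed + 1L
  set.seed(seed)
  p_sub <- if (error_free) 0 else cfg$p_sub
  p_ins <- if (error_free) 0 else cfg$p_ins
  p_del <- if (error_free) 0 else cfg$p_del
  aln_l <- list(); truth_l <- list()
  for (ch in names(sim$chroms)) {
    g <- sim$chroms[[ch]]
    lc <- length(g$run_lengths)
    n <- max(1L, as.integer(round(depth * lc / cfg$read_length_mean)))
    len <- as.integer(round(rnorm(n, cfg$read_length_mean, cfg$read_length_sd)))
    len <- pmax(200L, pmin(len, lc))
    start <- vapply(len, function(l) sample.int(lc - l + 1L, 1L) - 1L, 0L)
    recomb <- runif(n) < cfg$recomb_fraction
    bp <- ifelse(recomb,
                 vapply(len, function(l) sample.int(l - 1L, 1L), 0L),
                 -1L)
    b_first <- runif(n) < 0.5
    reads <- .sim_read_batch(g$hap_a_seq, g$hap_b_seq, g$hp_flag,
                             start, len, as.integer(bp), b_first,
                             p_sub, p_ins, p_del, cfg$hp_indel_mult)
    ids <- sprintf("%s_read%06d", ch, seq_len(n))
    aln_l[[ch]] <- data.frame(read_id = ids, flag = 0L, chrom = ch,
                              pos = reads$pos, mapq = 60L,
                              cigar = reads$cigar, seq = reads$seq,
                              stringsAsFactors = FALSE)
    truth_l[[ch]] <- data.frame(
      read_id = ids, chrom = ch, start = start, length = len,
      recombinant = recomb,
      bp_comp = ifelse(recomb, start + bp, NA_integer_),
      source_first = ifelse(b_first, "B", "A"),
      stringsAsFactors = FALSE)
  }
  aln <- do.call(rbind, c(aln_l, make.row.names = FALSE))
  aln <- aln[order(aln$chrom, aln$pos), , drop = FALSE]
  rownames(aln) <- NULL
  structure(list(aln = aln,
                 truth = do.call(rbind, c(truth_l, make.row.names = FALSE)),
                 ref_lengths = attr(sim$map, "compressed_lengths")),
            class = "gamete_pool")
}

#' @export
print.gamete_pool <- function(x, ...) {
  cat(sprintf("gamete_pool: %d read(s), %d recombinant (%.1f%%)\n",
              nrow(x$truth), sum(x$truth$recombinant),
              100 * mean(x$truth$recombinant)))
  invisible(x)
}

#' Write simulator outputs to disk
#'
#' Writes the original reference FASTA, compressed reference FASTA, phased
#' VCF, position map, chrom.sizes, compressed-read FASTQ, coordinate-sorted
#' indexed BAM and the truth TSV.
#'
#' @param sim A \code{gamete_sim}.
#' @param pool A \code{gamete_pool} from the same simulation.
#' @param dir Output directory (created).
#' @return Named list of file paths.
#' @export
write_sim_files <- function(sim, pool, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- list(reference = file.path(dir, "reference.fa"),
            reference_comp = file.path(dir, "reference_comp.fa"),
            vcf = file.path(dir, "variants.vcf"),
            map = file.path(dir, "position_map.tsv.gz"),
            chrom_sizes = file.path(dir, "chrom.sizes"),
            fastq = file.path(dir, "reads.fastq"),
            bam = file.path(dir, "pool.bam"),
            truth = file.path(dir, "truth.tsv"))
  orig <- vapply(sim$chroms, function(g) {
    raws <- rep(charToRaw(g$comp_ref), g$run_lengths)
    rawToChar(raws)
  }, "")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(orig), p$reference)
  comp <- vapply(sim$chroms, function(g) g$comp_ref, "")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(comp), p$reference_comp)
  write_sim_vcf(sim, p$vcf)
  write_position_map(sim$map, p$map)
  writeLines(sprintf("%s\t%d", names(sim$chroms),
                     vapply(sim$chroms, function(g) g$orig_length, 0L)),
             p$chrom_sizes)
  .write_fastq(pool$aln$read_id, pool$aln$seq,
               strrep("I", nchar(pool$aln$seq)), p$fastq)
  sam <- file.path(dir, "pool.sam")
  write_sam(pool$aln, pool$ref_lengths, sam)
  sam_to_bam(sam, sub("\\.bam$", "", p$bam))
  write.table(pool$truth, p$truth, sep = "\t", quote = FALSE, row.names = FALSE)
  p
}

# minimal phased single-sample VCF writer for simulated variant tables
write_sim_vcf <- function(sim, path) {
  v <- sim$vcf
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>", names(sim$chroms),
                       attr(sim$map, "compressed_lengths")),
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=PS,Number=1,Type=Integer,Description=\"Phase set\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tpool"),
             con)
  ps <- ifelse(grepl("|", v$gt, fixed = TRUE), ":1", "")
  fmt <- ifelse(grepl("|", v$gt, fixed = TRUE), "GT:PS", "GT")
  writeLines(paste(v$chrom, v$pos1, ".", v$ref, v$alt,
                   sprintf("%.2f", v$qual), "PASS", ".", fmt,
                   paste0(v$gt, ps), sep = "\t"), con)
  invisible(path)
}

#' Variant QC + haplotype loading on an in-memory simulated variant table
#'
#' Mirrors the file-based route ([find_quality_cutoff()] ->
#' [filter_variants()] -> [load_haplotypes()]) on a \code{gamete_sim}'s
#' record table: quality threshold from the bimodal distribution, SNV-only,
#' clustered-variant rule, phased heterozygotes.
#'
#' @param sim A \code{gamete_sim}.
#' @param span,max_in_span Passed to [filter_clustered()].
#' @return A [haplotype_table()].
#' @export
sim_qc_haplotypes <- function(sim, span = 10L, max_in_span = 3L) {
  v <- sim$vcf
  thr <- find_quality_cutoff(v$qual)
  snv <- nchar(v$ref) == 1L & nchar(v$alt) == 1L & v$ref != v$alt
  keep <- snv & v$qual >= thr
  surv <- data.frame(chrom = v$chrom[keep], pos = v$pos1[keep] - 1L,
                     row = which(keep), stringsAsFactors = FALSE)
  surv <- surv[order(surv$chrom, surv$pos), , drop = FALSE]
  surv <- filter_clustered(surv, span = span, max_in_span = max_in_span)
  v <- v[surv$row, , drop = FALSE]
  phased <- v$gt %in% c("0|1", "1|0")
  v <- v[phased, , drop = FALSE]
  haplotype_table(v$chrom, v$pos1 - 1L,
                  hap_a = ifelse(v$gt == "0|1", v$ref, v$alt),
                  hap_b = ifelse(v$gt == "0|1", v$alt, v$ref),
                  phase_set = v$chrom)
}

#' Compare crossover calls with the simulation truth
#'
#' Sensitivity (accuracy rate) is the proportion of truly recombinant
#' molecules called recombinant; the error rate is the proportion of
#' non-recombinant molecules falsely called recombinant.  Also reports the
#' mean breakpoint localisation error: the distance (compressed bases) from
#' the true breakpoint to the reported switch interval, zero when contained.
#'
#' @param calls A \code{crossover_scan}, a call table (e.g. the kept table of
#'   [filter_by_coverage()]), or a character vector of recombinant read ids.
#' @param truth The truth table of a [simulate_reads()] pool.
#' @return List of class \code{crossover_eval}: \code{accuracy},
#'   \code{error_rate}, \code{tp}, \code{fn}, \code{fp}, \code{tn},
#'   \code{n_recombinant}, \code{n_nonrecombinant},
#'   \code{mean_breakpoint_error}.
#' @export
evaluate_calls <- function(calls, truth) {
  if (inherits(calls, "gamete_pool")) stop("pass calls, not the pool")
  tbl <- NULL
  if (inherits(calls, "crossover_scan")) tbl <- calls$calls
  else if (is.data.frame(calls)) tbl <- calls
  called <- if (is.character(calls)) unique(calls) else unique(tbl$read_id)
  if (!all(called %in% truth$read_id))
    stop("calls contain read ids absent from the truth set")
  rec <- truth$read_id[truth$recombinant]
  nonrec <- truth$read_id[!truth$recombinant]
  tp <- sum(called %in% rec)
  fp <- sum(called %in% nonrec)
  bpe <- NA_real_
  if (!is.null(tbl) && nrow(tbl)) {
    m <- tbl[tbl$read_id %in% rec, , drop = FALSE]
    if (nrow(m)) {
      b <- truth$bp_comp[match(m$read_id, truth$read_id)]
      d <- pmax(0, pmax(m$comp_start - b, b - (m$comp_end - 1L)))
      bpe <- mean(tapply(d, m$read_id, min))
    }
  }
  structure(list(accuracy = if (length(rec)) tp / length(rec) else NA_real_,
                 error_rate = if (length(nonrec)) fp / length(nonrec) else NA_real_,
                 tp = tp, fn = length(rec) - tp, fp = fp,
                 tn = length(nonrec) - fp,
                 n_recombinant = length(rec),
                 n_nonrecombinant = length(nonrec),
                 mean_breakpoint_error = bpe),
            class = "crossover_eval")
}

#' @export
print.crossover_eval <- function(x, ...) {
  cat(sprintf(paste0("crossover_eval: sensitivity %.4f (%d/%d), ",
                     "error rate %.5f (%d/%d), mean breakpoint error %s\n"),
              x$accuracy, x$tp, x$n_recombinant, x$error_rate, x$fp,
              x$n_nonrecombinant, format(x$mean_breakpoint_error)))
  invisible(x)
}

#' Run the detection pipeline on one simulated cell
#'
#' simulate reads -> alignment filter -> detect -> coverage filter ->
#' evaluate, all in memory.
#'
#' @param sim A \code{gamete_sim}.
#' @param haps Haplotype table (default: QC-derived via the simulated VCF).
#' @param depth,seed,error_free Passed to [simulate_reads()].
#' @param low_mult,high_mult Passed to [filter_by_coverage()].
#' @param ... Passed to [detect_crossovers()].
#' @return List with \code{eval} (a \code{crossover_eval}), \code{scan},
#'   \code{kept}, \code{pool}.
#' @export
run_sim_cell <- function(sim, haps = NULL, depth = NULL, seed = NULL,
                         error_free = FALSE, low_mult = 0.25, high_mult = 2.0,
                         ...) {
  if (is.null(haps)) haps <- sim_qc_haplotypes(sim)
  pool <- simulate_reads(sim, depth = depth, seed = seed,
                         error_free = error_free)
  aln <- filter_alignment_table(pool$aln)
  scan <- detect_crossovers(aln, haps, ...)
  prof <- compute_depth(aln)
  filt <- filter_by_coverage(scan, prof, low_mult = low_mult,
                             high_mult = high_mult)
  list(eval = evaluate_calls(filt$kept, pool$truth), scan = scan,
       kept = filt$kept, pool = pool)
}

#' Sensitivity / error-rate grid over variant densities and depths
#'
#' Runs the full in-memory pipeline (genome + variant QC once per density and
#' replicate; reads, detection, coverage filter and evaluation per depth) and
#' tabulates sensitivity and error rate per cell.
#'
#' @param spacings Mean original bases per SNV (default 100/200/300).
#' @param depths Mean coverages (default 20-70x in steps of 10).
#' @param reps Replicates (independent genomes/pools) per cell.
#' @param seed Master seed; all cell seeds derive from it.
#' @param genome_length,... Passed to [sim_config()].
#' @return data.frame of class \code{grid_result}, one row per
#'   (spacing, depth, rep): counts, \code{accuracy}, \code{error_rate},
#'   \code{mean_breakpoint_error}.
#' @seealso [summarize_grid()], [plot_grid()]
#' @export
run_grid <- function(spacings = c(100, 200, 300), depths = seq(20, 70, 10),
                     reps = 3L, seed = 1L, genome_length = 5e6, ...) {
  set.seed(seed)
  seeds <- matrix(sample.int(.Machine$integer.max %/% 2L,
                             length(spacings) * reps),
                  nrow = length(spacings))
  rows <- list()
  for (si in seq_along(spacings)) {
    for (rep in seq_len(reps)) {
      cfg <- sim_config(genome_length = genome_length,
                        snv_spacing = spacings[si],
                        seed = seeds[si, rep], ...)
      sim <- simulate_genome(cfg)
      haps <- sim_qc_haplotypes(sim)
      for (d in depths) {
        cell <- run_sim_cell(sim, haps = haps, depth = d,
                             seed = seeds[si, rep] + as.integer(d))
        ev <- cell$eval
        rows[[length(rows) + 1L]] <- data.frame(
          snv_spacing = spacings[si], depth = d, rep = rep,
          n_reads = nrow(cell$pool$truth),
          n_recombinant = ev$n_recombinant,
          n_nonrecombinant = ev$n_nonrecombinant,
          tp = ev$tp, fp = ev$fp,
          accuracy = ev$accuracy, error_rate = ev$error_rate,
          mean_breakpoint_error = ev$mean_breakpoint_error,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("grid_result", "data.frame")
  out
}

#' Summarise a validation grid per cell
#'
#' @param grid A \code{grid_result}.
#' @return data.frame per (spacing, depth): mean/sd sensitivity and error
#'   rate with normal-approximation 95% Monte-Carlo confidence half-widths.
#' @export
summarize_grid <- function(grid) {
  mn <- stats::aggregate(cbind(accuracy, error_rate) ~ snv_spacing + depth,
                         data = grid, FUN = mean)
  sd_ <- stats::aggregate(cbind(accuracy, error_rate) ~ snv_spacing + depth,
                          data = grid, FUN = stats::sd)
  n <- stats::aggregate(accuracy ~ snv_spacing + depth, data = grid,
                        FUN = length)
  out <- data.frame(snv_spacing = mn$snv_spacing, depth = mn$depth,
                    reps = n$accuracy,
                    accuracy = mn$accuracy, accuracy_sd = sd_$accuracy,
                    error_rate = mn$error_rate,
                    error_rate_sd = sd_$error_rate)
  out$accuracy_ci <- 1.96 * out$accuracy_sd / sqrt(out$reps)
  out$error_rate_ci <- 1.96 * out$error_rate_sd / sqrt(out$reps)
  out <- out[order(out$snv_spacing, out$depth), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Plot sensitivity and error rate against depth
#'
#' Two panels (sensitivity on top, error rate below), depth on the x axis,
#' one line per variant density.
#'
#' @param grid A \code{grid_result}.
#' @param out_image PNG path.
#' @return Invisibly, the [summarize_grid()] table that was plotted.
#' @export
plot_grid <- function(grid, out_image) {
  s <- summarize_grid(grid)
  grDevices::png(out_image, width = 700, height = 700)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(2, 1), mar = c(4, 4.5, 2, 1))
  sp <- sort(unique(s$snv_spacing))
  cols <- grDevices::hcl.colors(max(3L, length(sp)), "Dark 3")[seq_along(sp)]
  for (panel in c("accuracy", "error_rate")) {
    ylim <- range(0, s[[panel]], if (panel == "accuracy") 1)
    graphics::plot(NA, xlim = range(s$depth), ylim = ylim,
                   xlab = "mean sequencing depth (x)",
                   ylab = if (panel == "accuracy") "sensitivity" else "error rate")
    for (i in seq_along(sp)) {
      d <- s[s$snv_spacing == sp[i], ]
      graphics::lines(d$depth, d[[panel]], col = cols[i], lwd = 2, type = "b",
                      pch = 16)
    }
    graphics::legend(if (panel == "accuracy") "bottomright" else "topright",
                     legend = sprintf("1 SNV / %g bp", sp), col = cols,
                     lwd = 2, pch = 16, bty = "n")
  }
  invisible(s)
}
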