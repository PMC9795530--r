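# Alignment and variant quality control.  The crossover caller assumes a
# clean set of biallelic heterozygous SNVs: multiple/low-quality alignments
# are dropped before calling, the variant-quality threshold is read off the
# bimodal quality distribution (valley between the two modes + 50), and
# clustered variants (more than three within ten bases) are removed.

#' Filter a BAM file to primary, high-MAPQ alignments
#'
#' Removes secondary (0x100) and supplementary (0x800) alignments and records
#' with mapping quality below \code{min_mapq}.  Surviving records are
#' untouched and keep their sorted order.
#'
#' @param bam_in Coordinate-sorted BAM (or SAM) path.
#' @param bam_out Output BAM path.
#' @param min_mapq Minimum mapping quality kept (default 60, i.e. records
#'   with MAPQ < 60 are removed).
#' @return Named integer vector \code{c(kept=, removed=)}.
#' @export
filter_alignments <- function(bam_in, bam_out, min_mapq = 60L) {
  if (!file.exists(bam_in)) stop("alignment file not found: ", bam_in)
  if (grepl("\\.sam$", bam_in, ignore.case = TRUE)) bam_in <- sam_to_bam(bam_in)
  hdr <- Rsamtools::scanBamHeader(bam_in)[[1]]$text
  so <- if ("@HD" %in% names(hdr)) grep("^SO:", hdr[["@HD"]], value = TRUE) else character(0)
  if (length(so) && !identical(so, "SO:coordinate"))
    stop("input BAM is not coordinate-sorted (", so, ")")
  total <- Rsamtools::countBam(bam_in)$records
  flag <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  dest <- Rsamtools::filterBam(
    bam_in, bam_out,
    param = Rsamtools::ScanBamParam(flag = flag, mapqFilter = min_mapq,
                                    what = character(0)))
  kept <- Rsamtools::countBam(dest)$records
  c(kept = kept, removed = total - kept)
}

#' In-memory analogue of [filter_alignments()] for alignment tables
#' @param aln Alignment table (see [read_alignments()]).
#' @inheritParams filter_alignments
#' @return The filtered table.
#' @export
filter_alignment_table <- function(aln, min_mapq = 60L) {
  primary <- bitwAnd(aln$flag, 0x100L) == 0L & bitwAnd(aln$flag, 0x800L) == 0L
  ok <- primary & !is.na(aln$mapq) & aln$mapq >= min_mapq
  aln[ok, , drop = FALSE]
}

#' Variant-quality threshold from a bimodal quality distribution
#'
#' Long-read variant callers produce a characteristic bimodal quality
#' distribution: a low-quality error mode and a high-quality true-variant
#' mode.  The threshold is the quality at the valley between the two highest
#' modes of a kernel-smoothed density, plus a fixed offset of 50.  When fewer
#' than two modes are found (degenerate or unimodal input) the 5th percentile
#' of the qualities is returned with a warning.
#'
#' @param qual Numeric vector of variant quality scores (length >= 2).
#' @param offset Added to the valley location (default 50).
#' @return The quality threshold (variants strictly below it are removed by
#'   [filter_variants()]).
#' @export
find_quality_cutoff <- function(qual, offset = 50) {
  qual <- qual[is.finite(qual)]
  if (length(qual) < 2L) stop("need at least two quality values")
  if (stats::sd(qual) == 0) {
    warning("quality distribution is degenerate; falling back to 5th percentile")
    return(unname(quantile(qual, 0.05)))
  }
  d <- density(qual, n = 1024L)
  y <- d$y
  locmax <- which(diff(sign(diff(y))) == -2) + 1L
  if (length(locmax) >= 2L) {
    # primary mode = global maximum; secondary mode = the local maximum with
    # the greatest topographic prominence relative to the primary (sampling
    # ripples on a single mode have near-zero prominence and are ignored)
    p1 <- locmax[which.max(y[locmax])]
    prom <- vapply(locmax, function(m) {
      if (m == p1) return(0)
      y[m] - min(y[seq(min(m, p1), max(m, p1))])
    }, 0)
    if (max(prom) >= 0.05 * y[p1]) {
      p2 <- locmax[which.max(prom)]
      between <- seq(min(p1, p2), max(p1, p2))
      valley <- between[which.min(y[between])]
      return(d$x[valley] + offset)
    }
  }
  warning("quality distribution looks unimodal; falling back to 5th percentile")
  unname(quantile(qual, 0.05))
}

#' Remove clustered variants
#'
#' Drops every variant participating in any same-chromosome window of
#' \code{span} bases (both ends inclusive: positions p and p + span - 1 are
#' "within span bases") that contains more than \code{max_in_span} variants.
#' The whole offending cluster is removed, not just the excess.  Idempotent.
#'
#' @param variants data.frame with columns \code{chrom} and \code{pos},
#'   sorted by (chrom, pos).
#' @param span Window width in bases (default 10).
#' @param max_in_span Maximum variants tolerated per window (default 3).
#' @return The filtered data.frame (still sorted).
#' @export
filter_clustered <- function(variants, span = 10L, max_in_span = 3L) {
  stopifnot(all(c("chrom", "pos") %in% names(variants)))
  if (nrow(variants) == 0L) return(variants)
  o <- order(variants$chrom, variants$pos)
  if (!identical(o, seq_len(nrow(variants))))
    stop("variants must be sorted by (chrom, pos)")
  drop <- logical(nrow(variants))
  for (ch in unique(variants$chrom)) {
    idx <- which(variants$chrom == ch)
    p <- variants$pos[idx]
    jmax <- findInterval(p + span - 1L, p)
    bad <- which(jmax - seq_along(p) + 1L > max_in_span)
    for (i in bad) drop[idx[i:jmax[i]]] <- TRUE
  }
  variants[!drop, , drop = FALSE]
}

#' Filter a VCF to high-quality biallelic SNVs
#'
#' Removes records with quality strictly below \code{threshold}, non-SNV and
#' multiallelic records, then applies the clustered-variant rule
#' ([filter_clustered()]).  Survivors are written unmodified.
#'
#' @param vcf_in Input VCF path (plain or gzipped).
#' @param vcf_out Output path (written gzipped by [vcfR::write.vcf()]).
#' @param threshold Quality threshold, usually from [find_quality_cutoff()].
#' @param span,max_in_span Passed to [filter_clustered()].
#' @return Named integer vector \code{c(kept=, removed=)}.
#' @export
filter_variants <- function(vcf_in, vcf_out, threshold,
                            span = 10L, max_in_span = 3L) {
  v <- tryCatch(vcfR::read.vcfR(vcf_in, verbose = FALSE),
                error = function(e) stop("malformed VCF '", vcf_in, "': ",
                                         conditionMessage(e)))
  fix <- v@fix
  n <- nrow(fix)
  if (n == 0L) {
    vcfR::write.vcf(v, vcf_out)
    return(c(kept = 0L, removed = 0L))
  }
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  snv <- !is.na(fix[, "REF"]) & !is.na(fix[, "ALT"]) &
    nchar(fix[, "REF"]) == 1L & nchar(fix[, "ALT"]) == 1L &
    !grepl(",", fix[, "ALT"], fixed = TRUE) &
    fix[, "REF"] != fix[, "ALT"]
  keep <- snv & !is.na(qual) & qual >= threshold
  surv <- data.frame(chrom = fix[keep, "CHROM"],
                     pos = as.integer(fix[keep, "POS"]),
                     row = which(keep), stringsAsFactors = FALSE)
  surv <- surv[order(surv$chrom, surv$pos), , drop = FALSE]
  surv2 <- filter_clustered(surv, span = span, max_in_span = max_in_span)
  sel <- sort(surv2$row)
  out <- v
  out@fix <- v@fix[sel, , drop = FALSE]
  if (ncol(v@gt)) out@gt <- v@gt[sel, , drop = FALSE]
  vcfR::write.vcf(out, vcf_out)
  c(kept = length(sel), removed = n - length(sel))
}
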