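# Thin SAM/BAM helpers around Rsamtools.  The detection pipeline works on a
# plain data.frame of alignments so that simulated pools can flow through
# without round-tripping gigabytes of BAM at desk scale.

#' Read primary fields of a BAM/SAM file into an alignment table
#'
#' @param bam Path to a coordinate-sorted BAM (a SAM path is converted on the
#'   fly with [Rsamtools::asBam()]).
#' @return A data.frame with columns \code{read_id}, \code{flag},
#'   \code{chrom}, \code{pos} (0-based leftmost reference position),
#'   \code{mapq}, \code{cigar}, \code{seq}.
#' @export
read_alignments <- function(bam) {
  if (!file.exists(bam)) stop("alignment file not found: ", bam)
  if (grepl("\\.sam$", bam, ignore.case = TRUE)) bam <- sam_to_bam(bam)
  res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq")))[[1]]
  keep <- !is.na(res$pos)
  data.frame(read_id = res$qname[keep],
             flag = res$flag[keep],
             chrom = as.character(res$rname)[keep],
             pos = res$pos[keep] - 1L,
             mapq = res$mapq[keep],
             cigar = res$cigar[keep],
             seq = as.character(res$seq)[keep],
             stringsAsFactors = FALSE)
}

#' Write an alignment table as SAM (and optionally convert to sorted BAM)
#'
#' @param aln Alignment table as returned by [read_alignments()].
#' @param ref_lengths Named integer vector of reference sequence lengths
#'   (compressed coordinates).
#' @param path Output path ending in \code{.sam}.
#' @return Invisibly, \code{path}.
#' @keywords internal
#' @export
write_sam <- function(aln, ref_lengths, path) {
  ord <- order(match(aln$chrom, names(ref_lengths)), aln$pos)
  aln <- aln[ord, , drop = FALSE]
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths), ref_lengths))
  rec <- paste(aln$read_id, aln$flag, aln$chrom, aln$pos + 1L, aln$mapq,
               aln$cigar, "*", 0L, 0L, aln$seq, "*", sep = "\t")
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Convert SAM to coordinate-sorted, indexed BAM
#' @param sam SAM path.
#' @param bam_stem Output stem (default: SAM path without extension).
#' @return The BAM path.
#' @keywords internal
#' @export
sam_to_bam <- function(sam, bam_stem = sub("\\.sam$", "", sam, ignore.case = TRUE)) {
  Rsamtools::asBam(sam, bam_stem, overwrite = TRUE, indexDestination = TRUE)
}
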