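# Phased-variant ingestion: phased VCF -> per-site haplotype table.

#' Construct a haplotype table
#'
#' @param chrom Character vector of chromosome names.
#' @param pos Integer vector of 0-based site coordinates (compressed genome),
#'   strictly increasing within each chromosome.
#' @param hap_a,hap_b Single-nucleotide alleles of haplotype A / B at each
#'   site (must differ sitewise: heterozygous only).
#' @param phase_set Phase-set (block) identifier per site; phase is only
#'   comparable within a block.
#' @return A data.frame of class \code{haplotype_table}.
#' @export
haplotype_table <- function(chrom, pos, hap_a, hap_b,
                            phase_set = rep("1", length(pos))) {
  ht <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   hap_a = toupper(as.character(hap_a)),
                   hap_b = toupper(as.character(hap_b)),
                   phase_set = as.character(phase_set),
                   stringsAsFactors = FALSE)
  ht <- ht[order(ht$chrom, ht$pos), , drop = FALSE]
  rownames(ht) <- NULL
  if (any(ht$hap_a == ht$hap_b))
    stop("haplotype alleles must differ at every site (heterozygous only)")
  if (any(nchar(ht$hap_a) != 1L) || any(nchar(ht$hap_b) != 1L))
    stop("haplotype alleles must be single nucleotides")
  if (any(unlist(tapply(ht$pos, ht$chrom, function(p) duplicated(p)))))
    stop("site positions must be strictly increasing within a chromosome")
  class(ht) <- c("haplotype_table", "data.frame")
  ht
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat(sprintf("haplotype_table: %d site(s), %d chromosome(s), %d phase set(s)\n",
              nrow(x), length(unique(x$chrom)),
              length(unique(paste(x$chrom, x$phase_set)))))
  NextMethod()
}

#' Load phased heterozygous SNVs from a VCF into a haplotype table
#'
#' Keeps only phased ('|' separator) heterozygous biallelic SNVs; indels,
#' other structural alleles, multiallelic records and unphased genotypes are
#' disregarded.  Haplotype A is defined as the allele left of the phase
#' separator — an arbitrary but fixed convention; the downstream caller is
#' symmetric under a global relabelling.  Sites are grouped by the PS
#' (phase-set) FORMAT field when present, otherwise each chromosome is one
#' block.
#'
#' @param vcf Path to a VCF (on the compressed reference; positions are
#'   converted from 1-based VCF to the 0-based internal convention), or a
#'   \code{vcfR} object.
#' @param sample Column index of the sample genotype (default 1).
#' @return A \code{haplotype_table} (possibly with 0 rows, with a warning).
#' @export
load_haplotypes <- function(vcf, sample = 1L) {
  v <- if (inherits(vcf, "vcfR")) vcf else vcfR::read.vcfR(vcf, verbose = FALSE)
  fix <- v@fix
  if (nrow(fix) == 0L || ncol(v@gt) < sample + 1L) {
    warning("no genotype records in VCF")
    return(haplotype_table(character(0), integer(0), character(0), character(0),
                           character(0)))
  }
  fmt <- v@gt[, 1L]
  gtcol <- v@gt[, sample + 1L]
  keys <- strsplit(fmt, ":", fixed = TRUE)
  vals <- strsplit(gtcol, ":", fixed = TRUE)
  get_field <- function(i, field) {
    k <- match(field, keys[[i]])
    if (is.na(k) || k > length(vals[[i]])) NA_character_ else vals[[i]][k]
  }
  n <- nrow(fix)
  gt <- vapply(seq_len(n), get_field, "", field = "GT")
  ps <- vapply(seq_len(n), get_field, "", field = "PS")
  phased <- grepl("|", gt, fixed = TRUE)
  al <- strsplit(gt, "|", fixed = TRUE)
  a1 <- vapply(al, function(x) if (length(x) >= 1) x[1] else NA_character_, "")
  a2 <- vapply(al, function(x) if (length(x) >= 2) x[2] else NA_character_, "")
  snv <- !is.na(fix[, "REF"]) & !is.na(fix[, "ALT"]) &
    nchar(fix[, "REF"]) == 1L & nchar(fix[, "ALT"]) == 1L &
    !grepl(",", fix[, "ALT"], fixed = TRUE)
  het <- phased & !is.na(a1) & !is.na(a2) & a1 %in% c("0", "1") &
    a2 %in% c("0", "1") & a1 != a2
  keep <- snv & het
  if (!any(keep)) {
    warning("no phased heterozygous SNVs in VCF")
    return(haplotype_table(character(0), integer(0), character(0), character(0),
                           character(0)))
  }
  allele <- cbind(fix[, "REF"], fix[, "ALT"])
  idx <- which(keep)
  pick <- function(code) allele[cbind(idx, as.integer(code) + 1L)]
  haplotype_table(chrom = fix[idx, "CHROM"],
                  pos = as.integer(fix[idx, "POS"]) - 1L,
                  hap_a = pick(a1[idx]),
                  hap_b = pick(a2[idx]),
                  phase_set = ifelse(is.na(ps[idx]), fix[idx, "CHROM"], ps[idx]))
}
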