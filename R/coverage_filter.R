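# Depth-based filtering of candidate recombinant molecules.  Recombination
# calls sitting in regions of anomalous alignment depth (collapsed repeats,
# dropouts) are more likely haplotype-construction artifacts than true
# crossovers and are removed before the landscape is built.

#' Compute a per-position depth profile from alignments
#'
#' Depth is the number of primary alignments whose reference span (from the
#' CIGAR) covers each compressed-genome position.
#'
#' @param aln A BAM path or alignment table (see [read_alignments()]).
#' @return An object of class \code{depth_profile}: list with \code{depth}
#'   (named list of [S4Vectors::Rle] vectors, one per chromosome) and
#'   \code{genome_median} (median depth over covered positions).
#' @export
compute_depth <- function(aln) {
  if (is.character(aln)) aln <- read_alignments(aln)
  if (nrow(aln) == 0L) {
    warning("no alignments; empty depth profile")
    return(structure(list(depth = list(), genome_median = NA_real_),
                     class = "depth_profile"))
  }
  rw <- .cigar_widths(aln$cigar)[, "ref_width"]
  depth <- lapply(split(seq_len(nrow(aln)), aln$chrom), function(i) {
    IRanges::coverage(IRanges::IRanges(start = aln$pos[i] + 1L,
                                       width = rw[i]))
  })
  # weighted median over covered (depth > 0) positions
  vals <- unlist(lapply(depth, S4Vectors::runValue))
  lens <- unlist(lapply(depth, S4Vectors::runLength))
  keep <- vals > 0
  vals <- vals[keep]; lens <- lens[keep]
  o <- order(vals)
  cw <- cumsum(as.numeric(lens[o]))
  med <- if (length(vals)) vals[o][which(cw >= cw[length(cw)] / 2)[1]] else NA_real_
  structure(list(depth = depth, genome_median = as.numeric(med)),
            class = "depth_profile")
}

#' @export
print.depth_profile <- function(x, ...) {
  cat(sprintf("depth_profile: %d chromosome(s), genome median depth %s\n",
              length(x$depth), format(x$genome_median)))
  invisible(x)
}

#' Write / read a depth profile as samtools-depth-compatible TSV
#'
#' Three columns (chrom, 1-based position, depth), covered positions only.
#'
#' @param profile A \code{depth_profile}.
#' @param path TSV path (\code{.gz} supported).
#' @return \code{write_depth}: invisibly, the path; \code{read_depth}: a
#'   \code{depth_profile}.
#' @export
write_depth <- function(profile, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  for (ch in names(profile$depth)) {
    d <- as.integer(profile$depth[[ch]])
    p <- which(d > 0L)
    if (length(p)) writeLines(paste(ch, p, d[p], sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_depth
#' @export
read_depth <- function(path) {
  dt <- .fread_maybe_gz(path, header = FALSE,
                        col.names = c("chrom", "pos", "depth"))
  depth <- lapply(split(dt, by = "chrom", sorted = TRUE), function(d) {
    v <- integer(max(d$pos))
    v[d$pos] <- as.integer(d$depth)
    S4Vectors::Rle(v)
  })
  vals <- unlist(lapply(depth, S4Vectors::runValue))
  lens <- unlist(lapply(depth, S4Vectors::runLength))
  keep <- vals > 0
  vals <- vals[keep]; lens <- lens[keep]
  o <- order(vals)
  cw <- cumsum(as.numeric(lens[o]))
  med <- if (length(vals)) vals[o][which(cw >= cw[length(cw)] / 2)[1]] else NA_real_
  structure(list(depth = depth, genome_median = as.numeric(med)),
            class = "depth_profile")
}

#' Remove crossover calls in regions of anomalous depth
#'
#' For each call, the mean depth over the supporting read's aligned span is
#' compared with the genome median; calls with mean depth below
#' \code{low_mult} x median or above \code{high_mult} x median are removed.
#' The default bounds (0.25x, 2x) are a symmetric-on-log guard against
#' dropouts and collapsed-repeat pileups; \code{c(0, Inf)} disables the
#' filter.
#'
#' @param scan A \code{crossover_scan} or its \code{calls} data.frame (needs
#'   columns \code{chrom}, \code{aln_start}, \code{aln_end}).
#' @param profile A \code{depth_profile} covering the calls' chromosomes.
#' @param low_mult,high_mult Multiples of the genome median bounding normal
#'   depth.
#' @return list with \code{kept} and \code{removed} call tables;
#'   \code{removed} gains \code{mean_depth} and \code{reason}
#'   (\code{"low_depth"}, \code{"high_depth"} or \code{"no_depth"} for calls
#'   on contigs absent from the profile).
#' @export
filter_by_coverage <- function(scan, profile, low_mult = 0.25, high_mult = 2.0) {
  calls <- if (inherits(scan, "crossover_scan")) scan$calls else scan
  stopifnot(inherits(profile, "depth_profile"), low_mult <= high_mult)
  n <- nrow(calls)
  md <- rep(NA_real_, n)
  for (ch in unique(calls$chrom)) {
    k <- which(calls$chrom == ch)
    d <- profile$depth[[ch]]
    if (is.null(d)) next
    gl <- length(d)
    s <- pmin(pmax(calls$aln_start[k] + 1L, 1L), gl)
    e <- pmin(pmax(calls$aln_end[k], 1L), gl)
    md[k] <- IRanges::viewMeans(IRanges::Views(d, start = s, end = e))
  }
  gm <- profile$genome_median
  lo <- !is.na(md) & md < low_mult * gm
  hi <- !is.na(md) & md > high_mult * gm
  out <- is.na(md) | lo | hi
  removed <- calls[out, , drop = FALSE]
  removed$mean_depth <- md[out]
  removed$reason <- ifelse(is.na(md[out]), "no_depth",
                           ifelse(md[out] < low_mult * gm, "low_depth",
                                  "high_depth"))
  list(kept = calls[!out, , drop = FALSE], removed = removed)
}
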