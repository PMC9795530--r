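# Homopolymer compression and the compressed<->original coordinate map.
#
# All internal coordinates are 0-based half-open; VCF/SAM boundaries convert
# to and from 1-based at I/O time.

# fread with transparent gzip support (gz decompressed through a connection)
.fread_maybe_gz <- function(path, ...) {
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "r")
    on.exit(close(con))
    data.table::fread(text = readLines(con), ...)
  } else {
    data.table::fread(path, ...)
  }
}

#' Homopolymer-compress a nucleotide sequence
#'
#' Collapses every maximal run of identical nucleotides (case-insensitive)
#' to a single base, e.g. \code{"AGTTTCG"} becomes \code{"AGTCG"}.  Long-read
#' (nanopore) sequencers miscall homopolymer lengths far more often than they
#' miscall the base identity, so working in compressed space removes the
#' dominant error mode while preserving the heterozygous substitution signal
#' the crossover detector relies on.
#'
#' @param seq A single character string over A/C/G/T/N (case preserved in the
#'   output; runs are found case-insensitively).
#' @return An object of class \code{compressed_sequence}: a list with
#'   \describe{
#'     \item{seq}{the compressed sequence (no two adjacent identical bases),}
#'     \item{run_lengths}{integer vector, original run length per compressed
#'       position,}
#'     \item{run_starts}{integer vector, 0-based original start coordinate of
#'       each run (\code{run_starts[i+1] == run_starts[i] + run_lengths[i]}).}
#'   }
#' @examples
#' cs <- compress_sequence("AGTTTCG")
#' cs$seq          # "AGTCG"
#' cs$run_lengths  # 1 1 3 1 1
#' @seealso [build_position_map()], [lift_to_original()], [compress_reads()]
#' @export
compress_sequence <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  res <- .hpc_compress_one(seq)
  rl <- res$run_lengths
  structure(
    list(seq = res$seq,
         run_lengths = rl,
         run_starts = if (length(rl)) cumsum(c(0L, rl[-length(rl)])) else integer(0)),
    class = "compressed_sequence",
    original_length = sum(rl)
  )
}

#' @export
print.compressed_sequence <- function(x, ...) {
  n <- nchar(x$seq)
  cat(sprintf("compressed_sequence: %d bases (original %d, ratio %.3f)\n",
              n, attr(x, "original_length"),
              if (attr(x, "original_length") > 0) n / attr(x, "original_length") else NA_real_))
  if (n > 0) cat(" ", substr(x$seq, 1L, min(n, 60L)),
                 if (n > 60) "..." else "", "\n", sep = "")
  invisible(x)
}

#' Homopolymer-compress a FASTQ file of reads
#'
#' Applies [compress_sequence()] to every read.  Per-base qualities are
#' reduced by keeping the maximum quality value within each collapsed run
#' (the strongest evidence for the retained base).  Read identifiers are
#' preserved.
#'
#' @param fastq_in,fastq_out Paths (plain or gzipped FASTQ).
#' @return Invisibly, the number of reads written.
#' @export
compress_reads <- function(fastq_in, fastq_out) {
  if (!file.exists(fastq_in)) stop("FASTQ not found: ", fastq_in)
  nlines <- length(readLines(fastq_in, warn = FALSE))
  if (nlines %% 4L != 0L)
    stop(sprintf("truncated FASTQ '%s': record %d is incomplete",
                 fastq_in, nlines %/% 4L + 1L))
  if (nlines == 0L) {
    file.create(fastq_out)
    return(invisible(0L))
  }
  reads <- Biostrings::readDNAStringSet(fastq_in, format = "fastq",
                                        with.qualities = TRUE)
  quals <- as.character(S4Vectors::mcols(reads)$qualities)
  res <- .hpc_compress_batch(as.character(reads), quals)
  .write_fastq(names(reads), res$seq, res$qual, fastq_out)
  invisible(length(reads))
}

# plain-text FASTQ writer (no record-length limit, unlike the stream writers
# of the usual string classes, which cap line length well below ONT reads)
.write_fastq <- function(ids, seqs, quals, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", quals)), con)
  invisible(path)
}

#' Build the compressed/original position correspondence map for a reference
#'
#' For each chromosome of the (uncompressed) reference, records the original
#' half-open interval \code{[run_start, run_start + run_length)} behind every
#' compressed position.  This is the file that lets crossover intervals,
#' estimated in compressed space, be restored to original coordinates.
#'
#' @param reference A FASTA path or a [Biostrings::DNAStringSet].
#' @return An object of class \code{position_map}: per-chromosome list with
#'   integer vectors \code{run_starts} and \code{run_lengths}; attributes
#'   \code{original_lengths} and \code{compressed_lengths} (named integer
#'   vectors).
#' @seealso [write_position_map()], [load_position_map()], [lift_to_original()]
#' @export
build_position_map <- function(reference) {
  ref <- if (inherits(reference, "DNAStringSet")) reference
         else Biostrings::readDNAStringSet(reference)
  nm <- names(ref)
  nm <- sub("\\s.*$", "", nm)  # FASTA description -> id
  if (anyDuplicated(nm)) stop("duplicate chromosome names in reference: ",
                              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  chroms <- lapply(seq_along(ref), function(i) {
    cs <- compress_sequence(as.character(ref[[i]]))
    list(run_starts = cs$run_starts, run_lengths = cs$run_lengths)
  })
  names(chroms) <- nm
  structure(chroms,
            class = "position_map",
            original_lengths = setNames(vapply(chroms, function(x)
              sum(x$run_lengths), 0L), nm),
            compressed_lengths = setNames(vapply(chroms, function(x)
              length(x$run_lengths), 0L), nm))
}

#' @export
print.position_map <- function(x, ...) {
  ol <- attr(x, "original_lengths"); cl <- attr(x, "compressed_lengths")
  cat(sprintf("position_map: %d chromosome(s)\n", length(x)))
  for (nm in names(x))
    cat(sprintf("  %s: %d -> %d (ratio %.3f)\n", nm, ol[[nm]], cl[[nm]],
                cl[[nm]] / ol[[nm]]))
  invisible(x)
}

#' Write / load a position map as TSV
#'
#' Columns \code{chrom}, \code{compressed_pos} (0-based), \code{orig_start},
#' \code{orig_end} (0-based half-open).  Gzip-compressed when the path ends
#' in \code{.gz} (the default recommendation: maps have one row per
#' compressed base).
#'
#' @param map A \code{position_map}.
#' @param path Output TSV path (\code{.gz} for gzip).
#' @return \code{write_position_map}: invisibly, the path.
#' @export
write_position_map <- function(map, path) {
  stopifnot(inherits(map, "position_map"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines("chrom\tcompressed_pos\torig_start\torig_end", con)
  for (nm in names(map)) {
    rs <- map[[nm]]$run_starts
    re <- rs + map[[nm]]$run_lengths
    if (length(rs))
      writeLines(paste(nm, seq_along(rs) - 1L, rs, re, sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_position_map
#' @return \code{load_position_map}: the \code{position_map}.
#' @export
load_position_map <- function(path) {
  dt <- .fread_maybe_gz(path, header = TRUE,
                        colClasses = list(character = "chrom"))
  if (!all(c("chrom", "compressed_pos", "orig_start", "orig_end") %in% names(dt)))
    stop("not a position map file: ", path)
  sp <- split(dt, by = "chrom", sorted = FALSE)
  chroms <- lapply(sp, function(d) {
    d <- d[order(d$compressed_pos), ]
    list(run_starts = as.integer(d$orig_start),
         run_lengths = as.integer(d$orig_end - d$orig_start))
  })
  structure(chroms,
            class = "position_map",
            original_lengths = setNames(vapply(chroms, function(x)
              sum(x$run_lengths), 0L), names(chroms)),
            compressed_lengths = setNames(vapply(chroms, function(x)
              length(x$run_lengths), 0L), names(chroms)))
}

#' Lift a compressed-coordinate interval back to original coordinates
#'
#' Returns the smallest original half-open interval covering all original
#' bases of the runs inside the compressed interval.  Vectorised over
#' \code{start}/\code{end}; nested compressed intervals map to nested
#' original intervals, and adjacent compressed intervals map to adjacent
#' original intervals.
#'
#' @param map A \code{position_map}.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open compressed interval(s).
#' @return A data.frame with columns \code{orig_start}, \code{orig_end}.
#' @export
lift_to_original <- function(map, chrom, start, end) {
  stopifnot(inherits(map, "position_map"))
  if (!chrom %in% names(map)) stop("chromosome not in position map: ", chrom)
  m <- map[[chrom]]
  nc <- length(m$run_lengths)
  start <- as.integer(start); end <- as.integer(end)
  if (length(start) != length(end)) stop("start and end differ in length")
  if (any(is.na(start) | is.na(end)) || any(start < 0L) || any(end > nc) ||
      any(start > end))
    stop(sprintf("interval out of range for %s (compressed length %d)", chrom, nc))
  run_ends <- m$run_starts + m$run_lengths
  os <- ifelse(start < nc, m$run_starts[start + 1L],
               if (nc > 0) run_ends[nc] else 0L)
  oe <- ifelse(end > start, run_ends[pmax(end, 1L)], os)
  data.frame(orig_start = as.integer(os), orig_end = as.integer(oe))
}
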