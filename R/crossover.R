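# Core crossover detection: per-read haplotype scoring, sliding-window
# phasing, and phase-switch calling.
#
# Per haplotype site a read scores +1 when it carries the haplotype-A allele,
# -1 for the haplotype-B allele and 0 otherwise (sequencing error, deletion,
# unknown).  A 7-site window (the centre plus window_flank = 3 sites each
# side) slides along the score vector with step one, from the fourth site to
# the fourth-from-last; with Ln the number of non-zero scores in the window,
# the centre is called HapA when sum/Ln >= 4/6, HapB when sum/Ln <= -4/6
# (inclusive), and NA otherwise or when fewer than min_represented informative
# sites are present.  A read whose NA-free phase vector contains both HapA
# and HapB is a candidate recombinant molecule.

# integer phase calls for one score vector: 1 = HapA, -1 = HapB, 0 = NA
.phase_calls <- function(sc, flank = 3L, min_rep = 5L, thr = 4 / 6) {
  n <- length(sc)
  if (n < 2L * flank + 1L) return(integer(0))
  cs <- c(0, cumsum(sc))
  cz <- c(0L, cumsum(sc != 0L))
  i <- (flank + 1L):(n - flank)
  W <- cs[i + flank + 1L] - cs[i - flank]
  Ln <- cz[i + flank + 1L] - cz[i - flank]
  out <- integer(length(i))
  el <- Ln >= min_rep
  out[el & W >= thr * Ln] <- 1L
  out[el & W <= -thr * Ln] <- -1L
  out
}

.check_phase_params <- function(window_flank, min_represented, threshold) {
  stopifnot(is.numeric(window_flank), window_flank >= 1L,
            is.numeric(min_represented), min_represented >= 1L)
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]")
}

#' Extract read bases over haplotype sites by walking the CIGAR
#'
#' Computes the reference span of an alignment from its CIGAR and returns the
#' read base aligned to every haplotype site inside that span.  Sites under
#' deletions yield \code{NA} (unknown); insertions and clips consume read
#' bases without creating sites.
#'
#' @param read A list or one-row data.frame with elements \code{chrom},
#'   \code{pos} (0-based leftmost reference position), \code{cigar},
#'   \code{seq}.
#' @param haplotypes A [haplotype_table()].
#' @return data.frame with columns \code{pos} (0-based site coordinate) and
#'   \code{base} (upper-case character, \code{NA} for unknown).
#' @export
extract_genotypes <- function(read, haplotypes) {
  s <- haplotypes[haplotypes$chrom == as.character(read$chrom), , drop = FALSE]
  if (nrow(s) == 0L)
    return(data.frame(pos = integer(0), base = character(0)))
  res <- .score_alignments_cpp(as.integer(read$pos), as.character(read$cigar),
                               as.character(read$seq), s$pos,
                               paste(s$hap_a, collapse = ""),
                               paste(s$hap_b, collapse = ""))
  if (!res$ok[1])
    stop(sprintf("read '%s': CIGAR-implied read length does not match sequence length",
                 if (!is.null(read$read_id)) read$read_id else "?"))
  base <- rawToChar(res$base, multiple = TRUE)
  base[base == "-"] <- NA_character_
  data.frame(pos = s$pos[res$site], base = base, stringsAsFactors = FALSE)
}

#' Score a read's genotypes against the two haplotypes
#'
#' Per covered site: +1 if the read base equals the haplotype-A allele, -1 if
#' it equals the haplotype-B allele, 0 otherwise (including unknowns).
#'
#' @param genotypes Output of [extract_genotypes()].
#' @param haplotypes A [haplotype_table()] (one chromosome's sites).
#' @return data.frame of class \code{score_vector} with columns \code{pos},
#'   \code{base}, \code{score}.
#' @export
score_read <- function(genotypes, haplotypes) {
  m <- match(genotypes$pos, haplotypes$pos)
  if (anyNA(m)) stop("genotype positions missing from haplotype table")
  base <- toupper(genotypes$base)
  score <- integer(length(base))
  score[!is.na(base) & base == haplotypes$hap_a[m]] <- 1L
  score[!is.na(base) & base == haplotypes$hap_b[m]] <- -1L
  out <- data.frame(pos = genotypes$pos, base = genotypes$base, score = score,
                    stringsAsFactors = FALSE)
  class(out) <- c("score_vector", "data.frame")
  out
}

#' Sliding-window phase estimation over a haplotype score vector
#'
#' Traverses the score vector from position \code{window_flank + 1} to
#' \code{length - window_flank} with step one; each window holds the centre
#' and \code{window_flank} sites on either side (7 sites at the default).
#' With \code{Ln} the number of non-zero scores in the window, the centre is
#' called \code{HapA} when \code{sum(window)/Ln >= threshold}, \code{HapB}
#' when \code{<= -threshold} (both inclusive), and \code{NA} otherwise or
#' when \code{Ln < min_represented}.
#'
#' @param scores Integer vector over \{-1, 0, +1\} (or a \code{score_vector}
#'   from [score_read()]).
#' @param window_flank Sites on each side of the centre (default 3).
#' @param min_represented Minimum informative (non-zero) sites per window
#'   (default 5).
#' @param threshold Phase-call threshold on the mean non-zero score
#'   (default 4/6).
#' @param positions Optional site coordinates parallel to \code{scores}.
#' @return data.frame of class \code{phase_vector} with columns \code{index}
#'   (position in the score vector, 1-based), \code{pos} (if given),
#'   \code{ln}, and \code{call} (\code{"HapA"}, \code{"HapB"} or \code{NA}).
#'   Empty when the vector has fewer than \code{2*window_flank + 1} sites.
#' @export
phase_windows <- function(scores, window_flank = 3L, min_represented = 5L,
                          threshold = 4 / 6, positions = NULL) {
  if (inherits(scores, "score_vector")) {
    positions <- scores$pos
    scores <- scores$score
  }
  .check_phase_params(window_flank, min_represented, threshold)
  stopifnot(all(scores %in% c(-1L, 0L, 1L)))
  n <- length(scores)
  flank <- as.integer(window_flank)
  calls <- .phase_calls(scores, flank, as.integer(min_represented), threshold)
  idx <- if (n >= 2L * flank + 1L) (flank + 1L):(n - flank) else integer(0)
  cz <- c(0L, cumsum(scores != 0L))
  ln <- if (length(idx)) cz[idx + flank + 1L] - cz[idx - flank] else integer(0)
  out <- data.frame(index = idx, ln = ln,
                    call = c("HapB", NA, "HapA")[calls + 2L],
                    stringsAsFactors = FALSE)
  if (!is.null(positions)) out$pos <- positions[idx]
  class(out) <- c("phase_vector", "data.frame")
  out
}

#' Call phase switches (crossovers) from a phase vector
#'
#' Drops NA calls; if the remaining sequence contains both \code{HapA} and
#' \code{HapB}, one call is emitted per transition.  The switch interval runs
#' from the last site of the outgoing phase to the first site of the incoming
#' phase, reported 0-based half-open as \code{[last_out + 1, first_in + 1)}
#' so that the true exchange point is contained in it.
#'
#' @param phase A \code{phase_vector} from [phase_windows()] (with a
#'   \code{pos} column, else \code{index} is used as the coordinate).
#' @return \code{NULL} when no switch, otherwise a data.frame with one row
#'   per transition: \code{comp_start}, \code{comp_end}, \code{n_switches}
#'   (total for the read), \code{flank_out}, \code{flank_in} (supporting call
#'   counts each side), \code{out_phase}, \code{in_phase}.
#' @export
call_crossover <- function(phase) {
  pos <- if (!is.null(phase$pos)) phase$pos else phase$index
  nz <- which(!is.na(phase$call))
  if (length(nz) < 2L) return(NULL)
  v <- phase$call[nz]
  cp <- which(v[-1] != v[-length(v)])
  if (length(cp) == 0L) return(NULL)
  r <- rle(v)
  rend <- cumsum(r$lengths)
  data.frame(comp_start = pos[nz[rend[-length(rend)]]] + 1L,
             comp_end = pos[nz[rend[-length(rend)] + 1L]] + 1L,
             n_switches = length(cp),
             flank_out = r$lengths[-length(r$lengths)],
             flank_in = r$lengths[-1],
             out_phase = r$values[-length(r$values)],
             in_phase = r$values[-1],
             stringsAsFactors = FALSE)
}

#' Detect recombinant molecules across a whole alignment set
#'
#' Applies extract -> score -> phase -> call to every alignment.  Sites from
#' different phase sets are never combined in one window: each (chromosome,
#' phase set) is scored separately, and switches are called only within a
#' phase set.  Reads spanning fewer than \code{2*window_flank + 1} sites
#' yield no phase calls and can never be recombinant.
#'
#' @param aln A BAM path or an alignment table (see [read_alignments()]);
#'   expected to be pre-filtered ([filter_alignments()] /
#'   [filter_alignment_table()]).
#' @param haplotypes A [haplotype_table()].
#' @inheritParams phase_windows
#' @param position_map Optional [build_position_map()] result; when supplied,
#'   switch intervals are also reported in original coordinates.
#' @return An object of class \code{crossover_scan}: list with
#'   \describe{
#'     \item{calls}{data.frame, one row per phase transition: \code{read_id},
#'       \code{chrom}, \code{phase_set}, \code{comp_start}, \code{comp_end},
#'       \code{orig_start}, \code{orig_end}, \code{n_switches},
#'       \code{flank_A}, \code{flank_B}, \code{multi_switch},
#'       \code{aln_start}, \code{aln_end}, sorted by (chrom, comp_start,
#'       read_id);}
#'     \item{reads}{per-read summary: \code{read_id}, \code{chrom},
#'       \code{n_sites}, \code{n_informative}, \code{n_calls}, \code{n_A},
#'       \code{n_B}, \code{n_switches}, \code{recombinant};}
#'     \item{params}{the parameters used.}
#'   }
#' @export
detect_crossovers <- function(aln, haplotypes, window_flank = 3L,
                              min_represented = 5L, threshold = 4 / 6,
                              position_map = NULL) {
  if (is.character(aln)) aln <- read_alignments(aln)
  .check_phase_params(window_flank, min_represented, threshold)
  flank <- as.integer(window_flank)
  minr <- as.integer(min_represented)
  n_aln <- nrow(aln)
  rs <- list(read_id = aln$read_id, chrom = aln$chrom,
             n_sites = integer(n_aln), n_informative = integer(n_aln),
             n_calls = integer(n_aln), n_A = integer(n_aln),
             n_B = integer(n_aln), n_switches = integer(n_aln))
  call_rows <- list()
  for (ch in unique(aln$chrom)) {
    sch <- haplotypes[haplotypes$chrom == ch, , drop = FALSE]
    ri <- which(aln$chrom == ch)
    if (nrow(sch) == 0L) {
      warning("contig '", ch, "' has no haplotype sites; ",
              length(ri), " alignment(s) skipped")
      next
    }
    for (ps in unique(sch$phase_set)) {
      s <- sch[sch$phase_set == ps, , drop = FALSE]
      res <- .score_alignments_cpp(aln$pos[ri], aln$cigar[ri], aln$seq[ri],
                                   s$pos, paste(s$hap_a, collapse = ""),
                                   paste(s$hap_b, collapse = ""))
      if (!all(res$ok))
        warning("skipped ", sum(!res$ok), " read(s) on '", ch,
                "' with CIGAR/sequence length mismatch: ",
                paste(head(aln$read_id[ri][!res$ok], 5L), collapse = ", "))
      if (length(res$read) == 0L) next
      bnd <- c(0L, which(diff(res$read) != 0L), length(res$read))
      for (g in seq_len(length(bnd) - 1L)) {
        a <- bnd[g] + 1L; b <- bnd[g + 1L]
        r <- ri[res$read[a]]
        sc <- res$score[a:b]
        rs$n_sites[r] <- rs$n_sites[r] + (b - a + 1L)
        rs$n_informative[r] <- rs$n_informative[r] + sum(sc != 0L)
        calls <- .phase_calls(sc, flank, minr, threshold)
        if (!length(calls)) next
        rs$n_calls[r] <- rs$n_calls[r] + sum(calls != 0L)
        rs$n_A[r] <- rs$n_A[r] + sum(calls == 1L)
        rs$n_B[r] <- rs$n_B[r] + sum(calls == -1L)
        nzi <- which(calls != 0L)
        if (length(nzi) < 2L) next
        v <- calls[nzi]
        cp <- which(v[-1] != v[-length(v)])
        if (!length(cp)) next
        rs$n_switches[r] <- rs$n_switches[r] + length(cp)
        # site index (within s) of each evaluated window centre
        centre_site <- res$site[a:b][(flank + 1L):((b - a + 1L) - flank)]
        rn <- rle(v)
        rend <- cumsum(rn$lengths)
        out_i <- nzi[rend[-length(rend)]]
        in_i <- nzi[rend[-length(rend)] + 1L]
        out_ph <- rn$values[-length(rn$values)]
        call_rows[[length(call_rows) + 1L]] <- data.frame(
          read_id = aln$read_id[r], chrom = ch, phase_set = ps,
          comp_start = s$pos[centre_site[out_i]] + 1L,
          comp_end = s$pos[centre_site[in_i]] + 1L,
          n_switches = length(cp),
          flank_A = ifelse(out_ph == 1L, rn$lengths[-length(rn$lengths)],
                           rn$lengths[-1]),
          flank_B = ifelse(out_ph == 1L, rn$lengths[-1],
                           rn$lengths[-length(rn$lengths)]),
          aln_start = aln$pos[r],
          aln_end = aln$pos[r] + res$ref_width[res$read[a]],
          stringsAsFactors = FALSE)
      }
    }
  }
  calls <- if (length(call_rows)) do.call(rbind, call_rows) else
    data.frame(read_id = character(0), chrom = character(0),
               phase_set = character(0), comp_start = integer(0),
               comp_end = integer(0), n_switches = integer(0),
               flank_A = integer(0), flank_B = integer(0),
               aln_start = integer(0), aln_end = integer(0),
               stringsAsFactors = FALSE)
  calls$multi_switch <- calls$n_switches >= 2L
  calls$orig_start <- rep(NA_integer_, nrow(calls))
  calls$orig_end <- rep(NA_integer_, nrow(calls))
  if (!is.null(position_map) && nrow(calls)) {
    for (ch in unique(calls$chrom)) {
      k <- calls$chrom == ch
      li <- lift_to_original(position_map, ch, calls$comp_start[k],
                             calls$comp_end[k])
      calls$orig_start[k] <- li$orig_start
      calls$orig_end[k] <- li$orig_end
    }
  }
  calls <- calls[order(calls$chrom, calls$comp_start, calls$read_id), ,
                 drop = FALSE]
  rownames(calls) <- NULL
  cols <- c("read_id", "chrom", "phase_set", "comp_start", "comp_end",
            "orig_start", "orig_end", "n_switches", "flank_A", "flank_B",
            "multi_switch", "aln_start", "aln_end")
  reads <- as.data.frame(rs, stringsAsFactors = FALSE)
  reads$recombinant <- reads$n_switches >= 1L
  structure(list(calls = calls[, cols, drop = FALSE], reads = reads,
                 params = list(window_flank = flank, min_represented = minr,
                               threshold = threshold)),
            class = "crossover_scan")
}

#' @export
print.crossover_scan <- function(x, ...) {
  cat(sprintf(
    "crossover_scan: %d alignment(s), %d recombinant read(s), %d switch call(s)\n",
    nrow(x$reads), sum(x$reads$recombinant), nrow(x$calls)))
  cat(sprintf("  params: window_flank=%d, min_represented=%d, threshold=%.4g\n",
              x$params$window_flank, x$params$min_represented,
              x$params$threshold))
  invisible(x)
}

#' Write crossover calls as TSV and BED
#'
#' @param scan A \code{crossover_scan} (or its \code{calls} data.frame).
#' @param tsv Output TSV path.
#' @param bed Optional BED path (original coordinates; rows lacking a lifted
#'   interval are skipped).
#' @return Invisibly, the TSV path.
#' @export
write_crossover_calls <- function(scan, tsv, bed = NULL) {
  calls <- if (inherits(scan, "crossover_scan")) scan$calls else scan
  write.table(calls, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bed)) {
    b <- calls[!is.na(calls$orig_start), , drop = FALSE]
    writeLines(sprintf("%s\t%d\t%d\t%s", b$chrom, b$orig_start, b$orig_end,
                       b$read_id), bed)
  }
  invisible(tsv)
}
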