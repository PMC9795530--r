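# Brute-force oracles and fixture builders, independent of the package's
# implementation paths.

# expand a compressed sequence by its run lengths (decompression oracle)
oracle_expand <- function(comp, run_lengths) {
  paste(rep(strsplit(comp, "")[[1]], run_lengths), collapse = "")
}

# random nucleotide sequence with homopolymer runs
random_seq <- function(n, run_prob = 0.35) {
  b <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  reps <- 1L + stats::rgeom(n, prob = 1 - run_prob)
  paste(rep(b, reps)[seq_len(n)], collapse = "")
}

# per-base CIGAR expansion: read base aligned to every reference position
# (NA under deletions); returns a function of 0-based site positions
oracle_aligned_bases <- function(pos, cigar, seq) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  len <- as.integer(sub("[A-Z=]", "", ops))
  op <- sub("\\d+", "", ops)
  chars <- strsplit(seq, "")[[1]]
  ref <- pos; rd <- 0L
  ref_pos <- integer(0); base <- character(0)
  for (i in seq_along(op)) {
    if (op[i] %in% c("M", "=", "X")) {
      ref_pos <- c(ref_pos, ref + seq_len(len[i]) - 1L)
      base <- c(base, chars[rd + seq_len(len[i])])
      ref <- ref + len[i]; rd <- rd + len[i]
    } else if (op[i] %in% c("D", "N")) {
      ref_pos <- c(ref_pos, ref + seq_len(len[i]) - 1L)
      base <- c(base, rep(NA_character_, len[i]))
      ref <- ref + len[i]
    } else if (op[i] %in% c("I", "S")) {
      rd <- rd + len[i]
    }
  }
  function(sites) base[match(sites, ref_pos)]
}

# exhaustive per-window phase recomputation (explicit loop, no cumsums)
oracle_phase_calls <- function(sc, flank = 3L, min_rep = 5L, thr = 4 / 6) {
  n <- length(sc)
  if (n < 2L * flank + 1L) return(character(0))
  out <- character(n - 2L * flank)
  for (k in seq_along(out)) {
    centre <- k + flank
    w <- sc[(centre - flank):(centre + flank)]
    ln <- sum(w != 0)
    out[k] <- if (ln < min_rep) NA_character_
      else if (sum(w) / ln >= thr) "HapA"
      else if (sum(w) / ln <= -thr) "HapB"
      else NA_character_
  }
  out
}

# brute-force clustered-variant scan over every possible window start
oracle_clustered_drop <- function(pos, span = 10L, max_in = 3L) {
  drop <- logical(length(pos))
  if (!length(pos)) return(drop)
  for (s in (min(pos) - span + 1L):max(pos)) {
    inw <- which(pos >= s & pos <= s + span - 1L)
    if (length(inw) > max_in) drop[inw] <- TRUE
  }
  drop
}

# smoothed-histogram valley between two known mode locations
oracle_valley <- function(x, lo, hi) {
  h <- hist(x, breaks = seq(min(x) - 20, max(x) + 20, by = 5), plot = FALSE)
  y <- as.numeric(stats::filter(h$counts, rep(1 / 9, 9), sides = 2))
  mid <- h$mids
  sel <- which(mid > lo & mid < hi & !is.na(y))
  mid[sel][which.min(y[sel])]
}

# minimal single-sample VCF writer for fixtures
make_vcf <- function(df, path, contigs = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           if (!is.null(contigs))
             sprintf("##contig=<ID=%s,length=%d>", names(contigs), contigs),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=PS,Number=1,Type=Integer,Description=\"Phase set\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1")
  fmt <- if (!is.null(df$ps)) "GT:PS" else "GT"
  smp <- if (!is.null(df$ps)) paste0(df$gt, ":", df$ps) else df$gt
  writeLines(c(hdr, paste(df$chrom, df$pos1, ".", df$ref, df$alt,
                          df$qual, "PASS", ".", fmt, smp, sep = "\t")), path)
  path
}

make_fastq <- function(ids, seqs, quals, path) {
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", quals)), path)
  path
}

# shared validation grid for the acceptance checks (computed once per run)
.accept_cache <- new.env(parent = emptyenv())
acceptance_grid <- function() {
  if (is.null(.accept_cache$grid))
    .accept_cache$grid <- run_grid(spacings = c(100, 200, 300),
                                   depths = seq(20, 70, 10), reps = 3L,
                                   seed = 1L, genome_length = 5e6)
  .accept_cache$grid
}
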