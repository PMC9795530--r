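# Core detection: CIGAR-walk genotype extraction, per-site scoring,
# sliding-window phasing and phase-switch calling.

toy_haps <- function(pos, a, b, chrom = "chr1") {
  haplotype_table(rep(chrom, length(pos)), pos, a, b)
}

test_that("extract_genotypes walks matches, deletions and insertions", {
  h <- toy_haps(c(10L, 20L), c("A", "C"), c("G", "T"))
  seq30 <- paste(rep("A", 30), collapse = "")
  g <- extract_genotypes(list(chrom = "chr1", pos = 0L, cigar = "30M",
                              seq = seq30), h)
  expect_equal(g$pos, c(10L, 20L))
  expect_equal(g$base, c("A", "A"))

  # deletion spanning the second site -> unknown
  g2 <- extract_genotypes(list(chrom = "chr1", pos = 0L, cigar = "15M10D15M",
                               seq = seq30), h)
  expect_equal(g2$base, c("A", NA))

  # insertion shifts read offsets but creates no sites
  sq <- paste(c(rep("C", 12), "TTT", rep("C", 18)), collapse = "")
  g3 <- extract_genotypes(list(chrom = "chr1", pos = 0L, cigar = "12M3I18M",
                               seq = sq), h)
  expect_equal(g3$base, c("C", "C"))
})

test_that("extract_genotypes agrees with a brute-force aligned-pairs oracle", {
  set.seed(17)
  sites <- sort(sample(0:400, 60))
  h <- toy_haps(sites, rep("A", 60), rep("C", 60))
  for (i in 1:40) {
    nops <- sample(3:9, 1)
    op <- c("M", sample(c("M", "I", "D", "S", "M"), nops - 2, replace = TRUE), "M")
    len <- sample(1:40, nops, replace = TRUE)
    cigar <- paste0(len, op, collapse = "")
    readlen <- sum(len[op %in% c("M", "I", "S")])
    seq <- paste(sample(c("A", "C", "G", "T"), readlen, replace = TRUE),
                 collapse = "")
    pos <- sample(0:50, 1)
    got <- extract_genotypes(list(chrom = "chr1", pos = pos, cigar = cigar,
                                  seq = seq), h)
    refw <- sum(len[op %in% c("M", "D")])
    want_sites <- sites[sites >= pos & sites < pos + refw]
    oracle <- oracle_aligned_bases(pos, cigar, seq)
    expect_equal(got$pos, want_sites)
    expect_equal(got$base, unname(oracle(want_sites)))
  }
})

test_that("extract_genotypes rejects CIGAR/sequence length mismatches", {
  h <- toy_haps(5L, "A", "C")
  expect_error(extract_genotypes(list(chrom = "chr1", pos = 0L, cigar = "10M",
                                      seq = "ACGT", read_id = "bad"), h),
               "length")
})

test_that("score_read implements the +1/-1/0 site scoring", {
  h <- toy_haps(c(2L, 5L, 9L), c("A", "C", "G"), c("T", "G", "A"))
  g <- data.frame(pos = c(2L, 5L, 9L), base = c("A", "G", "C"))
  sc <- score_read(g, h)
  expect_equal(sc$score, c(1L, -1L, 0L))   # hapA match, hapB match, neither
  g2 <- data.frame(pos = c(2L, 5L), base = c(NA, "C"))
  expect_equal(score_read(g2, h)$score, c(0L, 1L))  # unknown scores 0
})

test_that("scoring against random haplotypes matches a direct comparison", {
  set.seed(18)
  n <- 200
  pos <- sort(sample.int(5000L, n)) - 1L
  a <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  b <- vapply(a, function(x) sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
  h <- toy_haps(pos, a, b)
  base <- sample(c("A", "C", "G", "T", NA), n, replace = TRUE)
  sc <- score_read(data.frame(pos = pos, base = base), h)
  direct <- ifelse(is.na(base), 0L, ifelse(base == a, 1L,
                                           ifelse(base == b, -1L, 0L)))
  expect_equal(sc$score, unname(direct))
})

test_that("phase_windows reproduces the window-rule arithmetic", {
  p <- phase_windows(rep(1L, 7))
  expect_equal(p$index, 4L)
  expect_equal(p$ln, 7L)
  expect_equal(p$call, "HapA")                    # 7/7 = 1 >= 4/6

  expect_equal(phase_windows(c(1L, 1L, 1L, 1L, 1L, 1L, -1L))$call, "HapA")
  # 5/7 ~ 0.714 >= 4/6
  expect_equal(phase_windows(c(1L, 1L, 0L, 1L, 1L, -1L, -1L))$call,
               NA_character_)                     # Ln = 6, 2/6 < 4/6
  expect_equal(phase_windows(rep(-1L, 7))$call, "HapB")
  expect_equal(nrow(phase_windows(rep(1L, 6))), 0L)  # too short
  expect_equal(nrow(phase_windows(rep(1L, 9))), 3L)  # len - 6 evaluated sites
})

test_that("the minimum-represented rule yields NA calls", {
  sc <- c(1L, 0L, 0L, 1L, 0L, 0L, 1L)   # Ln = 3 < 5
  expect_equal(phase_windows(sc)$call, NA_character_)
  expect_equal(phase_windows(sc, min_represented = 3L)$call, "HapA")
})

test_that("phase_windows matches the brute-force oracle on random vectors", {
  set.seed(19)
  for (i in 1:300) {
    n <- sample(7:50, 1)
    sc <- sample(c(-1L, 0L, 1L), n, replace = TRUE)
    expect_equal(phase_windows(sc)$call, oracle_phase_calls(sc))
  }
})

test_that("negating scores swaps HapA and HapB calls", {
  set.seed(20)
  for (i in 1:50) {
    sc <- sample(c(-1L, 0L, 1L), 30, replace = TRUE)
    p1 <- phase_windows(sc)$call
    p2 <- phase_windows(-sc)$call
    expect_equal(p2, c(HapA = "HapB", HapB = "HapA")[p1],
                 ignore_attr = TRUE)
  }
})

test_that("call_crossover finds transitions across dropped NAs", {
  mk <- function(calls) data.frame(index = seq_along(calls), ln = 7L,
                                   call = calls, pos = 10L * seq_along(calls))
  expect_null(call_crossover(mk(rep("HapA", 8))))
  cc <- call_crossover(mk(c(rep("HapA", 5), NA, NA, rep("HapB", 5))))
  expect_equal(nrow(cc), 1L)
  expect_equal(cc$n_switches, 1L)
  # between the 5th HapA site (pos 50) and the 1st HapB site (pos 80)
  expect_equal(cc$comp_start, 51L)
  expect_equal(cc$comp_end, 81L)
  expect_equal(c(cc$flank_out, cc$flank_in), c(5L, 5L))

  cc2 <- call_crossover(mk(c("HapA", "HapB", "HapA")))
  expect_equal(nrow(cc2), 2L)
  expect_equal(unique(cc2$n_switches), 2L)
})

test_that("detection on an error-free pool is exact", {
  cfg <- sim_config(genome_length = 1e6, seed = 42, recomb_fraction = 0.3,
                    read_length_mean = 8000, read_length_sd = 1500)
  sim <- simulate_genome(cfg)
  haps <- sim_truth_haplotypes(sim)
  pool <- simulate_reads(sim, depth = 3, seed = 5, error_free = TRUE)
  scan <- detect_crossovers(pool$aln, haps)
  called <- unique(scan$calls$read_id)
  # no error-free non-recombinant read is ever called recombinant
  expect_equal(sum(called %in% pool$truth$read_id[!pool$truth$recombinant]), 0L)
  # every recombinant with >= 7 sites per flank is found, interval contains
  # the true breakpoint
  s <- sim$sites$pos
  for (i in which(pool$truth$recombinant)) {
    tr <- pool$truth[i, ]
    inr <- s[s >= tr$start & s < tr$start + tr$length]
    if (sum(inr < tr$bp_comp) >= 7 && sum(inr >= tr$bp_comp) >= 7) {
      expect_true(tr$read_id %in% called)
      cc <- scan$calls[scan$calls$read_id == tr$read_id, ]
      expect_true(any(cc$comp_start <= tr$bp_comp & tr$bp_comp < cc$comp_end))
    }
  }
})

test_that("an all-noise-free pool with no recombinants yields zero calls", {
  cfg <- sim_config(genome_length = 3e5, seed = 6, recomb_fraction = 0)
  sim <- simulate_genome(cfg)
  pool <- simulate_reads(sim, depth = 5, seed = 7, error_free = TRUE)
  scan <- detect_crossovers(pool$aln, sim_truth_haplotypes(sim))
  expect_equal(nrow(scan$calls), 0L)
})

test_that("global haplotype relabelling swaps phases but not the call set", {
  cfg <- sim_config(genome_length = 4e5, seed = 23)
  sim <- simulate_genome(cfg)
  haps <- sim_truth_haplotypes(sim)
  pool <- simulate_reads(sim, depth = 8, seed = 24)
  swapped <- haplotype_table(haps$chrom, haps$pos, haps$hap_b, haps$hap_a,
                             haps$phase_set)
  s1 <- detect_crossovers(pool$aln, haps)
  s2 <- detect_crossovers(pool$aln, swapped)
  expect_equal(s2$calls$read_id, s1$calls$read_id)
  expect_equal(s2$calls$comp_start, s1$calls$comp_start)
  expect_equal(s2$calls$comp_end, s1$calls$comp_end)
  expect_equal(s2$calls$flank_A, s1$calls$flank_B)   # labels exchanged
  expect_equal(s2$reads$n_A, s1$reads$n_B)
  expect_equal(s2$reads$recombinant, s1$reads$recombinant)
})

test_that("read input order does not change the output", {
  cfg <- sim_config(genome_length = 3e5, seed = 29)
  sim <- simulate_genome(cfg)
  haps <- sim_truth_haplotypes(sim)
  pool <- simulate_reads(sim, depth = 6, seed = 30)
  set.seed(31)
  perm <- sample.int(nrow(pool$aln))
  s1 <- detect_crossovers(pool$aln, haps)
  s2 <- detect_crossovers(pool$aln[perm, ], haps)
  expect_equal(s2$calls, s1$calls)
})

test_that("reads on contigs without haplotype sites are skipped with a warning", {
  h <- toy_haps(c(10L, 20L), c("A", "C"), c("G", "T"))
  aln <- data.frame(read_id = "r1", flag = 0L, chrom = "chrZ", pos = 0L,
                    mapq = 60L, cigar = "5M", seq = "ACGTA",
                    stringsAsFactors = FALSE)
  expect_warning(scan <- detect_crossovers(aln, h), "chrZ")
  expect_equal(nrow(scan$calls), 0L)
})

test_that("phase sets are never mixed within a window", {
  # 14 sites, one read matching hapA on the first block and hapB on the
  # second; in a single block this is a crossover, in two blocks neither
  # block alone switches
  pos <- seq(0L, 130L, 10L)
  a <- rep("A", 14); b <- rep("C", 14)
  seqr <- paste(ifelse(seq_len(140) %in% (pos[1:7] + 1), "A",
                       ifelse(seq_len(140) %in% (pos[8:14] + 1), "C", "G")),
                collapse = "")
  aln <- data.frame(read_id = "r1", flag = 0L, chrom = "chr1", pos = 0L,
                    mapq = 60L, cigar = "140M", seq = seqr,
                    stringsAsFactors = FALSE)
  one_block <- haplotype_table(rep("chr1", 14), pos, a, b)
  two_blocks <- haplotype_table(rep("chr1", 14), pos, a, b,
                                phase_set = rep(c("p1", "p2"), each = 7))
  expect_equal(nrow(detect_crossovers(aln, one_block)$calls), 1L)
  expect_equal(nrow(detect_crossovers(aln, two_blocks)$calls), 0L)
})
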