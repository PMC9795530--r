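# The gamete-pool simulator and the validation harness.

test_that("sim_config validates its rates and sizes", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(recomb_fraction = 1.2), "rates")
  expect_error(sim_config(snv_spacing = -1), "positive")
  expect_error(sim_config(snv_spacing = 2e6, genome_length = 1e6), "smaller")
  expect_error(sim_config(mean_run_length = 0.5), "mean_run_length")
})

test_that("simulated SNV counts follow the configured density", {
  cfg <- sim_config(genome_length = 1e6, snv_spacing = 100, seed = 60)
  sim <- simulate_genome(cfg)
  lam <- sim$chroms$chr1$orig_length / 100
  expect_lt(abs(nrow(sim$sites) - lam), 3 * sqrt(lam))   # Poisson 3 sigma
  # spacing is near-exponential: mean original gap close to 100
  gaps <- diff(sim$sites$pos) * cfg$mean_run_length
  expect_lt(abs(mean(gaps) - 100), 10)
})

test_that("the simulated genome is internally consistent", {
  cfg <- sim_config(genome_length = 3e5, seed = 61)
  sim <- simulate_genome(cfg)
  g <- sim$chroms$chr1
  # compressed reference has no adjacent duplicates
  ch <- strsplit(g$comp_ref, "")[[1]]
  expect_false(any(ch[-1] == ch[-length(ch)]))
  # haplotypes differ exactly at the heterozygous sites
  ha <- strsplit(g$hap_a_seq, "")[[1]]
  hb <- strsplit(g$hap_b_seq, "")[[1]]
  expect_equal(which(ha != hb) - 1L, sim$sites$pos)
  expect_equal(ha[sim$sites$pos + 1L], sim$sites$hap_a)
  # compression of both haplotypes is structure-preserving
  expect_equal(compress_sequence(g$hap_a_seq)$seq, g$hap_a_seq)
  expect_equal(compress_sequence(g$hap_b_seq)$seq, g$hap_b_seq)
  # position map covers the original length
  expect_equal(sum(g$run_lengths), g$orig_length)
  # every true VCF record is a phased heterozygous SNV
  v <- sim$vcf[sim$vcf$type == "true", ]
  expect_true(all(v$gt %in% c("0|1", "1|0")))
  expect_true(all(nchar(v$ref) == 1L & nchar(v$alt) == 1L & v$ref != v$alt))
})

test_that("simulation is deterministic under a fixed seed", {
  cfg <- sim_config(genome_length = 2e5, seed = 62)
  s1 <- simulate_genome(cfg)
  s2 <- simulate_genome(cfg)
  expect_identical(s1, s2)
  p1 <- simulate_reads(s1, depth = 5, seed = 63)
  p2 <- simulate_reads(s2, depth = 5, seed = 63)
  expect_identical(p1, p2)
  p3 <- simulate_reads(s1, depth = 5, seed = 64)
  expect_false(identical(p1$aln$seq, p3$aln$seq))
})

test_that("error-free reads substring-match their source haplotype", {
  cfg <- sim_config(genome_length = 2e5, seed = 65, recomb_fraction = 0)
  sim <- simulate_genome(cfg)
  pool <- simulate_reads(sim, depth = 4, seed = 66, error_free = TRUE)
  expect_equal(sum(!is.na(pool$truth$bp_comp)), 0L)   # no breakpoints recorded
  g <- sim$chroms$chr1
  for (i in seq_len(nrow(pool$truth))) {
    tr <- pool$truth[i, ]
    src <- if (tr$source_first == "A") g$hap_a_seq else g$hap_b_seq
    expect_equal(pool$aln$seq[pool$aln$read_id == tr$read_id],
                 substr(src, tr$start + 1L, tr$start + tr$length))
  }
})

test_that("recombinant reads switch haplotype exactly at the truth breakpoint", {
  cfg <- sim_config(genome_length = 2e5, seed = 67, recomb_fraction = 1)
  sim <- simulate_genome(cfg)
  pool <- simulate_reads(sim, depth = 2, seed = 68, error_free = TRUE)
  g <- sim$chroms$chr1
  for (i in seq_len(nrow(pool$truth))) {
    tr <- pool$truth[i, ]
    first <- if (tr$source_first == "A") g$hap_a_seq else g$hap_b_seq
    second <- if (tr$source_first == "A") g$hap_b_seq else g$hap_a_seq
    want <- paste0(substr(first, tr$start + 1L, tr$bp_comp),
                   substr(second, tr$bp_comp + 1L, tr$start + tr$length))
    expect_equal(pool$aln$seq[pool$aln$read_id == tr$read_id], want)
  }
})

test_that("empirical error rates match the configured rates within 2 sigma", {
  # isolate each error channel (multiplier 1 so the nominal rate applies
  # genome-wide); compare counts from the emitted CIGAR/sequences
  base_cfg <- function(...) sim_config(genome_length = 1e6, seed = 70,
                                       hp_indel_mult = 1, recomb_fraction = 0,
                                       read_length_mean = 5000,
                                       read_length_sd = 500, ...)
  check <- function(cfg, count_fun, p) {
    sim <- simulate_genome(cfg)
    pool <- simulate_reads(sim, depth = 5, seed = 71)   # ~ 1000 reads
    n_bases <- sum(pool$truth$length)
    got <- count_fun(pool, sim)
    expect_lt(abs(got - p * n_bases), 2 * sqrt(p * (1 - p) * n_bases) + 3)
  }
  # deletions: reference width shortfall relative to template length
  check(base_cfg(p_sub = 0, p_ins = 0, p_del = 0.03), function(pool, sim) {
    sum(vapply(regmatches(pool$aln$cigar,
                          gregexpr("\\d+(?=D)", pool$aln$cigar, perl = TRUE)),
               function(x) sum(as.integer(x)), 0))
  }, 0.03)
  # insertions
  check(base_cfg(p_sub = 0, p_ins = 0.02, p_del = 0), function(pool, sim) {
    sum(vapply(regmatches(pool$aln$cigar,
                          gregexpr("\\d+(?=I)", pool$aln$cigar, perl = TRUE)),
               function(x) sum(as.integer(x)), 0))
  }, 0.02)
  # substitutions: direct comparison against the source haplotype
  check(base_cfg(p_sub = 0.02, p_ins = 0, p_del = 0), function(pool, sim) {
    g <- sim$chroms$chr1
    tot <- 0
    for (i in seq_len(nrow(pool$truth))) {
      tr <- pool$truth[i, ]
      src <- if (tr$source_first == "A") g$hap_a_seq else g$hap_b_seq
      a <- charToRaw(pool$aln$seq[pool$aln$read_id == tr$read_id])
      b <- charToRaw(substr(src, tr$start + 1L, tr$start + tr$length))
      tot <- tot + sum(a != b)
    }
    tot
  }, 0.02)
})

test_that("indel errors are elevated inside homopolymer-derived positions", {
  cfg <- sim_config(genome_length = 1e6, seed = 72, p_sub = 0, p_ins = 0,
                    p_del = 0.02, hp_indel_mult = 3, recomb_fraction = 0)
  sim <- simulate_genome(cfg)
  pool <- simulate_reads(sim, depth = 4, seed = 73)
  g <- sim$chroms$chr1
  # classify every deleted reference position via the CIGAR
  del_hp <- 0; del_nohp <- 0; cov_hp <- 0; cov_nohp <- 0
  for (i in seq_len(nrow(pool$aln))) {
    ops <- regmatches(pool$aln$cigar[i],
                      gregexpr("\\d+[MID]", pool$aln$cigar[i]))[[1]]
    len <- as.integer(sub("[MID]", "", ops)); op <- sub("\\d+", "", ops)
    ref <- pool$aln$pos[i]
    for (k in seq_along(op)) {
      if (op[k] == "D") {
        hp <- g$hp_flag[(ref + 1L):(ref + len[k])]
        del_hp <- del_hp + sum(hp); del_nohp <- del_nohp + sum(!hp)
      }
      if (op[k] %in% c("M", "D")) ref <- ref + len[k]
    }
    span <- g$hp_flag[(pool$aln$pos[i] + 1L):ref]
    cov_hp <- cov_hp + sum(span); cov_nohp <- cov_nohp + sum(!span)
  }
  ratio <- (del_hp / cov_hp) / (del_nohp / cov_nohp)
  expect_gt(ratio, 2)     # configured multiplier 3, allow sampling noise
  expect_lt(ratio, 4.5)
})

test_that("evaluate_calls computes sensitivity and error rate", {
  truth <- data.frame(read_id = sprintf("r%02d", 1:10),
                      recombinant = c(rep(TRUE, 3), rep(FALSE, 7)),
                      bp_comp = c(100L, 200L, 300L, rep(NA, 7)),
                      stringsAsFactors = FALSE)
  perfect <- evaluate_calls(sprintf("r%02d", 1:3), truth)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$error_rate, 0)

  all_called <- evaluate_calls(sprintf("r%02d", 1:10), truth)
  expect_equal(all_called$accuracy, 1)
  expect_equal(all_called$error_rate, 1)

  # 2 TP, 1 FN, 1 FP
  mixed <- evaluate_calls(c("r01", "r02", "r04"), truth)
  expect_equal(mixed$accuracy, 2 / 3)
  expect_equal(mixed$error_rate, 1 / 7)
  expect_equal(c(mixed$tp, mixed$fn, mixed$fp, mixed$tn), c(2L, 1L, 1L, 6L))

  expect_error(evaluate_calls("r99", truth), "absent")
})

test_that("breakpoint localisation error is zero when intervals contain the truth", {
  truth <- data.frame(read_id = c("a", "b"), recombinant = TRUE,
                      bp_comp = c(150L, 400L), stringsAsFactors = FALSE)
  calls <- data.frame(read_id = c("a", "b"),
                      comp_start = c(140L, 500L), comp_end = c(160L, 520L),
                      stringsAsFactors = FALSE)
  ev <- evaluate_calls(calls, truth)
  # read a: contained -> 0; read b: interval starts 100 bases past the truth
  expect_equal(ev$mean_breakpoint_error, mean(c(0, 500 - 400)))
})

test_that("a small validation grid is reproducible and well-formed", {
  g1 <- run_grid(spacings = c(150, 300), depths = c(4, 8), reps = 1L,
                 seed = 77, genome_length = 3e5)
  g2 <- run_grid(spacings = c(150, 300), depths = c(4, 8), reps = 1L,
                 seed = 77, genome_length = 3e5)
  expect_identical(g1, g2)
  expect_equal(nrow(g1), 4L)
  expect_true(all(g1$n_recombinant + g1$n_nonrecombinant == g1$n_reads))
  s <- summarize_grid(g1)
  expect_equal(nrow(s), 4L)
  expect_true(all(s$accuracy >= 0 & s$accuracy <= 1))
  p <- withr::local_tempfile(fileext = ".png")
  plot_grid(g1, p)
  expect_true(file.exists(p))
})
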