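test_that("generate_genome is deterministic with plausible composition", {
  g1 <- generate_genome(10000, 5)
  g2 <- generate_genome(10000, 5)
  expect_identical(g1, g2)
  gc <- sum(strsplit(g1, "")[[1]] %in% c("G", "C")) / 10000
  expect_gt(gc, 0.45)   # binomial 99.99% band at n = 10000
  expect_lt(gc, 0.55)
  g3 <- generate_genome(10000, 6)
  mism <- mean(strsplit(g1, "")[[1]] != strsplit(g3, "")[[1]])
  expect_gt(mism, 0.70)   # expected 0.75 for independent uniform draws
  # repeat insertion copies a segment
  gr <- generate_genome(20000, 5, repeat_segment = TRUE)
  seg <- substr(generate_genome(20000, 5), 5000, 6999)
  expect_gte(length(gregexpr(substr(seg, 1, 100), gr, fixed = TRUE)[[1]]), 1L)
})

test_that("plant_variants matches configured rates and constraints", {
  g <- generate_genome(1e6, 2)
  cfg <- sim_config(genome_len = 1e6, seed = 2, sv_events = NULL)
  tr <- plant_variants(g, cfg)$truth
  n <- nrow(tr)
  expect_gt(n, qpois(0.005, 100))   # Poisson 99% band around rate*len = 100
  expect_lt(n, qpois(0.995, 100))
  expect_true(all(tr$vaf %in% seq(0.1, 0.5, by = 0.1)))
  expect_true(all(diff(sort(tr$pos0)) >= 150))   # no overlapping events

  # indel_fraction 0: SNVs (and configured SVs) only
  cfg0 <- sim_config(genome_len = 2e5, seed = 3, indel_fraction = 0,
                     sv_events = default_sv_events(2))
  tr0 <- plant_variants(generate_genome(2e5, 3), cfg0)$truth
  expect_false(any(tr0$type %in% c("ins", "del")))
  expect_equal(sum(tr0$type == "sv"), 2L)
  expect_true(all(tr0$length[tr0$type == "sv"] > 50))

  # single VAF choice propagates to every record
  cfg5 <- sim_config(genome_len = 1e5, seed = 4, vaf_choices = 0.5,
                     sv_events = NULL)
  tr5 <- plant_variants(generate_genome(1e5, 4), cfg5)$truth
  expect_true(all(tr5$vaf == 0.5))
})

test_that("simulate_reads honours count arithmetic and the error model", {
  g <- generate_genome(10000, 9)
  cfg <- sim_config(genome_len = 10000, seed = 9, coverage = 50,
                    read_len = 100L, error_rate = 0, sv_events = NULL)
  rd <- simulate_reads(g, list(), cfg)
  expect_equal(length(rd$r1), 2500L)   # 10000*50/(100*2)
  expect_equal(length(rd$r2), 2500L)
  # error-free reads are perfect substrings of the genome (either strand)
  idx <- sample(2500, 40)
  hit <- vapply(idx, function(i)
    grepl(rd$r1$seq[i], g, fixed = TRUE) ||
      grepl(revcomp_dna(rd$r1$seq[i]), g, fixed = TRUE), logical(1))
  expect_true(all(hit))
  # determinism under the seed
  rd2 <- simulate_reads(g, list(), cfg)
  expect_identical(rd$r1$seq, rd2$r1$seq)

  # mean depth within 10% of target at 50x on 100 kb
  g2 <- generate_genome(1e5, 10)
  cfg2 <- sim_config(genome_len = 1e5, seed = 10, coverage = 50,
                     sv_events = NULL)
  rd2 <- simulate_reads(g2, list(), cfg2)
  depth <- (length(rd2$r1) + length(rd2$r2)) * 100 / 1e5
  expect_lt(abs(depth - 50) / 50, 0.10)

  # error quality model: errors are Q10, everything else Q30
  cfge <- sim_config(genome_len = 10000, seed = 9, coverage = 10,
                     error_rate = 0.01, sv_events = NULL)
  rde <- simulate_reads(g, list(), cfge)
  q <- unique(unlist(strsplit(rde$r1$qual[1:50], "")))
  expect_true(all(q %in% c("?", "+")))
})

test_that("VAF realisation approximates the configured mixing fraction", {
  g <- generate_genome(50000, 12)
  cfg <- sim_config(genome_len = 50000, seed = 12, coverage = 60,
                    snv_rate = 1e-4, indel_fraction = 0, vaf_choices = 0.4,
                    error_rate = 0, sv_events = NULL)
  pv <- plant_variants(g, cfg)
  rd <- simulate_reads(g, pv$regions, cfg)
  reads <- c(rd$r1$seq, rd$r2$seq)
  # measure allele fraction at each planted SNV via 21-mer counts
  tab <- count_kmers(reads, 21L)
  fr <- vapply(seq_len(nrow(pv$truth)), function(i) {
    p <- pv$truth$pos0[i]
    wild_w <- substr(g, p - 9, p + 11)   # 0-based [p-10, p+10]
    mut_w <- wild_w
    substr(mut_w, 11, 11) <- pv$truth$alt_allele[i]   # 0-based p
    m <- kmervar:::lookup_counts(tab, mut_w)
    w <- kmervar:::lookup_counts(tab, wild_w)
    m / (m + w)
  }, numeric(1))
  expect_gt(mean(fr), 0.3)
  expect_lt(mean(fr), 0.5)
})

test_that("evaluate_calls reproduces published metric arithmetic", {
  m <- confusion_metrics(581, 45, 241)
  expect_equal(round(m$recall, 2), 0.71)
  expect_equal(round(m$FDR, 2), 0.07)
  expect_equal(round(m$precision, 2), 0.93)
  expect_equal(round(m$F1, 2), 0.80)

  # exact agreement between calls and truth
  truth <- data.frame(pos0 = c(99L, 199L), pos0_alt = NA_integer_,
                      type = c("snv", "del"), svtype = NA,
                      ref_allele = "A", alt_allele = "T",
                      length = c(1L, 2L), vaf = 0.5)
  calls <- data.frame(var_type = c("mutation", "indel"),
                      pos = c(100L, 200L), pos2 = NA_integer_,
                      phred = c(30, 20), unmapped = FALSE)
  ev <- evaluate_calls(calls, truth)
  expect_equal(ev$overall$recall, 1)
  expect_equal(ev$overall$FDR, 0)
  expect_equal(ev$overall$F1, 1)

  # SNV matching is exact: 1 bp off is a miss
  off <- calls
  off$pos[1] <- 101L
  ev_off <- evaluate_calls(off, truth)
  expect_equal(ev_off$snv$TP, 0L)
  # indels tolerate up to 10 bp
  off$pos[2] <- 209L
  expect_equal(evaluate_calls(off, truth)$indel$TP, 1L)
  off$pos[2] <- 215L
  expect_equal(evaluate_calls(off, truth)$indel$TP, 0L)

  # category mismatch never matches
  cross <- data.frame(var_type = "indel", pos = 100L, pos2 = NA_integer_,
                      phred = 10, unmapped = FALSE)
  expect_equal(evaluate_calls(cross, truth)$snv$TP, 0L)

  # degenerate case: no calls at all
  none <- evaluate_calls(data.frame(var_type = character(0),
                                    pos = integer(0)), truth)
  expect_equal(none$overall$recall, 0)
  expect_true(none$overall$degenerate)

  # each truth record matches at most one call
  dup <- data.frame(var_type = "mutation", pos = c(100L, 100L),
                    pos2 = NA_integer_, phred = c(30, 10), unmapped = FALSE)
  ev_dup <- evaluate_calls(dup, truth)
  expect_equal(ev_dup$snv$TP, 1L)
  expect_equal(ev_dup$snv$FP, 1L)
})

test_that("simulator files round-trip: truth VCF and FASTQ outputs", {
  out <- withr::local_tempdir()
  cfg <- sim_config(genome_len = 20000, seed = 14, coverage = 10,
                    sv_events = default_sv_events(2))
  sim <- simulate_dataset(cfg, outdir = out)
  expect_true(all(file.exists(unlist(sim$paths))))
  tr <- read_truth_vcf(sim$paths$truth)
  expect_equal(nrow(tr), nrow(sim$truth))
  expect_equal(tr$pos0, sim$truth$pos0)
  expect_equal(tr$type, sim$truth$type)
  expect_equal(tr$vaf, sim$truth$vaf)
  r1 <- read_fastq(sim$paths$case[1])
  expect_equal(length(r1), length(sim$case$r1))
})
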