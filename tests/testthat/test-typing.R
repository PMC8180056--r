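test_that("align_contig_pair edit structure on elementary cases", {
  a <- align_contig_pair("ACGTA", "ACCTA")
  expect_equal(a$pattern, "ACGTA")
  expect_equal(a$subject, "ACCTA")   # one mismatch, no gaps
  d <- align_contig_pair("ACGTA", "ACGA")
  expect_equal(nchar(d$pattern), 5L)
  expect_equal(sum(strsplit(d$subject, "")[[1]] == "-"), 1L)
})

test_that("alignment score equals the exhaustive DP oracle on short strings", {
  set.seed(29)
  for (rep in 1:60) {
    a <- rnd_dna(sample(3:12, 1))
    b <- rnd_dna(sample(3:12, 1))
    expect_equal(align_contig_pair(a, b)$score, oracle_align_score(a, b),
                 tolerance = 1e-9, label = paste(a, b))
  }
})

test_that("classification of elementary variants", {
  set.seed(83)
  wild <- rnd_dna(90)
  # single substitution
  mut <- wild
  substr(mut, 45, 45) <- setdiff(BASES, substr(wild, 45, 45))[1]
  cl <- classify_variant(mut, wild)
  expect_equal(cl$var_type, "mutation")
  expect_equal(cl$pos_in_contig, 44L)  # 0-based
  expect_equal(cl$alt_allele, substr(mut, 45, 45))
  expect_equal(cl$ref_allele, substr(wild, 45, 45))

  # 3-base deletion in the mutant
  mut3 <- paste0(substr(wild, 1, 44), substr(wild, 48, 90))
  cl3 <- classify_variant(mut3, wild)
  expect_equal(cl3$var_type, "indel")
  expect_equal(nchar(cl3$ref_allele) - nchar(cl3$alt_allele), 3L)

  # 60-base deletion -> sv
  wild150 <- paste0(wild, rnd_dna(60))
  mut_sv <- paste0(substr(wild150, 1, 45), substr(wild150, 106, 150))
  cl60 <- classify_variant(mut_sv, wild150)
  expect_equal(cl60$var_type, "sv")

  # two substitutions, no gaps
  mm <- mut
  substr(mm, 60, 60) <- setdiff(BASES, substr(wild, 60, 60))[1]
  expect_equal(classify_variant(mm, wild)$var_type, "multiple_mutation")

  # no reference assembled
  none <- classify_variant(mut, NA_character_)
  expect_equal(none$var_type, "sv")
  expect_equal(none$alt_allele, "<SV>")
})

test_that("classification is invariant under reverse complement", {
  set.seed(37)
  for (rep in 1:15) {
    wild <- rnd_dna(80)
    kind <- rep %% 3
    mut <- wild
    if (kind == 0) {
      substr(mut, 40, 40) <- setdiff(BASES, substr(wild, 40, 40))[1]
    } else if (kind == 1) {
      mut <- paste0(substr(wild, 1, 39), substr(wild, 44, 80))      # 4bp del
    } else {
      mut <- paste0(substr(wild, 1, 40), rnd_dna(5), substr(wild, 41, 80))
    }
    fwd <- classify_variant(mut, wild)
    rcv <- classify_variant(revcomp_dna(mut), revcomp_dna(wild))
    expect_equal(fwd$var_type, rcv$var_type, label = paste("rep", rep))
  }
})

test_that("junction contigs are typed sv, not indel, against one flank", {
  set.seed(91)
  genome <- rnd_dna(2000)
  # 300 bp deletion junction: 30 bases either side of the breakpoints
  jc <- paste0(substr(genome, 971, 1000), substr(genome, 1301, 1330))
  flank_ref <- substr(genome, 880, 1090)   # covers the left flank only
  expect_equal(classify_variant(jc, flank_ref)$var_type, "sv")
  # with a reference spanning the whole deletion: one >= 50 gap run
  span_ref <- substr(genome, 880, 1420)
  expect_equal(classify_variant(jc, span_ref)$var_type, "sv")
})

test_that("VCF export round-trips calls and validates structurally", {
  set.seed(59)
  cfg <- sim_config(genome_len = 20000, seed = 8, coverage = 40,
                    vaf_choices = 0.5, sv_events = default_sv_events(2))
  sim <- simulate_dataset(cfg)
  res <- run_call(list(r1 = sim$case$r1, r2 = sim$case$r2),
                  list(r1 = sim$control$r1, r2 = sim$control$r2),
                  genome = sim$genome)
  expect_gt(nrow(res$passing), 0)
  fp <- file.path(withr::local_tempdir(), "calls.vcf")
  write_vcf(res$passing, fp)
  # independent parser sees the same records
  vcf <- VariantAnnotation::readVcf(fp)
  expect_equal(nrow(vcf), nrow(res$passing))
  info <- VariantAnnotation::info(vcf)
  ord <- order(res$passing$chrom, res$passing$pos)
  p <- res$passing[ord, ]
  expect_equal(as.integer(info$CSCOUNT), p$cs_count)
  expect_equal(as.integer(info$COV), p$coverage)
  expect_equal(as.character(info$VTYPE), p$var_type)
  expect_equal(as.numeric(info$AF), p$af, tolerance = 1e-3)
  expect_equal(as.character(info$MUTCONTIG), p$mutant_seq)
  expect_equal(BiocGenerics::start(vcf), p$pos)
  # REF/ALT alleles survive for point calls
  pt <- which(p$var_type == "mutation")
  if (length(pt)) {
    ref <- as.character(VariantAnnotation::ref(vcf))
    expect_equal(ref[pt], p$ref_allele[pt])
  }
  # our light reader agrees too
  back <- read_vcf_calls(fp)
  expect_equal(back$pos, p$pos)
  expect_equal(back$VTYPE, p$var_type)
})

test_that("records are sorted by CHROM then POS", {
  calls <- data.frame(
    contig_id = c("c2", "c1"), mutant_seq = c("ACGT", "ACGT"),
    ref_seq = c("ACCT", "ACCT"), ref_used = c("ACCT", "ACCT"),
    var_type = "mutation", pos_in_contig = 2L, pos_in_ref = 2L,
    ref_allele = "C", alt_allele = "G", branch = "ct_merge",
    cs_count = 5L, coverage = 10L, control_cs_count = 0L,
    control_coverage = 12L, n_support_reads = NA_integer_, af = 0.5,
    p_value = 0.01, phred = 20, matched_fraction = 1,
    chrom = "chr1", pos = c(500L, 100L), pos2 = NA_integer_,
    unmapped = FALSE, stringsAsFactors = FALSE)
  fp <- file.path(withr::local_tempdir(), "two.vcf")
  write_vcf(calls, fp)
  got <- read_vcf_calls(fp)
  expect_equal(got$pos, c(100L, 500L))
})
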