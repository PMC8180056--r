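# build a matched-branch scenario: wild sequence, one substitution, full
# k-mer support in a fake control table
snv_scenario <- function(seed, k = 31L) {
  set.seed(seed)
  wild <- rnd_dna(120)
  p <- sample(seq(2 * k, 120 - 2 * k), 1)
  mut <- wild
  substr(mut, p, p) <- sample(setdiff(BASES, substr(wild, p, p)), 1)
  case_reads <- vapply(0:(120 - 100), function(i) substr(mut, i + 1, i + 100),
                       character(1))
  ctrl_reads <- vapply(0:(120 - 100), function(i) substr(wild, i + 1, i + 100),
                       character(1))
  case_raw <- count_kmers(rep(c(case_reads, ctrl_reads), 5), k)  # VAF 0.5
  ctrl_raw <- count_kmers(rep(ctrl_reads, 10), k)
  cs <- extract_cs_kmers(filter_low_count(case_raw, 3L),
                         filter_low_count(ctrl_raw, 3L), ctrl_raw)
  pairs <- match_counterparts(cs, ctrl_raw)
  contigs <- assemble_contigs(cs, 25L, pairs)
  list(wild = wild, mut = mut, p = p, cs = cs, pairs = pairs,
       contigs = contigs, case_raw = case_raw, ctrl_raw = ctrl_raw,
       ctrl_reads = ctrl_reads)
}

test_that("ct-merge reverts exactly the substituted base", {
  for (seed in c(1, 2, 3)) {
    sc <- snv_scenario(seed)
    expect_equal(length(sc$contigs), 1L)
    ctg <- sc$contigs[[1]]
    expect_gt(ctg$matched_fraction, 0.5)
    ref <- infer_reference_matched(ctg, sc$pairs)
    want <- substr(sc$wild, sc$p - 30, sc$p + 30)
    expect_true(ref %in% c(want, revcomp_dna(want)))
    expect_true(ctg$seq %in% c(substr(sc$mut, sc$p - 30, sc$p + 30),
                               revcomp_dna(substr(sc$mut, sc$p - 30,
                                                  sc$p + 30))))
  }
})

test_that("branch routing is strict at matched_fraction 0.5", {
  sc <- snv_scenario(4)
  ctg <- sc$contigs[[1]]
  ctg$matched_fraction <- 0.5
  expect_error(infer_reference_matched(ctg, sc$pairs), "matched_fraction")
  ctg$matched_fraction <- 0.4
  expect_error(infer_reference_matched(ctg, sc$pairs), "matched_fraction")
})

test_that("k-mer statistics use the half-down median convention", {
  # direct examples
  ctg <- list(members = data.frame(kmer = c("AAAAACA", "AAAAACC", "AAAAACG"),
                                   offset = 0:2, strand = "+",
                                   count = c(5L, 7L, 9L)),
              matched_fraction = 1)
  # pair each member with a ct-kmer whose case counts are 10, 12, 20
  ct <- c("AAAAATA", "AAAAATC", "AAAAATG")
  pairs <- data.frame(cs_kmer = ctg$members$kmer, ct_kmer = ct, pos = 5L,
                      case_allele = "C", control_allele = "T",
                      ct_count = c(10L, 12L, 20L))
  case_raw <- kmer_table(7, canonicalize(c(ctg$members$kmer, ct)),
                         c(5L, 7L, 9L, 10L, 12L, 20L))
  ctrl_raw <- kmer_table(7, canonicalize(ct), c(10L, 12L, 20L))
  st <- compute_kmer_stats(ctg, pairs, case_raw, ctrl_raw)
  expect_equal(st$cs_count_case, 7L)        # median(5,7,9)
  expect_equal(st$coverage_case, 7L + 12L)  # + median ct count in case
  expect_equal(st$cs_count_control, 0L)
  expect_equal(st$coverage_control, 12L)

  # median convention against the sort-based oracle, incl. half-down
  set.seed(9)
  for (rep in 1:40) {
    x <- sample(0:30, sample(1:8, 1), replace = TRUE)
    expect_identical(kmervar:::.median_hd(x), oracle_median_hd(x))
  }
  expect_identical(kmervar:::.median_hd(c(4L, 6L)), 5L)
  expect_identical(kmervar:::.median_hd(c(4L, 5L)), 4L)  # 4.5 rounds down
  expect_identical(kmervar:::.median_hd(7L), 7L)
})

test_that("retrieve_control_reads implements the 1-mismatch screen", {
  set.seed(31)
  k <- 31L
  member <- rnd_dna(k)
  ctg <- list(members = data.frame(kmer = member, offset = 0L, strand = "+",
                                   count = 5L))
  exact <- paste0(rnd_dna(20), member, rnd_dna(20))
  one_mm <- exact
  substr(one_mm, 35, 35) <- setdiff(BASES, substr(exact, 35, 35))[1]
  # reverse complement containing read must also be retrieved
  rc_read <- revcomp_dna(exact)
  # >= 2 mismatches in every window
  two_mm <- exact
  substr(two_mm, 25, 25) <- setdiff(BASES, substr(exact, 25, 25))[1]
  substr(two_mm, 45, 45) <- setdiff(BASES, substr(exact, 45, 45))[1]
  unrelated <- rnd_dna(70)
  reads <- mk_reads(c(exact, one_mm, rc_read, two_mm, unrelated))
  got <- retrieve_control_reads(ctg, reads, k)
  expect_setequal(got$seq, c(exact, one_mm, rc_read))
})

test_that("greedy read assembly matches the naive mirror and ground truth", {
  set.seed(61)
  for (rep in 1:15) {
    src <- rnd_dna(300)
    offs <- seq(1, 201, by = sample(15:25, 1))
    reads <- vapply(offs, function(o) substr(src, o, o + 99), character(1))
    flip <- runif(length(reads)) < 0.4
    reads[flip] <- revcomp_dna(reads[flip])
    perm <- sample(length(reads))
    got <- assemble_control_reads(mk_reads(reads[perm]), 30L)
    expect_equal(got$n_support_reads, length(reads))
    want <- substr(src, 1, max(offs) + 99)
    expect_true(got$ref_seq %in% c(want, revcomp_dna(want)),
                label = paste("rep", rep))
    # naive mirror on <= 10 reads agrees on the assembled sequence set
    if (length(reads) <= 10) {
      orc <- oracle_assemble_reads(reads[perm], 30L)
      expect_true(got$ref_seq %in% c(orc[1], revcomp_dna(orc[1])))
    }
  }
  # zero reads -> no reference, zero support
  empty <- assemble_control_reads(mk_reads(character(0)))
  expect_true(is.na(empty$ref_seq))
  expect_equal(empty$n_support_reads, 0L)
})

test_that("infer_references routes every contig through exactly one branch", {
  sc <- snv_scenario(6)
  out <- infer_references(sc$contigs, sc$pairs, sc$case_raw, sc$ctrl_raw,
                          mk_reads(rep(sc$ctrl_reads, 3)))
  for (ctg in out) {
    expect_true(ctg$branch %in% c("ct_merge", "read_assembly"))
    expect_gte(ctg$coverage_case, ctg$cs_count_case)
    expect_gte(ctg$coverage_control, ctg$cs_count_control)
    expect_true(all(c(ctg$cs_count_case, ctg$coverage_case,
                      ctg$cs_count_control, ctg$coverage_control) >= 0))
  }
  # unmatched contig (no pairs) goes through read assembly
  cs_un <- cs_kmer_set(31, canonicalize(rnd_dna(31)), 5L, 0L)
  ctg_un <- assemble_contigs(cs_un, 25L,
                             pairs = data.frame(cs_kmer = character(0),
                                                ct_kmer = character(0),
                                                pos = integer(0),
                                                case_allele = character(0),
                                                control_allele = character(0),
                                                ct_count = integer(0)))
  out_un <- infer_references(ctg_un,
                             data.frame(cs_kmer = character(0),
                                        ct_kmer = character(0), pos = integer(0),
                                        case_allele = character(0),
                                        control_allele = character(0),
                                        ct_count = integer(0)),
                             sc$case_raw, sc$ctrl_raw, mk_reads(character(0)))
  expect_equal(out_un[[1]]$branch, "read_assembly")
  expect_true(is.na(out_un[[1]]$ref_seq))   # zero reads: candidate SV
  expect_equal(out_un[[1]]$n_support_reads, 0L)
})
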