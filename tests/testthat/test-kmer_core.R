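test_that("canonicalize returns the lexicographic minimum of both strands", {
  expect_identical(canonicalize("TTTTT"), "AAAAA")
  expect_identical(canonicalize("AAAAA"), "AAAAA")
  expect_error(canonicalize("ACGTN"), "non-ACGT")
  set.seed(3)
  x <- replicate(200, rnd_dna(sample(c(7, 31), 1)))
  expect_identical(canonicalize(x), canonicalize(revcomp_dna(x)))
  expect_identical(canonicalize(x), oracle_canonical(x))
  expect_identical(revcomp_dna(x), oracle_revcomp(x))
})

test_that("count_kmers equals the brute-force window oracle", {
  set.seed(19)
  for (k in c(5L, 31L)) {
    # random reads incl. Ns so masked windows are exercised
    seqs <- replicate(60, {
      s <- rnd_dna(sample(k:(3 * k), 1))
      if (runif(1) < 0.5) {
        p <- sample(nchar(s), 1)
        substr(s, p, p) <- "N"
      }
      s
    })
    tab <- count_kmers(seqs, k)
    orc <- oracle_count_kmers(seqs, k)
    got <- data.frame(kmer = tab$kmer, count = tab$count)
    got <- got[order(got$kmer), ]
    orc <- orc[order(orc$kmer), ]
    expect_equal(got$kmer, orc$kmer)
    expect_equal(got$count, orc$count)
  }
  # single read of length k
  one <- count_kmers("ACGTACG", 7L)
  expect_equal(length(one), 1L)
  expect_equal(one$count, 1L)
  # k larger than every read
  expect_equal(length(count_kmers(c("ACGT", "AC"), 7L)), 0L)
  # windows overlapping an N are absent: only the two flanking clean
  # windows survive (both are the same canonical 5-mer)
  noN <- count_kmers("ACGTTNACGTT", 5L)
  expect_equal(length(noN), 1L)
  expect_equal(noN$count, 2L)
})

test_that("filter_low_count keeps counts >= min_count exactly", {
  tab <- kmer_table(5, canonicalize(c("AAAAA", "CCCCC")), c(2L, 3L))
  f <- filter_low_count(tab, 3L)
  expect_equal(f$kmer, canonicalize("CCCCC"))
  expect_identical(filter_low_count(tab, 1L)$count, tab$count)
  expect_equal(length(filter_low_count(kmer_table(5), 3L)), 0L)
})

test_that("extract_cs_kmers applies the control-count guard", {
  X <- canonicalize("ACGTACG")
  case <- kmer_table(7, X, 5L)
  # shared k-mer excluded
  expect_equal(length(extract_cs_kmers(case, kmer_table(7, X, 5L),
                                       kmer_table(7, X, 5L))), 0L)
  # absent from control entirely
  cs <- extract_cs_kmers(case, kmer_table(7), kmer_table(7))
  expect_equal(cs$kmer, X)
  expect_equal(cs$control_raw, 0L)
  # raw control count 2 (below the filter) is tolerated at the default guard
  cs2 <- extract_cs_kmers(case, kmer_table(7), kmer_table(7, X, 2L),
                          max_control_count = 2L)
  expect_equal(cs2$kmer, X)
  expect_equal(cs2$control_raw, 2L)
  # ... but not with a stricter guard
  cs3 <- extract_cs_kmers(case, kmer_table(7), kmer_table(7, X, 2L),
                          max_control_count = 1L)
  expect_equal(length(cs3), 0L)
  # mismatched k errors
  expect_error(extract_cs_kmers(case, kmer_table(5), kmer_table(7)), "same k")
})

test_that("cs extraction is monotone in its thresholds", {
  set.seed(23)
  reads_case <- replicate(80, rnd_dna(40))
  reads_ctrl <- c(reads_case[1:40], replicate(40, rnd_dna(40)))
  k <- 7L
  case_raw <- count_kmers(reads_case, k)
  ctrl_raw <- count_kmers(reads_ctrl, k)
  sizes <- integer(0)
  for (mc in 1:4) {
    cs <- extract_cs_kmers(filter_low_count(case_raw, mc),
                           filter_low_count(ctrl_raw, mc), ctrl_raw,
                           max_control_count = mc - 1L)
    sizes <- c(sizes, length(cs))
    # case-specificity invariant
    expect_false(any(cs$kmer %in% filter_low_count(ctrl_raw, mc)$kmer))
  }
  expect_true(all(diff(sizes) <= 0))  # raising min_count never adds cs-kmers
  # raising max_control_count never removes cs-kmers
  base <- extract_cs_kmers(filter_low_count(case_raw, 2L),
                           filter_low_count(ctrl_raw, 2L), ctrl_raw, 0L)
  wide <- extract_cs_kmers(filter_low_count(case_raw, 2L),
                           filter_low_count(ctrl_raw, 2L), ctrl_raw, 1L)
  expect_true(all(base$kmer %in% wide$kmer))
})

test_that("panel-of-normals exclusion drops k-mers seen in 2+ normals", {
  kms <- canonicalize(c("ACGTACG", "GGGTACG", "TTTTACG"))
  cs <- cs_kmer_set(7, kms, c(5L, 6L, 7L), c(0L, 0L, 0L))
  n1 <- kmer_table(7, canonicalize(kms[1:2]), c(1L, 1L))
  n2 <- kmer_table(7, canonicalize(kms[1]), 4L)
  out <- filter_panel_of_normals(cs, list(n1, n2), max_normals = 1L)
  expect_setequal(out$kmer, kms[2:3])   # kms[1] in two normals -> removed
  # kept in exactly one normal
  expect_true(kms[2] %in% out$kmer)
  # empty panel is the identity
  expect_identical(filter_panel_of_normals(cs, list())$kmer, cs$kmer)
})
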