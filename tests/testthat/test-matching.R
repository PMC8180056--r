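# random matching instance: some control k-mers are exact Hamming-1
# neighbours of cs-kmers (possibly reverse-complemented), the rest noise
rnd_matching_instance <- function(k, n_cs = 12, n_ctrl = 20) {
  cs <- unique(canonicalize(replicate(n_cs, rnd_dna(k))))
  ctrl <- character(0)
  for (s in sample(cs, ceiling(length(cs) / 2))) {
    p <- sample(k, 1)
    b <- sample(setdiff(BASES, substr(s, p, p)), 1)
    nb <- s
    substr(nb, p, p) <- b
    if (runif(1) < 0.5) nb <- oracle_revcomp(nb)
    ctrl <- c(ctrl, nb)
  }
  ctrl <- unique(canonicalize(c(ctrl, replicate(n_ctrl, rnd_dna(k)))))
  ctrl <- setdiff(ctrl, cs)
  list(cs = cs_kmer_set(k, cs, rep(5L, length(cs)), rep(0L, length(cs))),
       ctrl = kmer_table(k, ctrl, sample(1:30, length(ctrl), replace = TRUE)))
}

test_that("key index buckets k-mers by both end keys and orientations", {
  cs <- cs_kmer_set(7, "AAATAAA", 5L, 0L)
  ctrl <- kmer_table(7, canonicalize("AAACAAA"), 9L)
  idx <- build_key_index(cs, ctrl)
  expect_s3_class(idx, "key_index")
  expect_equal(idx$key_len, 3L)
  expect_true("AAA" %in% names(idx$buckets))
  b <- idx$buckets[["AAA"]]
  expect_true("AAATAAA" %in% b$kmer[b$origin == "case"])
  expect_true(any(b$origin == "control"))
  # a control k-mer sharing no key with any cs-kmer appears in no bucket
  far <- kmer_table(7, canonicalize("CCCCCCC"), 2L)
  idx2 <- build_key_index(cs, far)
  expect_false(any(unlist(lapply(idx2$buckets,
                                 function(d) d$origin == "control"))))
})

test_that("find_pairs reports Hamming-1 pairs with positions and alleles", {
  cs <- cs_kmer_set(7, "AAATAAA", 5L, 0L)
  ctrl <- kmer_table(7, canonicalize("AAACAAA"), 9L)
  pr <- find_pairs(build_key_index(cs, ctrl))
  expect_equal(nrow(pr), 1L)
  expect_equal(pr$pos, 3L)
  expect_equal(pr$case_allele, "T")
  expect_equal(pr$control_allele, "C")
  expect_equal(pr$ct_count, 9L)
  # Hamming distance 2: no pair
  cs2 <- cs_kmer_set(7, "AAATTAA", 5L, 0L)
  ctrl2 <- kmer_table(7, canonicalize("AAACCAA"), 9L)
  expect_equal(nrow(find_pairs(build_key_index(cs2, ctrl2))), 0L)
})

test_that("bucket search equals all-pairs brute force (R and C++ routes)", {
  set.seed(77)
  for (k in c(7L, 31L)) {
    for (rep in 1:25) {
      inst <- rnd_matching_instance(k)
      fast <- match_counterparts(inst$cs, inst$ctrl)
      slow <- find_pairs(build_key_index(inst$cs, inst$ctrl))
      orc <- oracle_find_pairs(inst$cs$kmer, inst$ctrl$kmer, inst$ctrl$count)
      rownames(fast) <- rownames(slow) <- rownames(orc) <- NULL
      expect_equal(fast, orc, label = sprintf("c++ k=%d rep=%d", k, rep))
      expect_equal(slow[order(slow$cs_kmer), ], orc,
                   label = sprintf("R k=%d rep=%d", k, rep))
      # invariant: every reported pair is at Hamming distance exactly 1
      if (nrow(fast))
        expect_true(all(mapply(oracle_hamming, fast$cs_kmer,
                               fast$ct_kmer) == 1L))
    }
  }
})

test_that("partition_cs_kmers is a partition", {
  set.seed(5)
  inst <- rnd_matching_instance(7L)
  pr <- match_counterparts(inst$cs, inst$ctrl)
  pt <- partition_cs_kmers(inst$cs, pr)
  expect_equal(length(pt$matched) + length(pt$unmatched), length(inst$cs))
  expect_length(intersect(pt$matched, pt$unmatched), 0L)
  expect_setequal(c(pt$matched, pt$unmatched), inst$cs$kmer)
  # no control table -> nothing matched
  none <- partition_cs_kmers(inst$cs,
                             match_counterparts(inst$cs, kmer_table(7)))
  expect_length(none$matched, 0L)
})
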