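# Independent reference implementations used to cross-check the package's
# primitives. These deliberately use naive enumeration / base R only.

BASES <- c("A", "C", "G", "T")

rnd_dna <- function(n, alphabet = BASES) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

oracle_revcomp <- function(x) {
  vapply(x, function(s) {
    v <- rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]])
    paste(v, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

oracle_canonical <- function(x) {
  rc <- oracle_revcomp(x)
  ifelse(rc < x, rc, x)
}

# naive window-enumeration k-mer counter
oracle_count_kmers <- function(seqs, k) {
  wins <- unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    substring(s, 1:(n - k + 1), k:n)
  }))
  wins <- wins[!grepl("[^ACGT]", wins)]
  if (!length(wins)) return(data.frame(kmer = character(0), count = integer(0)))
  tab <- table(oracle_canonical(wins))
  data.frame(kmer = names(tab), count = as.integer(tab),
             stringsAsFactors = FALSE)
}

oracle_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# all-pairs Hamming-1 (case, control) enumeration with orientation handling
# and best-counterpart selection, mirroring the matching contract
oracle_find_pairs <- function(cs, ctrl_kmer, ctrl_count) {
  rows <- list()
  for (s in cs) {
    best <- NULL
    for (j in seq_along(ctrl_kmer)) {
      for (o in unique(c(ctrl_kmer[j], oracle_revcomp(ctrl_kmer[j])))) {
        if (oracle_hamming(s, o) != 1L) next
        cand <- list(ct = o, count = ctrl_count[j])
        if (is.null(best) || cand$count > best$count ||
            (cand$count == best$count && cand$ct < best$ct)) best <- cand
      }
    }
    if (!is.null(best)) {
      d <- which(strsplit(s, "")[[1]] != strsplit(best$ct, "")[[1]])
      rows[[length(rows) + 1L]] <- data.frame(
        cs_kmer = s, ct_kmer = best$ct, pos = d - 1L,
        case_allele = substr(s, d, d),
        control_allele = substr(best$ct, d, d),
        ct_count = best$count, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(cs_kmer = character(0), ct_kmer = character(0),
                      pos = integer(0), case_allele = character(0),
                      control_allele = character(0), ct_count = integer(0)))
  out <- do.call(rbind, rows)
  out[order(out$cs_kmer), , drop = FALSE]
}

# exact hypergeometric upper tail by direct summation (log-binomials)
oracle_hyper_tail <- function(cs_case, cov_case, cs_ctrl, cov_ctrl) {
  N <- cov_case + cov_ctrl
  K <- cs_case + cs_ctrl
  if (N == 0 || K == 0) return(1)
  x <- cs_case:min(K, cov_case)
  x <- x[K - x <= cov_ctrl]
  if (!length(x)) return(0)
  min(1, sum(exp(lchoose(K, x) + lchoose(N - K, cov_case - x) -
                   lchoose(N, cov_case))))
}

# Gotoh global alignment score with first-base gap charging:
# open (-2) on the first gap base, extend (-0.5) thereafter
oracle_align_score <- function(a, b, match = 2, mismatch = -1,
                               open = -2, ext = -0.5) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av)
  m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # gap in b (pattern base consumed)
  Y <- matrix(NEG, n + 1, m + 1)  # gap in a
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- open + ext * (i - 2)
  for (j in 2:(m + 1)) Y[1, j] <- open + ext * (j - 2)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (av[i - 1] == bv[j - 1]) match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] + open, X[i - 1, j] + ext,
                     Y[i - 1, j] + open)
      Y[i, j] <- max(M[i, j - 1] + open, Y[i, j - 1] + ext,
                     X[i, j - 1] + open)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# median with halves rounded down, via explicit sorting
oracle_median_hd <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (!n) return(0L)
  if (n %% 2) return(as.integer(s[(n + 1) / 2]))
  as.integer(floor((s[n / 2] + s[n / 2 + 1]) / 2))
}

# naive greedy overlap-consensus mirror (error-free reads; no vote logic):
# merge the pair with the longest exact suffix-prefix overlap, either
# orientation, ties by smaller indices / forward first
oracle_assemble_reads <- function(reads, min_ovl) {
  ovl <- function(a, b) {
    la <- nchar(a); lb <- nchar(b)
    for (L in seq(min(la, lb), min_ovl)) {
      if (substr(a, la - L + 1, la) == substr(b, 1, L)) return(L)
    }
    0L
  }
  items <- reads
  repeat {
    n <- length(items)
    if (n < 2) break
    best <- c(0L, 0L, 0L, 0L)  # L, i, j, o (o: 0 i->j, 1 i->rc(j), 2 rc(i)->j)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      for (o in 0:2) {
        a <- if (o == 2) oracle_revcomp(items[i]) else items[i]
        b <- if (o == 1) oracle_revcomp(items[j]) else items[j]
        L <- ovl(a, b)
        if (L > best[1]) best <- c(L, i, j, o)
      }
    }
    if (best[1] < min_ovl) break
    a <- if (best[4] == 2) oracle_revcomp(items[best[2]]) else items[best[2]]
    b <- if (best[4] == 1) oracle_revcomp(items[best[3]]) else items[best[3]]
    merged <- paste0(a, substr(b, best[1] + 1, nchar(b)))
    items <- c(merged, items[-c(best[2], best[3])])
  }
  items[order(-nchar(items), items)]
}

# build a read_set with uniform quality
mk_reads <- function(seqs, q = 30L) {
  read_set(sprintf("r%04d", seq_along(seqs)), seqs,
           vapply(seqs, function(s) phred_to_qual(rep(q, nchar(s))),
                  character(1), USE.NAMES = FALSE))
}
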