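#' Build the split-key bucket index for counterpart search
#'
#' Keys are the `(k-1)/2`-base prefix and suffix of every cs-kmer, taken in
#' both orientations. Each bucket collects every cs-kmer and every control
#' k-mer (either orientation) starting or ending with its key. Because a
#' single substitution cannot destroy both end keys of a k-mer, any two
#' k-mers at Hamming distance 1 are guaranteed to share a bucket, making
#' the bucket search complete for odd `k`.
#'
#' This R-level index is the reference implementation used on small inputs
#' and in tests; the production path ([match_counterparts()]) performs the
#' same algorithm in C++.
#'
#' @param cs a `cs_kmer_set`.
#' @param control a `kmer_table` from the control library.
#' @return An object of class `key_index`: list with `k`, `key_len` and
#'   `buckets`, a named list of data frames with columns `kmer` (oriented
#'   sequence), `source` (stored canonical form), `origin`
#'   (`case`/`control`), `orientation` (`fwd`/`rc`) and `count`.
#' @export
build_key_index <- function(cs, control) {
  stopifnot(inherits(cs, "cs_kmer_set"), inherits(control, "kmer_table"))
  if (cs$k != control$k) stop("cs-kmer set and control table must share k")
  k <- cs$k
  key_len <- (k - 1L) %/% 2L

  orient_entries <- function(kmers, counts, origin) {
    if (!length(kmers))
      return(data.frame(kmer = character(0), source = character(0),
                        origin = character(0), orientation = character(0),
                        count = integer(0)))
    rc <- revcomp_dna(kmers)
    data.frame(
      kmer = c(kmers, rc),
      source = c(kmers, kmers),
      origin = origin,
      orientation = rep(c("fwd", "rc"), each = length(kmers)),
      count = c(counts, counts))
  }
  ecs <- orient_entries(cs$kmer, cs$case_count, "case")
  ect <- orient_entries(control$kmer, control$count, "control")

  keys_of <- function(x) cbind(substr(x, 1L, key_len),
                               substr(x, k - key_len + 1L, k))
  cs_keys <- unique(as.vector(keys_of(ecs$kmer)))

  all <- rbind(ecs, ect)
  km <- keys_of(all$kmer)
  idx <- data.frame(key = c(km[, 1], km[, 2]), row = rep(seq_len(nrow(all)), 2))
  idx <- idx[idx$key %in% cs_keys, , drop = FALSE]
  idx <- idx[!duplicated(idx), , drop = FALSE]
  buckets <- lapply(split(idx$row, idx$key), function(r) all[r, , drop = FALSE])
  structure(list(k = k, key_len = key_len, buckets = buckets),
            class = "key_index")
}

#' Enumerate Hamming-1 (case, control) pairs from a key index
#'
#' Surveys every bucket for (cs-kmer, control k-mer) pairs at Hamming
#' distance exactly 1 in a shared orientation. Pairs are reported in the
#' cs-kmer's stored orientation. When a cs-kmer has several candidate
#' counterparts, the one with the highest control count wins (ties broken
#' by the lexicographically smallest counterpart); duplicates arising from
#' multiple shared keys or orientations are collapsed.
#'
#' @param index a `key_index`.
#' @return A data frame with columns `cs_kmer`, `ct_kmer`, `pos` (0-based
#'   mismatch offset), `case_allele`, `control_allele`, `ct_count`.
#' @export
find_pairs <- function(index) {
  stopifnot(inherits(index, "key_index"))
  k <- index$k
  best <- new.env(parent = emptyenv())
  for (b in index$buckets) {
    csr <- which(b$origin == "case")
    ctr <- which(b$origin == "control")
    if (!length(csr) || !length(ctr)) next
    for (i in csr) {
      a_raw <- charToRaw(b$kmer[i])
      for (j in ctr) {
        d <- which(a_raw != charToRaw(b$kmer[j]))
        if (length(d) != 1L) next
        ct <- b$kmer[j]
        pos <- d - 1L
        if (b$orientation[i] == "rc") {   # report in stored orientation
          ct <- revcomp_dna(ct)
          pos <- k - 1L - pos
        }
        key <- b$source[i]
        cand <- list(ct = ct, pos = pos, count = b$count[j])
        cur <- if (exists(key, envir = best)) get(key, envir = best) else NULL
        if (is.null(cur) || cand$count > cur$count ||
            (cand$count == cur$count && cand$ct < cur$ct))
          assign(key, cand, envir = best)
      }
    }
  }
  cs_kmer <- sort(ls(best))
  if (!length(cs_kmer))
    return(data.frame(cs_kmer = character(0), ct_kmer = character(0),
                      pos = integer(0), case_allele = character(0),
                      control_allele = character(0), ct_count = integer(0)))
  rows <- lapply(cs_kmer, function(s) {
    x <- get(s, envir = best)
    data.frame(cs_kmer = s, ct_kmer = x$ct, pos = x$pos,
               case_allele = substr(s, x$pos + 1L, x$pos + 1L),
               control_allele = substr(x$ct, x$pos + 1L, x$pos + 1L),
               ct_count = x$count)
  })
  do.call(rbind, rows)
}

#' Pair cs-kmers with wild-type counterparts (production path)
#'
#' C++ implementation of [build_key_index()] + [find_pairs()]; the two
#' routes are asserted equivalent in the test suite.
#'
#' @param cs a `cs_kmer_set`.
#' @param control the (raw) control `kmer_table` to draw counterparts from.
#' @return A pair data frame, as [find_pairs()].
#' @export
match_counterparts <- function(cs, control) {
  stopifnot(inherits(cs, "cs_kmer_set"), inherits(control, "kmer_table"))
  if (cs$k != control$k) stop("cs-kmer set and control table must share k")
  df <- cpp_match_counterparts(cs$kmer, control$kmer, control$count, cs$k)
  df[order(df$cs_kmer), , drop = FALSE]
}

#' Partition cs-kmers into matched and unmatched groups
#'
#' @param cs a `cs_kmer_set`.
#' @param pairs a pair data frame from [find_pairs()] or
#'   [match_counterparts()].
#' @return list with character vectors `matched` and `unmatched`; the two
#'   partition `cs$kmer`.
#' @export
partition_cs_kmers <- function(cs, pairs) {
  stopifnot(inherits(cs, "cs_kmer_set"))
  m <- cs$kmer %in% pairs$cs_kmer
  list(matched = cs$kmer[m], unmatched = cs$kmer[!m])
}
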