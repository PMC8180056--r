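# Greedy iterative k-mer merging. Overlap length L decreases from k-1 to
# min_overlap; at each L two sequences are merged only when the junction is
# unambiguous on both sides (exactly one candidate extension and exactly one
# incoming sequence). Merging is orientation-aware: canonical k-mers from
# one locus may be stored in mixed orientations, so each contig is treated
# as double-stranded and may be flipped when merged.

.oriented <- function(seq, orient) if (orient == "+") seq else revcomp_dna(seq)

.flip_members <- function(members, len, k) {
  members$offset <- len - k - members$offset
  members$strand <- ifelse(members$strand == "+", "-", "+")
  members
}

# one pass of compatible merges at overlap length L; returns contigs + flag
.merge_pass <- function(contigs, L, k) {
  n <- length(contigs)
  if (n < 2L) return(list(contigs = contigs, merged = FALSE))
  # oriented entry tables
  ids <- rep(seq_len(n), each = 2L)
  ors <- rep(c("+", "-"), n)
  oseq <- character(2L * n)
  for (i in seq_len(n)) {
    oseq[2L * i - 1L] <- contigs[[i]]$seq
    oseq[2L * i] <- revcomp_dna(contigs[[i]]$seq)
  }
  lens <- nchar(oseq)
  pref <- substr(oseq, 1L, L)
  suf <- substr(oseq, lens - L + 1L, lens)
  pref_map <- split(seq_along(oseq), pref)
  suf_map <- split(seq_along(oseq), suf)

  used <- rep(FALSE, n)
  merges <- list()
  ord <- .contig_order(contigs)
  for (a in ord) {
    if (used[a]) next
    for (oa in c("+", "-")) {
      if (used[a]) break
      ea <- 2L * a - (oa == "+")
      S <- suf[ea]
      cand <- setdiff(pref_map[[S]], c(2L * a - 1L, 2L * a))
      if (length(cand) != 1L) next
      b <- ids[cand]
      if (used[b]) next
      inc <- setdiff(suf_map[[S]], c(2L * b - 1L, 2L * b))
      if (length(inc) != 1L || ids[inc] != a) next
      merges[[length(merges) + 1L]] <- list(a = a, oa = oa, b = b, ob = ors[cand])
      used[a] <- TRUE
      used[b] <- TRUE
    }
  }
  if (!length(merges)) return(list(contigs = contigs, merged = FALSE))
  drop <- logical(n)
  for (m in merges) {
    ca <- contigs[[m$a]]
    cb <- contigs[[m$b]]
    sa <- .oriented(ca$seq, m$oa)
    sb <- .oriented(cb$seq, m$ob)
    ma <- if (m$oa == "+") ca$members else .flip_members(ca$members, nchar(ca$seq), k)
    mb <- if (m$ob == "+") cb$members else .flip_members(cb$members, nchar(cb$seq), k)
    mb$offset <- mb$offset + nchar(sa) - L
    contigs[[m$a]] <- list(seq = paste0(sa, substr(sb, L + 1L, nchar(sb))),
                           members = rbind(ma, mb))
    drop[m$b] <- TRUE
  }
  list(contigs = contigs[!drop], merged = TRUE)
}

# deterministic processing order: descending best member count, then by
# strand-independent sequence
.contig_order <- function(contigs) {
  topc <- vapply(contigs, function(x) max(x$members$count), numeric(1))
  key <- vapply(contigs, function(x) min(x$seq, revcomp_dna(x$seq)), character(1))
  order(-topc, key)
}

# greedy merge of equal-length seed sequences (cs-kmers or ct-kmers)
.greedy_merge <- function(seqs, counts, k, min_overlap) {
  contigs <- lapply(seq_along(seqs), function(i) {
    list(seq = seqs[i],
         members = data.frame(kmer = seqs[i], offset = 0L, strand = "+",
                              count = counts[i]))
  })
  if (length(contigs) > 1L) {
    for (L in seq(k - 1L, min_overlap)) {
      repeat {
        res <- .merge_pass(contigs, L, k)
        contigs <- res$contigs
        if (!res$merged || length(contigs) < 2L) break
      }
    }
  }
  contigs[.contig_order(contigs)]
}

#' Assemble cs-kmers into mutant contigs
#'
#' Iteratively merges cs-kmers overlapping by `L` bases, with `L` decreasing
#' from `k-1` down to `min_overlap`; a merge is performed only when it is
#' unambiguous (a unique candidate extension with a unique incoming
#' sequence). Every cs-kmer ends up in exactly one contig; isolated
#' cs-kmers become length-`k` contigs. Output order and sequences are
#' invariant under permutation of the input.
#'
#' @param cs a `cs_kmer_set`.
#' @param min_overlap minimum overlap length (default 25 for `k = 31`).
#' @param pairs optional counterpart pair data frame
#'   ([match_counterparts()]); used to mark members matched and to compute
#'   `matched_fraction`.
#' @return An object of class `contig_set`: list of contigs, each a list
#'   with `id`, `seq`, `members` (data frame: `kmer`, `offset`, `strand`,
#'   `count`, `matched`) and `matched_fraction`.
#' @export
assemble_contigs <- function(cs, min_overlap = 25L, pairs = NULL) {
  stopifnot(inherits(cs, "cs_kmer_set"))
  k <- cs$k
  if (min_overlap >= k) stop("min_overlap must be smaller than k")
  if (!length(cs)) return(structure(list(), class = "contig_set"))
  contigs <- .greedy_merge(cs$kmer, cs$case_count, k, as.integer(min_overlap))
  matched_set <- if (is.null(pairs)) character(0) else pairs$cs_kmer
  out <- lapply(seq_along(contigs), function(i) {
    ctg <- contigs[[i]]
    ctg$members$matched <- ctg$members$kmer %in% matched_set
    ctg$members <- ctg$members[order(ctg$members$offset), , drop = FALSE]
    rownames(ctg$members) <- NULL
    ctg$id <- sprintf("contig_%05d", i)
    ctg$matched_fraction <- mean(ctg$members$matched)
    ctg
  })
  structure(out, class = "contig_set")
}

#' @export
print.contig_set <- function(x, ...) {
  cat("contig_set with", length(x), "contigs\n")
  invisible(x)
}

#' Write contigs as FASTA
#'
#' Headers carry the contig id, member count and matched fraction.
#' @param contigs a `contig_set`.
#' @param path output FASTA file.
#' @export
write_contig_fasta <- function(contigs, path) {
  seqs <- Biostrings::DNAStringSet(vapply(contigs, `[[`, character(1), "seq"))
  names(seqs) <- vapply(contigs, function(x)
    sprintf("%s n_members=%d matched_fraction=%.3f",
            x$id, nrow(x$members), x$matched_fraction), character(1))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
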