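# Wild-type reference inference per mutant contig. Two branches:
#  * ct_merge: >50% of member cs-kmers have Hamming-1 counterparts; the
#    counterpart k-mers are merged with the same overlap rule as assembly.
#  * read_assembly: control reads within one mismatch of any member k-mer
#    are retrieved and assembled by greedy overlap consensus.

# median with the even-count convention fixed package-wide: mean of the two
# middle values, halves rounded down to an integer
.median_hd <- function(x) {
  if (!length(x)) return(0L)
  s <- sort(x)
  n <- length(s)
  if (n %% 2L == 1L) as.integer(s[(n + 1L) %/% 2L])
  else as.integer(floor((s[n %/% 2L] + s[n %/% 2L + 1L]) / 2))
}

# counterpart k-mers of a contig's matched members, oriented to the contig
.contig_cts <- function(contig, pairs) {
  m <- contig$members
  idx <- match(m$kmer, pairs$cs_kmer)
  ct <- pairs$ct_kmer[idx]
  ok <- !is.na(ct)
  ct[ok & m$strand == "-"] <- revcomp_dna(ct[ok & m$strand == "-"])
  data.frame(ct = ct, ct_count = pairs$ct_count[idx])[ok, , drop = FALSE]
}

#' Infer the reference contig from merged counterpart k-mers
#'
#' Applies when strictly more than half of the contig's member cs-kmers are
#' matched. The counterpart (ct) k-mers, oriented to the contig, are merged
#' with the same decreasing-overlap rule as contig assembly; the reference
#' is reported only if they merge into a single sequence.
#'
#' @param contig a contig from [assemble_contigs()].
#' @param pairs counterpart pair data frame.
#' @param min_overlap minimum merge overlap (default 25).
#' @return The reference sequence, or `NA_character_` if the ct-kmers do
#'   not merge into one sequence.
#' @export
infer_reference_matched <- function(contig, pairs, min_overlap = 25L) {
  if (contig$matched_fraction <= 0.5)
    stop("infer_reference_matched requires matched_fraction > 0.5")
  k <- nchar(contig$members$kmer[1])
  cts <- .contig_cts(contig, pairs)
  cts <- cts[!duplicated(cts$ct), , drop = FALSE]
  if (!nrow(cts)) return(NA_character_)
  merged <- .greedy_merge(cts$ct, cts$ct_count, k, as.integer(min_overlap))
  if (length(merged) != 1L) return(NA_character_)
  merged[[1]]$seq
}

#' Per-library cs-count and coverage from k-mer medians
#'
#' `cs_count` is the median member cs-kmer count; `coverage` adds the
#' median count of the paired ct-kmers in the same library (a ct-kmer
#' absent from a library counts 0). Medians are used instead of means so
#' repeat- or amplification-inflated k-mers do not dominate.
#'
#' @param contig a contig.
#' @param pairs counterpart pair data frame.
#' @param case_raw,control_raw unfiltered `kmer_table`s of the two
#'   libraries.
#' @return list with `cs_count_case`, `coverage_case`, `cs_count_control`,
#'   `coverage_control`.
#' @export
compute_kmer_stats <- function(contig, pairs, case_raw, control_raw) {
  m <- contig$members
  cs_case <- .median_hd(m$count)
  cs_ctrl <- .median_hd(lookup_counts(control_raw, m$kmer))
  cts <- .contig_cts(contig, pairs)
  if (nrow(cts)) {
    ct_case <- .median_hd(lookup_counts(case_raw, cts$ct))
    ct_ctrl <- .median_hd(lookup_counts(control_raw, cts$ct))
  } else {
    ct_case <- 0L
    ct_ctrl <- 0L
  }
  list(cs_count_case = cs_case, coverage_case = cs_case + ct_case,
       cs_count_control = cs_ctrl, coverage_control = cs_ctrl + ct_ctrl)
}

#' Retrieve control reads within one mismatch of a contig
#'
#' Returns every control read containing, in either orientation, at least
#' one length-`k` window within Hamming distance 1 of some member k-mer of
#' the contig (the 1-mismatch k-mer screen used for the read-assembly
#' branch).
#'
#' @param contig a contig.
#' @param control_reads a `read_set`.
#' @param k k-mer length.
#' @return A `read_set` with the retrieved reads.
#' @export
retrieve_control_reads <- function(contig, control_reads, k = 31L) {
  hits <- cpp_retrieve_reads_multi(list(contig$members$kmer),
                                   control_reads$seq, as.integer(k))[[1]]
  read_set(control_reads$id[hits], control_reads$seq[hits],
           control_reads$qual[hits])
}

#' Assemble retrieved control reads into a reference
#'
#' Greedy overlap-consensus assembly: the pair of current consensus
#' sequences with the longest exact suffix-prefix overlap (at least
#' `min_read_overlap`, either orientation, `N` wildcard) is merged
#' repeatedly; per-column majority vote over supporting reads calls the
#' consensus. The longest assembled sequence is the putative reference;
#' coverage for this branch is the number of retrieved reads.
#'
#' @param reads a `read_set` (or character vector of read sequences).
#' @param min_read_overlap minimum exact overlap (default 30).
#' @return list with `ref_seq` (`NA_character_` if no reads) and
#'   `n_support_reads`.
#' @export
assemble_control_reads <- function(reads, min_read_overlap = 30L) {
  seqs <- if (inherits(reads, "read_set")) reads$seq else as.character(reads)
  if (!length(seqs)) return(list(ref_seq = NA_character_, n_support_reads = 0L))
  res <- cpp_assemble_reads(seqs, as.integer(min_read_overlap))
  list(ref_seq = res$consensus[1], n_support_reads = length(seqs))
}

#' Infer references and statistics for all contigs
#'
#' Routes every contig through exactly one branch: `ct_merge` when
#' `matched_fraction > 0.5` (strict), otherwise `read_assembly`; a failed
#' ct-kmer merge falls back to `read_assembly` so every contig gets a
#' reference attempt. Read retrieval for all read-assembly contigs is done
#' in one pass over the control library.
#'
#' @param contigs a `contig_set`.
#' @param pairs counterpart pair data frame.
#' @param case_raw,control_raw unfiltered `kmer_table`s.
#' @param control_reads cleaned control `read_set`.
#' @param min_overlap ct-kmer merge overlap (default 25).
#' @param min_read_overlap read merge overlap (default 30).
#' @param max_reads_per_contig cap on reads fed to the assembler per contig
#'   (default 120, ample at 50x coverage; the retrieved-read count is still
#'   reported in full).
#' @return The `contig_set` with per-contig fields `branch`, `ref_seq`,
#'   `cs_count_case`, `coverage_case`, `cs_count_control`,
#'   `coverage_control`, `n_support_reads`.
#' @export
infer_references <- function(contigs, pairs, case_raw, control_raw,
                             control_reads, min_overlap = 25L,
                             min_read_overlap = 30L,
                             max_reads_per_contig = 120L) {
  k <- case_raw$k
  need_reads <- logical(length(contigs))
  # batched count lookups: one hash build per table instead of one per contig
  cts_list <- lapply(contigs, .contig_cts, pairs = pairs)
  mems <- unlist(lapply(contigs, function(x) x$members$kmer))
  mem_grp <- rep(seq_along(contigs),
                 vapply(contigs, function(x) nrow(x$members), integer(1)))
  ctq <- unlist(lapply(cts_list, `[[`, "ct"))
  ct_grp <- rep(seq_along(contigs), vapply(cts_list, nrow, integer(1)))
  mem_ctrl <- lookup_counts(control_raw, mems)
  ct_case <- lookup_counts(case_raw, ctq)
  ct_ctrl <- lookup_counts(control_raw, ctq)
  for (i in seq_along(contigs)) {
    ctg <- contigs[[i]]
    cs_case <- .median_hd(ctg$members$count)
    cs_ctrl <- .median_hd(mem_ctrl[mem_grp == i])
    sel <- ct_grp == i
    st <- list(cs_count_case = cs_case,
               coverage_case = cs_case +
                 (if (any(sel)) .median_hd(ct_case[sel]) else 0L),
               cs_count_control = cs_ctrl,
               coverage_control = cs_ctrl +
                 (if (any(sel)) .median_hd(ct_ctrl[sel]) else 0L))
    ctg[names(st)] <- st
    if (ctg$matched_fraction > 0.5) {
      ref <- infer_reference_matched(ctg, pairs, min_overlap)
      if (!is.na(ref)) {
        ctg$branch <- "ct_merge"
        ctg$ref_seq <- ref
        ctg$n_support_reads <- NA_integer_
      } else need_reads[i] <- TRUE
    } else need_reads[i] <- TRUE
    contigs[[i]] <- ctg
  }
  if (any(need_reads)) {
    members <- lapply(contigs[need_reads], function(x) x$members$kmer)
    hits <- cpp_retrieve_reads_multi(members, control_reads$seq, as.integer(k))
    for (j in seq_along(hits)) {
      i <- which(need_reads)[j]
      ctg <- contigs[[i]]
      idx <- hits[[j]]
      n_total <- length(idx)
      if (n_total > max_reads_per_contig) idx <- idx[seq_len(max_reads_per_contig)]
      asm <- assemble_control_reads(control_reads$seq[idx], min_read_overlap)
      ctg$branch <- "read_assembly"
      ctg$ref_seq <- asm$ref_seq
      ctg$n_support_reads <- n_total
      # control-side coverage for this branch is the retrieved-read count
      ctg$coverage_control <- max(n_total, ctg$cs_count_control)
      contigs[[i]] <- ctg
    }
  }
  contigs
}
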