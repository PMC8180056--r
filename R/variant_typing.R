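# Typing of mutant contigs against their inferred references: global
# pairwise alignment, parsing of the edit structure, classification into
# mutation / multiple_mutation / indel / sv / unresolved.

.submat <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      bases <- c("A", "C", "G", "T", "N")
      mm <- matrix(-1, 5, 5, dimnames = list(bases, bases))
      diag(mm) <- 2
      mm["N", ] <- 0
      mm[, "N"] <- 0
      m <<- mm
    }
    m
  }
})

#' Globally align a mutant contig to its putative reference
#'
#' Needleman-Wunsch with affine gaps: match +2, mismatch -1, a length-L gap
#' costs 2 + 0.5*(L-1) (i.e. open -2 on the first gap base, extend -0.5
#' thereafter); `N` scores 0 against anything. Classification downstream
#' depends only on the alignment's edit structure, which cushions the exact
#' parameter choice.
#'
#' @param mutant,ref non-empty DNA strings.
#' @return list with `pattern` and `subject` (aligned strings with `-`)
#'   and `score`.
#' @export
align_contig_pair <- function(mutant, ref) {
  stopifnot(nchar(mutant) > 0, nchar(ref) > 0)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(mutant), Biostrings::DNAString(ref),
    type = "global", substitutionMatrix = .submat(),
    gapOpening = 1.5, gapExtension = 0.5)
  list(pattern = as.character(Biostrings::alignedPattern(aln)),
       subject = as.character(Biostrings::alignedSubject(aln)),
       score = Biostrings::score(aln))
}

# column-level parse of an alignment into states M/I/D plus offsets
.parse_alignment <- function(aln) {
  p <- strsplit(aln$pattern, "")[[1]]
  s <- strsplit(aln$subject, "")[[1]]
  state <- ifelse(p == "-", "D", ifelse(s == "-", "I", "M"))
  poff <- cumsum(p != "-") - 1L   # 0-based pattern offset per column
  soff <- cumsum(s != "-") - 1L
  sub <- state == "M" & p != s & p %in% c("A", "C", "G", "T") &
    s %in% c("A", "C", "G", "T")
  list(p = p, s = s, state = state, poff = poff, soff = soff, sub = sub)
}

#' Classify a contig/reference pair into a variant call
#'
#' Decision rules, applied in order to the global alignment:
#' no reference assembled -> `sv` (candidate junction); an internal gap run
#' of 50+ bases, 25+ contig bases overhanging the reference at one end, or
#' 8+ substitution columns (far beyond what point mutations can produce at
#' realistic rates, and typical of a junction half aligned against the
#' wrong locus) -> `sv`; internal gaps with net length 1-49 -> `indel`
#' (anchored, left-shifted); exactly one substitution -> `mutation`; two or
#' more -> `multiple_mutation`; an identical pair -> `unresolved`.
#'
#' Terminal gap runs (the overhang of the longer sequence) are not treated
#' as deletions: the read-assembled reference usually extends well past the
#' contig.
#'
#' @param mutant mutant contig sequence.
#' @param ref reference sequence or `NA`.
#' @param try_revcomp also align against the reverse complement of `ref`
#'   and use the better-scoring orientation (default `TRUE`).
#' @return list with `var_type`, `pos_in_contig` and `pos_in_ref` (0-based
#'   anchors), `ref_allele`, `alt_allele`, `ref_used` (the reference in the
#'   orientation used) and `alignment`.
#' @export
classify_variant <- function(mutant, ref, try_revcomp = TRUE) {
  if (is.null(ref) || is.na(ref) || !nzchar(ref)) {
    return(list(var_type = "sv", pos_in_contig = 0L, pos_in_ref = NA_integer_,
                ref_allele = "N", alt_allele = "<SV>", ref_used = NA_character_,
                alignment = NULL))
  }
  ref_used <- ref
  if (try_revcomp) {
    # orient the reference by shared 15-mers; only on a tie fall back to
    # comparing full alignment scores
    rcr <- revcomp_dna(ref)
    offs <- .anchor_offsets(nchar(mutant), 15L, stride = 5L)
    probes <- substring(mutant, offs + 1L, offs + 15L)
    sc_f <- sum(vapply(probes, grepl, logical(1), x = ref, fixed = TRUE))
    sc_r <- sum(vapply(probes, grepl, logical(1), x = rcr, fixed = TRUE))
    if (sc_r > sc_f) ref_used <- rcr
    else if (sc_r == sc_f && sc_f == 0) {
      a1 <- align_contig_pair(mutant, ref)
      a2 <- align_contig_pair(mutant, rcr)
      if (a2$score > a1$score) ref_used <- rcr
    }
  }
  # restrict a long read-assembled reference to the contig's neighbourhood
  # before the (quadratic) global alignment
  if (nchar(ref_used) > nchar(mutant) + 300L) {
    offs <- .anchor_offsets(nchar(mutant), 15L, stride = 5L)
    probes <- substring(mutant, offs + 1L, offs + 15L)
    hits <- vapply(probes, regexpr, integer(1), text = ref_used,
                   fixed = TRUE, USE.NAMES = FALSE)
    hits <- hits[hits > 0L]
    if (length(hits)) {
      lo <- max(1L, min(hits) - nchar(mutant) - 100L)
      hi <- min(nchar(ref_used), max(hits) + 14L + nchar(mutant) + 100L)
      ref_used <- substr(ref_used, lo, hi)
    }
  }
  aln <- align_contig_pair(mutant, ref_used)
  pa <- .parse_alignment(aln)
  n <- length(pa$state)
  # delimit the alignment core by solid runs of >= 8 identical bases: short
  # coincidental matches at a far-away position must not convert a terminal
  # overhang into spurious internal variation, and mismatch-rich "soup" at
  # a junction must not anchor the core
  eq <- pa$state == "M" & pa$p == pa$s
  eqruns <- rle(eq)
  rends <- cumsum(eqruns$lengths)
  rstarts <- rends - eqruns$lengths + 1L
  solid <- which(eqruns$values & eqruns$lengths >= 8L)
  if (length(solid)) {
    bounds <- c(rstarts[solid[1]], rends[solid[length(solid)]])
  } else {
    m <- which(pa$state == "M")
    bounds <- if (length(m)) range(m) else c(NA_integer_, NA_integer_)
  }
  res <- .classify_core(pa, n, bounds[1], bounds[2], mutant, ref_used, aln)
  if (res$var_type == "unresolved" && length(solid)) {
    # the solid core was clean but variation sits in a short clipped end
    # (e.g. a variant near the contig edge): retry with loose bounds
    m <- which(pa$state == "M")
    loose <- .classify_core(pa, n, m[1], m[length(m)], mutant, ref_used, aln)
    if (loose$var_type %in% c("mutation", "multiple_mutation", "indel"))
      res <- loose
  }
  res
}

# decision rules over the alignment core [first, last]
.classify_core <- function(pa, n, first, last, mutant, ref_used, aln) {
  # contig bases left out of the core at either end (overhang / unaligned)
  clip_left <- if (!is.na(first) && first > 1L)
    sum(pa$state[seq_len(first - 1L)] != "D") else 0L
  clip_right <- if (!is.na(first) && last < n)
    sum(pa$state[seq(last + 1L, n)] != "D") else 0L
  if (is.na(first) || first > last) {   # nothing solidly aligned at all
    return(list(var_type = "sv", pos_in_contig = 0L, pos_in_ref = NA_integer_,
                ref_allele = "N", alt_allele = "<SV>", ref_used = ref_used,
                alignment = aln))
  }
  core <- seq(first, last)
  st <- pa$state[core]
  runs <- rle(st)
  gap_runs <- which(runs$values != "M")
  gap_lens <- runs$lengths[gap_runs]
  nsub <- sum(pa$sub[core])
  acgt <- c("A", "C", "G", "T")
  n_ident <- sum(st == "M" & pa$p[core] %in% acgt & pa$s[core] %in% acgt)
  ins_len <- sum(st == "I")
  del_len <- sum(st == "D")
  net_gap <- abs(ins_len - del_len)

  sv_call <- function(col) {
    list(var_type = "sv",
         pos_in_contig = pa$poff[col],
         pos_in_ref = pa$soff[col],
         ref_allele = "N", alt_allele = "<SV>",
         ref_used = ref_used, alignment = aln)
  }
  if (length(gap_lens) && max(gap_lens) >= 50L) {
    r <- gap_runs[which.max(gap_lens)]
    col <- core[sum(runs$lengths[seq_len(r - 1L)]) + 1L]
    return(sv_call(col))
  }
  if (clip_left >= 20L) return(sv_call(first))
  if (clip_right >= 20L) return(sv_call(last))
  if (nsub >= 8L) return(sv_call(core[which(pa$sub[core])[1]]))
  # a junction half forced onto the wrong locus shows collapsed identity,
  # far beyond point-mutation or sequencing-error densities
  if (n_ident >= 20L && nsub / n_ident > 0.15)
    return(sv_call(core[which(pa$sub[core])[1]]))
  # or dissolves into scattered gap runs: a genuine small indel produces a
  # single internal gap run (possibly two with a sequencing error), never
  # a sprinkle of them
  if (length(gap_runs) >= 3L && ins_len + del_len >= 15L)
    return(sv_call(core[sum(runs$lengths[seq_len(gap_runs[1] - 1L)]) + 1L]))
  if (length(gap_runs)) {
    # first internal gap run, anchored VCF-style and left-shifted
    r <- gap_runs[1]
    beg <- sum(runs$lengths[seq_len(r - 1L)]) + 1L
    len <- runs$lengths[r]
    cols <- core[seq(beg, beg + len - 1L)]
    is_del <- runs$values[r] == "D"
    gap_seq <- if (is_del) paste(pa$s[cols], collapse = "")
               else paste(pa$p[cols], collapse = "")
    anchor_col <- core[beg] - 1L
    pos_c <- pa$poff[anchor_col]
    pos_r <- pa$soff[anchor_col]
    anchor <- substr(mutant, pos_c + 1L, pos_c + 1L)
    # left-shift while the base before the gap equals its last base
    host <- if (is_del) ref_used else mutant
    hpos <- if (is_del) pos_r else pos_c
    while (hpos > 0L &&
           substr(host, hpos + 1L, hpos + 1L) ==
           substr(gap_seq, nchar(gap_seq), nchar(gap_seq))) {
      gap_seq <- paste0(substr(host, hpos + 1L, hpos + 1L),
                        substr(gap_seq, 1L, nchar(gap_seq) - 1L))
      hpos <- hpos - 1L
      pos_c <- pos_c - 1L
      pos_r <- pos_r - 1L
      anchor <- substr(mutant, pos_c + 1L, pos_c + 1L)
    }
    ref_allele <- if (is_del) paste0(anchor, gap_seq) else anchor
    alt_allele <- if (is_del) anchor else paste0(anchor, gap_seq)
    return(list(var_type = "indel", pos_in_contig = pos_c, pos_in_ref = pos_r,
                ref_allele = ref_allele, alt_allele = alt_allele,
                ref_used = ref_used, alignment = aln))
  }
  subs <- core[which(pa$sub[core])]
  if (length(subs) == 1L) {
    return(list(var_type = "mutation",
                pos_in_contig = pa$poff[subs], pos_in_ref = pa$soff[subs],
                ref_allele = pa$s[subs], alt_allele = pa$p[subs],
                ref_used = ref_used, alignment = aln))
  }
  if (length(subs) >= 2L) {
    span <- seq(subs[1], subs[length(subs)])
    return(list(var_type = "multiple_mutation",
                pos_in_contig = pa$poff[subs[1]], pos_in_ref = pa$soff[subs[1]],
                ref_allele = paste(pa$s[span], collapse = ""),
                alt_allele = paste(pa$p[span], collapse = ""),
                ref_used = ref_used, alignment = aln))
  }
  list(var_type = "unresolved", pos_in_contig = 0L, pos_in_ref = 0L,
       ref_allele = "N", alt_allele = "N", ref_used = ref_used,
       alignment = aln)
}

#' Type all scored contigs
#'
#' Runs [classify_variant()] on every contig and collects a call table.
#'
#' @param contigs a `contig_set` after [score_contigs()].
#' @return A data frame of calls (class `variant_calls`), one row per
#'   contig, with typing, statistics and (initially contig-space)
#'   coordinates.
#' @export
type_contigs <- function(contigs) {
  rows <- lapply(contigs, function(ctg) {
    cls <- classify_variant(ctg$seq, ctg$ref_seq)
    data.frame(
      contig_id = ctg$id,
      mutant_seq = ctg$seq,
      ref_seq = if (is.null(ctg$ref_seq)) NA_character_ else ctg$ref_seq,
      ref_used = cls$ref_used,
      var_type = cls$var_type,
      pos_in_contig = cls$pos_in_contig,
      pos_in_ref = cls$pos_in_ref,
      ref_allele = cls$ref_allele,
      alt_allele = cls$alt_allele,
      branch = ctg$branch,
      cs_count = ctg$cs_count_case,
      coverage = ctg$coverage_case,
      control_cs_count = ctg$cs_count_control,
      control_coverage = ctg$coverage_control,
      n_support_reads = if (is.null(ctg$n_support_reads)) NA_integer_
                        else ctg$n_support_reads,
      af = ctg$af,
      p_value = ctg$p_value,
      phred = ctg$phred,
      matched_fraction = ctg$matched_fraction,
      chrom = NA_character_,
      pos = NA_integer_,
      pos2 = NA_integer_,
      unmapped = NA,
      stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    utils::read.table(text = "", col.names = c("contig_id"))
  class(out) <- c("variant_calls", class(out))
  out
}
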