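# Genome coordinate lift-over for calls, using an internal unique-k-mer
# anchor index of the genome rather than an external aligner. Calls whose
# sequences cannot be anchored keep contig coordinates and are flagged
# UNMAPPED.

# anchor offsets for a sequence: k-mer windows at a fixed stride plus the
# final window
.anchor_offsets <- function(len, k, stride = 7L) {
  if (len < k) return(integer(0))
  off <- seq(0L, len - k, by = stride)
  if (off[length(off)] != len - k) off <- c(off, len - k)
  off
}

# majority-vote placement of one sequence; returns list(start0, strand) or
# NULL. Anchors mapping to the minus strand vote for the placement of the
# reverse complement.
.vote_place <- function(seq, loc, offs, k) {
  if (!length(offs)) return(NULL)
  len <- nchar(seq)
  g_plus <- ifelse(!is.na(loc$pos0) & loc$strand == 1L, loc$pos0 - offs, NA)
  g_minus <- ifelse(!is.na(loc$pos0) & loc$strand == -1L,
                    loc$pos0 - (len - k - offs), NA)
  vote <- function(g) {
    g <- g[!is.na(g)]
    if (!length(g)) return(NULL)
    tab <- sort(table(g), decreasing = TRUE)
    list(start0 = as.integer(names(tab)[1]), n = as.integer(tab[1]))
  }
  vp <- vote(g_plus)
  vm <- vote(g_minus)
  if (is.null(vp) && is.null(vm)) return(NULL)
  if (is.null(vm) || (!is.null(vp) && vp$n >= vm$n))
    list(start0 = vp$start0, strand = "+", n = vp$n)
  else
    list(start0 = vm$start0, strand = "-", n = vm$n)
}

# walk an exact match of `seq` against `genome` starting at genome offset
# g0 (both 0-based); returns the first mismatching offset in `seq`
.walk_match <- function(seq, genome, g0, from = 0L) {
  len <- nchar(seq)
  glen <- nchar(genome)
  i <- from
  while (i < len && g0 + i < glen &&
         substr(seq, i + 1L, i + 1L) == substr(genome, g0 + i + 1L, g0 + i + 1L))
    i <- i + 1L
  i
}

#' Place calls on a supplied genome
#'
#' Point and indel calls are placed through their wild-type reference
#' sequence (unique-k-mer anchor voting, both strands); the variant
#' coordinate is the alignment anchor lifted to genome space. Junction
#' (`sv`) calls are placed by exact extension of the contig's flanks: both
#' flank breakpoints are reported (`pos`, `pos2`). Minus-strand placements
#' flip the call to genome orientation and re-type it (classification is
#' strand-invariant). Calls that cannot be anchored are flagged unmapped
#' and keep contig coordinates.
#'
#' @param calls a `variant_calls` data frame from [type_contigs()].
#' @param genome a single genome sequence (character) or path to a FASTA.
#' @param chrom chromosome name to report (default: FASTA record name or
#'   `"chr1"`).
#' @param k anchor k-mer size (default 31).
#' @return `calls` with `chrom`, `pos` (1-based), `pos2` and `unmapped`
#'   filled in.
#' @export
place_calls <- function(calls, genome, chrom = NULL, k = 31L) {
  if (length(genome) == 1 && file.exists(genome)) {
    gs <- Biostrings::readDNAStringSet(genome)
    if (is.null(chrom)) chrom <- sub("\\s.*", "", names(gs)[1])
    genome <- as.character(gs[[1]])
  }
  if (is.null(chrom)) chrom <- "chr1"
  if (!nrow(calls)) return(calls)
  k <- as.integer(k)

  # phase A: collect anchors over all calls
  place_seq <- ifelse(calls$var_type %in% c("mutation", "multiple_mutation",
                                            "indel") & !is.na(calls$ref_used),
                      calls$ref_used, calls$mutant_seq)
  anchors <- character(0)
  a_call <- integer(0)
  a_off <- integer(0)
  for (i in seq_len(nrow(calls))) {
    offs <- .anchor_offsets(nchar(place_seq[i]), k)
    sub <- substring(place_seq[i], offs + 1L, offs + k)
    ok <- !grepl("[^ACGT]", sub)
    anchors <- c(anchors, sub[ok])
    a_call <- c(a_call, rep(i, sum(ok)))
    a_off <- c(a_off, offs[ok])
  }
  loc <- if (length(anchors)) cpp_locate_kmers(genome, anchors, k) else
    list(pos0 = integer(0), strand = integer(0), ambiguous = logical(0))

  calls$chrom <- chrom
  calls$unmapped <- TRUE
  for (i in seq_len(nrow(calls))) {
    if (!(calls$var_type[i] %in% c("mutation", "multiple_mutation", "indel")) ||
        is.na(calls$pos_in_ref[i])) {
      # junction or unresolved call: every k-sized anchor crosses the
      # junction, so place the flanks by exact extension instead
      bp <- .place_junction(calls$mutant_seq[i], genome)
      if (is.null(bp)) {
        calls$chrom[i] <- calls$contig_id[i]
        calls$pos[i] <- calls$pos_in_contig[i] + 1L
      } else {
        calls$pos[i] <- bp$pos
        calls$pos2[i] <- bp$pos2
        calls$unmapped[i] <- FALSE
      }
      next
    }
    sel <- a_call == i
    pl <- .vote_place(place_seq[i], lapply(loc, `[`, sel), a_off[sel], k)
    if (is.null(pl)) {
      calls$chrom[i] <- calls$contig_id[i]
      calls$pos[i] <- calls$pos_in_contig[i] + 1L
      next
    }
    if (pl$strand == "-") {
      # flip the call to genome orientation and re-type
      mut <- revcomp_dna(calls$mutant_seq[i])
      ref <- if (is.na(calls$ref_used[i])) NA_character_ else
        revcomp_dna(calls$ref_used[i])
      cls <- classify_variant(mut, ref, try_revcomp = FALSE)
      calls$mutant_seq[i] <- mut
      calls$ref_used[i] <- cls$ref_used
      calls$var_type[i] <- cls$var_type
      calls$pos_in_contig[i] <- cls$pos_in_contig
      calls$pos_in_ref[i] <- cls$pos_in_ref
      calls$ref_allele[i] <- cls$ref_allele
      calls$alt_allele[i] <- cls$alt_allele
      place_seq[i] <- if (calls$var_type[i] %in%
                          c("mutation", "multiple_mutation", "indel") &&
                          !is.na(calls$ref_used[i]))
        calls$ref_used[i] else mut
      # placement start of the flipped sequence
      pl$start0 <- pl$start0  # same start: anchors voted for the rc placement
    }
    if (calls$var_type[i] %in% c("mutation", "multiple_mutation", "indel") &&
        !is.na(calls$pos_in_ref[i])) {
      calls$pos[i] <- pl$start0 + calls$pos_in_ref[i] + 1L
      calls$unmapped[i] <- FALSE
    } else {
      # the minus-strand re-type turned this into a junction call
      bp <- .place_junction(calls$mutant_seq[i], genome)
      if (!is.null(bp)) {
        calls$pos[i] <- bp$pos
        calls$pos2[i] <- bp$pos2
        calls$unmapped[i] <- FALSE
      } else {
        calls$chrom[i] <- calls$contig_id[i]
        calls$pos[i] <- calls$pos_in_contig[i] + 1L
      }
    }
  }
  calls
}

# breakpoint placement for a junction contig: anchor the first (last)
# uniquely mapping short k-mer (15 bases: long k-sized anchors would all
# cross the junction), extend the exact match right (left), and report the
# genome position where each flank's match ends; tried in both contig
# orientations
.place_junction <- function(seq, genome, k = 15L) {
  for (s in list(seq, revcomp_dna(seq))) {
    len <- nchar(s)
    if (len < k) next
    offs <- .anchor_offsets(len, k, stride = 2L)
    sub <- substring(s, offs + 1L, offs + k)
    ok <- !grepl("[^ACGT]", sub)
    offs <- offs[ok]
    sub <- sub[ok]
    if (!length(sub)) next
    loc <- cpp_locate_kmers(genome, sub, k)
    fwd <- which(!is.na(loc$pos0) & loc$strand == 1L)
    if (!length(fwd)) next
    # left flank: earliest forward anchor
    a <- fwd[1]
    g0 <- loc$pos0[a] - offs[a]
    end <- .walk_match(s, genome, g0, from = offs[a])
    pos <- g0 + end + 1L          # 1-based position after the left flank
    # right flank: latest forward anchor consistent with a different locus
    b <- fwd[length(fwd)]
    g0b <- loc$pos0[b] - offs[b]
    pos2 <- NA_integer_
    if (g0b != g0) {
      # walk backwards from the right flank anchor
      i <- offs[b]
      while (i > 0L && g0b + i - 1L >= 0L &&
             substr(s, i, i) == substr(genome, g0b + i, g0b + i))
        i <- i - 1L
      pos2 <- g0b + i + 1L        # 1-based first matched base of right flank
    }
    return(list(pos = as.integer(pos), pos2 = pos2))
  }
  NULL
}
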