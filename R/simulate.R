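# Matched case/control read simulator with planted SNVs, small indels and
# structural-variant junctions, plus the truth-based evaluator.

# run expr under a private RNG stream, restoring the caller's state
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Default structural-variant event list
#'
#' Twelve events (deletions, tandem duplications and templated-insertion
#' translocation junctions in rotation) with lengths spread from 60 to
#' 500 bp, all above the conventional 50 bp structural-variant threshold.
#' @param n number of events (default 12).
#' @export
default_sv_events <- function(n = 12L) {
  types <- rep(c("deletion", "duplication", "translocation"),
               length.out = n)
  lens <- as.integer(round(seq(60, 500, length.out = n)))
  data.frame(type = types, length = lens, stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Defaults encode the benchmark protocol emulated throughout: case
#' mutation rate 1e-4 and control rate 0, 20% of small variants being
#' indels (lengths 1-10), expected VAF drawn from \{0.1, ..., 0.5\},
#' mean coverage 50x with 2x100 bp paired reads, per-base error rate
#' 0.001, and a set of structural variants longer than 50 bp.
#'
#' @param genome_len genome length in bp.
#' @param seed integer seed controlling every random choice.
#' @param snv_rate per-base rate of small variants in the case sample.
#' @param indel_fraction fraction of small variants that are indels.
#' @param vaf_choices candidate variant allele frequencies.
#' @param coverage mean fold coverage.
#' @param read_len read length in bp.
#' @param paired paired-end sequencing.
#' @param error_rate per-base substitution error rate.
#' @param sv_events data frame with columns `type`
#'   (`deletion`/`duplication`/`translocation`) and `length` (> 50), or
#'   `NULL` for none.
#' @param fragment_mean,fragment_sd insert-size model for paired reads.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(genome_len = 5e5, seed = 1L, snv_rate = 1e-4,
                       indel_fraction = 0.2,
                       vaf_choices = seq(0.1, 0.5, by = 0.1),
                       coverage = 50, read_len = 100L, paired = TRUE,
                       error_rate = 0.001, sv_events = default_sv_events(),
                       fragment_mean = 350, fragment_sd = 30) {
  stopifnot(snv_rate >= 0, snv_rate <= 1, indel_fraction >= 0,
            indel_fraction <= 1, error_rate >= 0, error_rate <= 1,
            all(vaf_choices > 0 & vaf_choices <= 1))
  if (!is.null(sv_events) && nrow(sv_events) && any(sv_events$length <= 50))
    stop("structural-variant lengths must exceed 50 bp")
  structure(list(genome_len = as.integer(genome_len), seed = as.integer(seed),
                 snv_rate = snv_rate, indel_fraction = indel_fraction,
                 vaf_choices = vaf_choices, coverage = coverage,
                 read_len = as.integer(read_len), paired = paired,
                 error_rate = error_rate, sv_events = sv_events,
                 fragment_mean = fragment_mean, fragment_sd = fragment_sd),
            class = "sim_config")
}

#' Generate a uniform random genome
#'
#' Deterministic for a given seed. `repeat_segment = TRUE` copies a 2 kb
#' segment to a second locus to emulate a simple repeat.
#'
#' @param length genome length (>= 1000).
#' @param seed integer seed.
#' @param repeat_segment insert a duplicated segment.
#' @return A single DNA string.
#' @export
generate_genome <- function(length, seed, repeat_segment = FALSE) {
  stopifnot(length >= 1000)
  .with_seed(seed, {
    g <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
               collapse = "")
    if (repeat_segment && length >= 10000) {
      seg <- substr(g, length %/% 4, length %/% 4 + 1999)
      at <- 3 * length %/% 4
      g <- paste0(substr(g, 1, at - 1), seg,
                  substr(g, at + 2000, length))
      g <- substr(g, 1, length)
    }
    g
  })
}

# one planted variant as an anchored replacement on the wild genome:
# wild footprint [fs, fe] (0-based, fe < fs for pure insertions) replaced
# by `alt_seq`
.mk_region <- function(genome, fs, fe, alt_seq, window = 600L) {
  L <- nchar(genome)
  ws <- max(0L, fs - window)
  we <- min(L - 1L, max(fe, fs - 1L) + window)
  left <- if (fs > ws) substr(genome, ws + 1L, fs) else ""
  right <- if (fe + 1L <= we) substr(genome, fe + 2L, we + 1L) else ""
  list(ws = ws, fs = fs, fe = fe,
       mutwin = paste0(left, alt_seq, right))
}

#' Plant variants into a genome
#'
#' Small variants are drawn per base at `snv_rate`; each is an indel with
#' probability `indel_fraction` (length 1-10, insertion or deletion with
#' equal probability) and an SNV otherwise. Configured structural-variant
#' events are placed without overlap: deletions remove a segment, tandem
#' duplications repeat one, translocation junctions insert a distant
#' segment. Every variant receives a VAF drawn from `vaf_choices` and is
#' realised at read time by local haplotype mixing. Planted events are
#' kept at least 150 bp apart so neighbouring variants stay unlinked.
#'
#' @param genome wild-type genome string.
#' @param config a `sim_config`.
#' @return list with `truth` (data frame: `pos0` 0-based, `pos0_alt`,
#'   `type` in `snv`/`ins`/`del`/`sv`, `svtype`, `ref_allele`,
#'   `alt_allele`, `length`, `vaf`) and `regions` (per-variant replacement
#'   windows consumed by [simulate_reads()]).
#' @export
plant_variants <- function(genome, config) {
  L <- nchar(genome)
  .with_seed(config$seed + 1L, {
    margin <- 600L
    pos <- which(stats::runif(L) < config$snv_rate) - 1L
    pos <- pos[pos >= margin & pos < L - margin]
    if (length(pos) > 1L) {    # enforce >= 150 bp spacing
      keep <- c(TRUE, diff(pos) >= 150L)
      while (!all(keep)) {
        pos <- pos[keep]
        keep <- c(TRUE, diff(pos) >= 150L)
      }
    }
    truth <- list()
    regions <- list()
    occupied <- cbind(pos - 150L, pos + 150L)
    base_at <- function(p0) substr(genome, p0 + 1L, p0 + 1L)
    for (p in pos) {
      vaf <- sample(config$vaf_choices, 1L)
      if (stats::runif(1) < config$indel_fraction) {
        len <- sample.int(10L, 1L)
        if (stats::runif(1) < 0.5) {  # deletion of [p+1, p+len]
          ref_a <- substr(genome, p + 1L, p + 1L + len)
          alt_a <- base_at(p)
          truth[[length(truth) + 1L]] <- data.frame(
            pos0 = p, pos0_alt = NA_integer_, type = "del", svtype = NA,
            ref_allele = ref_a, alt_allele = alt_a, length = len, vaf = vaf)
          regions[[length(regions) + 1L]] <-
            c(.mk_region(genome, p + 1L, p + len, ""), vaf = vaf)
        } else {                      # insertion after p
          ins <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                       collapse = "")
          truth[[length(truth) + 1L]] <- data.frame(
            pos0 = p, pos0_alt = NA_integer_, type = "ins", svtype = NA,
            ref_allele = base_at(p), alt_allele = paste0(base_at(p), ins),
            length = len, vaf = vaf)
          regions[[length(regions) + 1L]] <-
            c(.mk_region(genome, p + 1L, p, ins), vaf = vaf)
        }
      } else {
        ref_b <- base_at(p)
        alt_b <- sample(setdiff(c("A", "C", "G", "T"), ref_b), 1L)
        truth[[length(truth) + 1L]] <- data.frame(
          pos0 = p, pos0_alt = NA_integer_, type = "snv", svtype = NA,
          ref_allele = ref_b, alt_allele = alt_b, length = 1L, vaf = vaf)
        regions[[length(regions) + 1L]] <-
          c(.mk_region(genome, p, p, alt_b), vaf = vaf)
      }
    }
    # structural variants
    sv <- config$sv_events
    if (!is.null(sv) && nrow(sv)) {
      for (i in seq_len(nrow(sv))) {
        len <- sv$length[i]
        ty <- sv$type[i]
        vaf <- sample(config$vaf_choices, 1L)
        ok <- FALSE
        for (try in 1:200) {
          a <- sample.int(L - len - 2L * margin, 1L) + margin
          lo <- a - margin
          hi <- a + len + margin
          if (!any(occupied[, 1] <= hi & occupied[, 2] >= lo)) { ok <- TRUE; break }
        }
        if (!ok) stop("genome too short to place the requested SV events")
        occupied <- rbind(occupied, c(a - margin, a + len + margin))
        if (ty == "deletion") {
          truth[[length(truth) + 1L]] <- data.frame(
            pos0 = a, pos0_alt = a + len, type = "sv", svtype = "deletion",
            ref_allele = NA, alt_allele = NA, length = len, vaf = vaf)
          regions[[length(regions) + 1L]] <-
            c(.mk_region(genome, a, a + len - 1L, ""), vaf = vaf)
        } else if (ty == "duplication") {
          seg <- substr(genome, a + 1L, a + len)
          truth[[length(truth) + 1L]] <- data.frame(
            pos0 = a + len, pos0_alt = a, type = "sv", svtype = "duplication",
            ref_allele = NA, alt_allele = NA, length = len, vaf = vaf)
          regions[[length(regions) + 1L]] <-
            c(.mk_region(genome, a + len, a + len - 1L, seg), vaf = vaf)
        } else {
          # translocation: a single junction joining locus a to a distant
          # locus c (one side of a reciprocal rearrangement); reads crossing
          # the junction continue into the distant sequence
          repeat {
            cpos <- sample.int(L - len - 2L * margin, 1L) + margin
            if (abs(cpos - a) > 5000L &&
                !any(occupied[, 1] <= cpos + len + margin &
                     occupied[, 2] >= cpos - margin)) break
          }
          occupied <- rbind(occupied, c(cpos - margin, cpos + len + margin))
          ws <- a - 600L
          mutwin <- paste0(substr(genome, ws + 1L, a + 1L),
                           substr(genome, cpos + 1L, cpos + len + 600L))
          truth[[length(truth) + 1L]] <- data.frame(
            pos0 = a + 1L, pos0_alt = cpos, type = "sv",
            svtype = "translocation", ref_allele = NA, alt_allele = NA,
            length = len, vaf = vaf)
          regions[[length(regions) + 1L]] <-
            list(ws = ws, fs = a + 1L, fe = a, mutwin = mutwin, vaf = vaf)
        }
      }
    }
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(pos0 = integer(0), pos0_alt = integer(0), type = character(0),
                 svtype = character(0), ref_allele = character(0),
                 alt_allele = character(0), length = integer(0),
                 vaf = numeric(0))
    list(truth = truth, regions = regions)
  })
}

#' Simulate paired (or single-end) reads with haplotype mixing
#'
#' Fragments are placed uniformly on the wild genome; a fragment
#' overlapping a planted variant's footprint is drawn from the local
#' mutant window with probability equal to the variant's VAF. Base errors
#' are substitutions at `error_rate`; error bases get quality Q10 and all
#' others Q30, so quality-based cleaning interacts realistically with the
#' simulated errors.
#'
#' @param genome wild-type genome string.
#' @param regions per-variant replacement windows from [plant_variants()]
#'   (use `list()` for the control library).
#' @param config a `sim_config`.
#' @param seed seed for this library (defaults to `config$seed + 2`).
#' @return list with `read_set`s `r1` and `r2` (`r2` is `NULL` for
#'   single-end).
#' @export
simulate_reads <- function(genome, regions, config,
                           seed = config$seed + 2L) {
  L <- nchar(genome)
  rl <- config$read_len
  mates <- if (config$paired) 2L else 1L
  n_frag <- round(L * config$coverage / (rl * mates))
  .with_seed(seed, {
    flen <- if (config$paired)
      pmax(2L * rl, as.integer(round(stats::rnorm(n_frag, config$fragment_mean,
                                                  config$fragment_sd))))
    else rep(rl, n_frag)
    flen <- pmin(flen, L)
    s0 <- as.integer(floor(stats::runif(n_frag) * (L - flen + 1)))  # 0-based
    frag <- substring(genome, s0 + 1L, s0 + flen)
    for (rg in regions) {
      anchor_lo <- min(rg$fs, rg$fe)
      anchor_hi <- max(rg$fs - 1L, rg$fe)
      ov <- which(s0 <= anchor_hi + 1L & s0 + flen - 1L >= anchor_lo)
      if (!length(ov)) next
      apply_idx <- ov[stats::runif(length(ov)) < rg$vaf]
      if (!length(apply_idx)) next
      mlen <- nchar(rg$mutwin)
      for (j in apply_idx) {
        m0 <- if (s0[j] < rg$fs) s0[j] - rg$ws
              else as.integer(floor(stats::runif(1) * max(1L, mlen - flen[j] + 1L)))
        m0 <- max(0L, min(m0, mlen - flen[j]))
        if (mlen >= flen[j])
          frag[j] <- substr(rg$mutwin, m0 + 1L, m0 + flen[j])
      }
    }
    r1 <- substr(frag, 1L, rl)
    ids <- sprintf("sim_%07d", seq_len(n_frag))
    if (config$paired) {
      r2 <- cpp_revcomp(substring(frag, flen - rl + 1L, flen))
      swap <- stats::runif(n_frag) < 0.5
      tmp <- r1[swap]
      r1[swap] <- r2[swap]
      r2[swap] <- tmp
    } else r2 <- NULL
    add_errors <- function(reads) {
      n <- length(reads)
      qual <- rep(strrep("?", rl), n)   # Q30
      if (config$error_rate > 0) {
        n_err <- stats::rbinom(1L, n * rl, config$error_rate)
        if (n_err > 0) {
          gi <- sample.int(n * rl, n_err)
          ri <- (gi - 1L) %/% rl + 1L
          pi <- (gi - 1L) %% rl + 1L
          for (e in seq_len(n_err)) {
            cur <- substr(reads[ri[e]], pi[e], pi[e])
            if (!cur %in% c("A", "C", "G", "T")) next
            substr(reads[ri[e]], pi[e], pi[e]) <-
              sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
            substr(qual[ri[e]], pi[e], pi[e]) <- "+"   # Q10
          }
        }
      }
      list(seq = reads, qual = qual)
    }
    e1 <- add_errors(r1)
    out <- list(r1 = read_set(paste0(ids, "/1"), e1$seq, e1$qual), r2 = NULL)
    if (config$paired) {
      e2 <- add_errors(r2)
      out$r2 <- read_set(paste0(ids, "/2"), e2$seq, e2$qual)
    }
    out
  })
}

#' Simulate a matched case/control dataset
#'
#' Generates the genome, plants variants into the case sample only, and
#' simulates both libraries. With `outdir` set, writes `genome.fa`,
#' `truth.vcf` and gzipped FASTQ files.
#'
#' @param config a `sim_config`.
#' @param outdir optional output directory.
#' @return list with `genome`, `truth`, `case` and `control` read sets,
#'   and `paths` when files were written.
#' @export
simulate_dataset <- function(config, outdir = NULL) {
  genome <- generate_genome(config$genome_len, config$seed)
  pv <- plant_variants(genome, config)
  case <- simulate_reads(genome, pv$regions, config, seed = config$seed + 2L)
  control <- simulate_reads(genome, list(), config, seed = config$seed + 3L)
  out <- list(genome = genome, truth = pv$truth, case = case,
              control = control)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    g <- Biostrings::DNAStringSet(genome)
    names(g) <- "chr1"
    paths <- list(genome = file.path(outdir, "genome.fa"),
                  truth = file.path(outdir, "truth.vcf"),
                  case = file.path(outdir, c("case_R1.fastq.gz",
                                             "case_R2.fastq.gz")),
                  control = file.path(outdir, c("control_R1.fastq.gz",
                                                "control_R2.fastq.gz")))
    Biostrings::writeXStringSet(g, paths$genome)
    write_truth_vcf(pv$truth, paths$truth)
    write_fastq(case$r1, paths$case[1])
    write_fastq(control$r1, paths$control[1])
    if (config$paired) {
      write_fastq(case$r2, paths$case[2])
      write_fastq(control$r2, paths$control[2])
    } else {
      paths$case <- paths$case[1]
      paths$control <- paths$control[1]
    }
    out$paths <- paths
  }
  out
}

#' Write a truth set as VCF
#'
#' @param truth truth data frame from [plant_variants()].
#' @param path output file.
#' @export
write_truth_vcf <- function(truth, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=kmervar-simulator",
           "##INFO=<ID=TYPE,Number=1,Type=String,Description=\"snv, ins, del or sv\">",
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"deletion, duplication or translocation\">",
           "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"Simulated variant allele frequency\">",
           "##INFO=<ID=POS2,Number=1,Type=Integer,Description=\"Second breakpoint (1-based) for junction events\">",
           "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Event length\">",
           "##ALT=<ID=SV,Description=\"Structural variant junction\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  rows <- character(0)
  if (nrow(truth)) {
    info <- sprintf("TYPE=%s;VAF=%g;SVLEN=%d", truth$type, truth$vaf,
                    truth$length)
    info <- ifelse(!is.na(truth$svtype),
                   paste0(info, ";SVTYPE=", truth$svtype), info)
    info <- ifelse(!is.na(truth$pos0_alt),
                   paste0(info, ";POS2=", truth$pos0_alt + 1L), info)
    ref <- ifelse(is.na(truth$ref_allele), "N", truth$ref_allele)
    alt <- ifelse(is.na(truth$alt_allele), "<SV>", truth$alt_allele)
    rows <- sprintf("chr1\t%d\ttruth_%04d\t%s\t%s\t.\tPASS\t%s",
                    truth$pos0 + 1L, seq_len(nrow(truth)), ref, alt, info)
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Confusion-count metrics
#'
#' `recall = TP/(TP+FN)`, `FDR = FP/(TP+FP)`,
#' `precision = TP/(TP+FP)`, `F1 = 2*precision*recall/(precision+recall)`.
#' Undefined ratios (zero denominators) are reported as 0 with
#' `degenerate = TRUE`.
#'
#' @param tp,fp,fn confusion counts.
#' @return list with `TP`, `FP`, `FN`, `recall`, `FDR`, `precision`, `F1`,
#'   `degenerate`.
#' @export
confusion_metrics <- function(tp, fp, fn) {
  degen <- (tp + fn) == 0 || (tp + fp) == 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  fdr <- if (tp + fp > 0) fp / (tp + fp) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  list(TP = tp, FP = fp, FN = fn, recall = recall, FDR = fdr,
       precision = precision, F1 = f1, degenerate = degen)
}

# category of a call / truth record for matching
.call_category <- function(var_type) {
  ifelse(var_type %in% c("mutation", "multiple_mutation"), "snv",
         ifelse(var_type == "indel", "indel", "sv"))
}
.truth_category <- function(type) {
  ifelse(type == "snv", "snv", ifelse(type %in% c("ins", "del"),
                                      "indel", "sv"))
}

#' Score calls against a truth set
#'
#' A call matches a truth record of the same category (SNV / indel / SV)
#' when the positions agree exactly (SNV) or a breakpoint lies within
#' `tolerance` bp (indel / SV, either reported breakpoint against either
#' truth breakpoint). Each truth record matches at most one call; calls
#' are consumed in decreasing Phred order.
#'
#' @param calls a `variant_calls` data frame with genome coordinates
#'   (`pos`, optionally `pos2`, 1-based), or the data frame returned by
#'   [read_vcf_calls()] on a kmervar VCF.
#' @param truth truth data frame from [plant_variants()] (0-based `pos0`),
#'   or from [read_truth_vcf()].
#' @param tolerance breakpoint tolerance in bp for indels and SVs
#'   (default 10).
#' @return list with `overall` and per-category (`snv`, `indel`, `sv`)
#'   [confusion_metrics()].
#' @export
evaluate_calls <- function(calls, truth, tolerance = 10L) {
  if (!nrow(calls)) {
    cats <- .truth_category(truth$type)
    per <- lapply(c(snv = "snv", indel = "indel", sv = "sv"), function(ct)
      confusion_metrics(0L, 0L, sum(cats == ct)))
    return(c(list(overall = confusion_metrics(0L, 0L, nrow(truth))), per))
  }
  call_cat <- .call_category(calls$var_type)
  truth_cat <- .truth_category(truth$type)
  ord <- if ("phred" %in% names(calls)) order(-as.numeric(calls$phred))
         else seq_len(nrow(calls))
  truth_used <- rep(FALSE, nrow(truth))
  call_hit <- rep(FALSE, nrow(calls))
  pos2 <- if ("pos2" %in% names(calls)) suppressWarnings(as.integer(calls$pos2))
          else rep(NA_integer_, nrow(calls))
  unm <- if ("unmapped" %in% names(calls))
    !is.na(calls$unmapped) & calls$unmapped == TRUE
  else rep(FALSE, nrow(calls))
  for (i in ord) {
    if (unm[i]) next                             # unplaced calls stay FP
    ct <- call_cat[i]
    tol <- if (ct == "snv") 0L else as.integer(tolerance)
    cand <- which(!truth_used & truth_cat == ct)
    if (!length(cand)) next
    cp <- as.integer(calls$pos[i]) - 1L          # to 0-based
    cp2 <- pos2[i] - 1L
    d <- pmin(
      abs(truth$pos0[cand] - cp),
      ifelse(is.na(truth$pos0_alt[cand]), Inf, abs(truth$pos0_alt[cand] - cp)),
      if (is.na(cp2)) Inf else abs(truth$pos0[cand] - cp2),
      if (is.na(cp2)) Inf else
        ifelse(is.na(truth$pos0_alt[cand]), Inf, abs(truth$pos0_alt[cand] - cp2)))
    j <- cand[which.min(d)]
    if (min(d) <= tol) {
      truth_used[j] <- TRUE
      call_hit[i] <- TRUE
    }
  }
  per <- lapply(c(snv = "snv", indel = "indel", sv = "sv"), function(ct) {
    tp <- sum(call_hit & call_cat == ct)
    fp <- sum(!call_hit & call_cat == ct)
    fn <- sum(!truth_used & truth_cat == ct)
    confusion_metrics(tp, fp, fn)
  })
  overall <- confusion_metrics(sum(call_hit), sum(!call_hit),
                               sum(!truth_used))
  c(list(overall = overall), per)
}

#' Read a simulator truth VCF back into a truth data frame
#'
#' @param path truth VCF written by [write_truth_vcf()].
#' @export
read_truth_vcf <- function(path) {
  df <- read_vcf_calls(path)
  if (!nrow(df))
    return(data.frame(pos0 = integer(0), pos0_alt = integer(0),
                      type = character(0), svtype = character(0),
                      vaf = numeric(0)))
  data.frame(pos0 = df$pos - 1L,
             pos0_alt = if ("POS2" %in% names(df))
               suppressWarnings(as.integer(df$POS2)) - 1L else NA_integer_,
             type = df$TYPE,
             svtype = if ("SVTYPE" %in% names(df)) df$SVTYPE else NA,
             ref_allele = df$ref, alt_allele = df$alt,
             vaf = suppressWarnings(as.numeric(df$VAF)),
             stringsAsFactors = FALSE)
}
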