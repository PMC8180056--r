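# Full workflow orchestration: clean -> count -> cs-extract -> match ->
# assemble -> infer-reference -> score -> filter -> type/export.

.stage <- function(name, log, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
  if (!is.null(log))
    cat(sprintf("[%s] stage %-16s %6.1f s\n", format(Sys.time(), "%H:%M:%S"),
                name, as.numeric(difftime(Sys.time(), t0, units = "secs"))),
        file = log, append = TRUE)
  res
}

.load_library <- function(x, label) {
  if (inherits(x, "read_set")) return(x)
  if (is.list(x) && !is.null(x$r1)) {
    r1 <- x$r1
    if (!is.null(x$r2))
      return(read_set(c(r1$id, x$r2$id), c(r1$seq, x$r2$seq),
                      c(r1$qual, x$r2$qual)))
    return(r1)
  }
  paths <- as.character(x)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop(sprintf("%s FASTQ not found: %s", label,
                 paste(missing, collapse = ", ")))
  sets <- lapply(paths, read_fastq)
  read_set(unlist(lapply(sets, `[[`, "id")),
           unlist(lapply(sets, `[[`, "seq")),
           unlist(lapply(sets, `[[`, "qual")))
}

#' Run the full variant-calling workflow
#'
#' Executes cleaning, canonical k-mer counting, cs-kmer extraction
#' (optionally panel-of-normals exclusion), Hamming-1 counterpart
#' matching, contig assembly, reference inference, Fisher scoring,
#' filtering, typing and VCF export. All stages are deterministic for
#' identical inputs and configuration; `threads` is accepted for interface
#' compatibility but the implementation is serial, which satisfies the
#' thread-invariance contract trivially.
#'
#' @param case,control case and control libraries: FASTQ path(s) (R1 or
#'   `c(R1, R2)`, optionally gzipped), a `read_set`, or a
#'   `list(r1 =, r2 =)` of `read_set`s.
#' @param outdir output directory (created). `NULL` for no files
#'   (in-memory result only).
#' @param k k-mer length (odd, default 31).
#' @param min_count abundance cutoff for both libraries (default 3).
#' @param max_control_count raw-control-count tolerance for cs-kmers
#'   (default `min_count - 1`).
#' @param min_overlap assembly minimum overlap (default 25).
#' @param min_cs,min_cov,min_af,min_phred call filters (defaults 3, 10,
#'   0.05, 5).
#' @param quality_cutoff,mask_threshold read-cleaning parameters
#'   (defaults 10, 10).
#' @param genome optional genome (FASTA path or sequence) for coordinate
#'   lift-over.
#' @param normals optional list of panel-of-normals libraries (same forms
#'   as `case`).
#' @param max_normals panel exclusion threshold (default 1).
#' @param threads accepted for compatibility; results are
#'   thread-count-invariant.
#' @param resume if `TRUE` and `outdir` contains a typed-call checkpoint
#'   (`calls_unfiltered.tsv`), restart from it (placement, filtering and
#'   export only).
#' @param two_sided use the two-sided Fisher test.
#' @return list with `calls` (all typed calls), `passing`, `rejected`,
#'   and `paths` of written files.
#' @export
run_call <- function(case, control, outdir = NULL, k = 31L, min_count = 3L,
                     max_control_count = min_count - 1L, min_overlap = 25L,
                     min_cs = 3L, min_cov = 10L, min_af = 0.05,
                     min_phred = 5, quality_cutoff = 10L,
                     mask_threshold = 10L, genome = NULL, normals = NULL,
                     max_normals = 1L, threads = 10L, resume = FALSE,
                     two_sided = FALSE) {
  log <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    log <- file.path(outdir, "run.log")
  }
  ckpt <- if (!is.null(outdir)) file.path(outdir, "calls_unfiltered.tsv")
          else ""
  if (resume && nzchar(ckpt) && file.exists(ckpt)) {
    calls <- utils::read.delim(ckpt, stringsAsFactors = FALSE)
    class(calls) <- c("variant_calls", class(calls))
  } else {
    # fail fast on missing inputs before producing any output
    case_reads <- .stage("load_case", log, .load_library(case, "case"))
    control_reads <- .stage("load_control", log,
                            .load_library(control, "control"))
    case_reads <- .stage("clean", log, {
      clean_reads(case_reads, quality_cutoff, mask_threshold)
    })
    control_reads <- clean_reads(control_reads, quality_cutoff,
                                 mask_threshold)
    case_raw <- .stage("count_case", log, count_kmers(case_reads, k))
    control_raw <- .stage("count_control", log, count_kmers(control_reads, k))
    case_filt <- filter_low_count(case_raw, min_count)
    control_filt <- filter_low_count(control_raw, min_count)
    cs <- .stage("extract_cs", log,
                 extract_cs_kmers(case_filt, control_filt, control_raw,
                                  max_control_count))
    if (!is.null(normals) && length(normals)) {
      panel <- .stage("panel_of_normals", log, lapply(normals, function(nn) {
        count_kmers(clean_reads(.load_library(nn, "normal"),
                                quality_cutoff, mask_threshold), k)
      }))
      cs <- filter_panel_of_normals(cs, panel, max_normals)
    }
    pairs <- .stage("match", log, match_counterparts(cs, control_raw))
    contigs <- .stage("assemble", log,
                      assemble_contigs(cs, min_overlap, pairs))
    contigs <- .stage("infer_reference", log,
                      infer_references(contigs, pairs, case_raw, control_raw,
                                       control_reads, min_overlap))
    contigs <- .stage("score", log, score_contigs(contigs, two_sided))
    calls <- .stage("type", log, type_contigs(contigs))
    if (!is.null(outdir)) {
      write_contig_fasta(contigs, file.path(outdir, "contigs.fa"))
      utils::write.table(calls, ckpt, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
  }
  if (!is.null(genome) && nrow(calls)) {
    calls <- .stage("place", log, place_calls(calls, genome))
    calls <- .collapse_sv_calls(calls)
  }
  pass <- if (nrow(calls))
    apply_filters(calls, min_cs, min_cov, min_af, min_phred)
  else logical(0)
  passing <- calls[pass, , drop = FALSE]
  rejected <- calls[!pass, , drop = FALSE]
  paths <- NULL
  if (!is.null(outdir)) {
    paths <- list(vcf = file.path(outdir, "calls.vcf"),
                  rejected = file.path(outdir, "rejected.vcf"),
                  stats = file.path(outdir, "stats.tsv"),
                  alignments = file.path(outdir, "alignments.txt"),
                  contigs = file.path(outdir, "contigs.fa"),
                  log = log)
    .stage("export", log, {
      write_vcf(passing, paths$vcf)
      write_vcf(rejected, paths$rejected, filter_label = "FAIL")
      utils::write.table(
        calls[, setdiff(names(calls), c("mutant_seq", "ref_seq", "ref_used"))],
        paths$stats, sep = "\t", quote = FALSE, row.names = FALSE)
      write_alignments(calls, paths$alignments)
    })
  }
  list(calls = calls, passing = passing, rejected = rejected, paths = paths)
}

# one junction can seed several mutant contigs (e.g. split by an error
# k-mer); placed sv calls sharing a breakpoint within `tol` are collapsed
# onto the highest-Phred call
.collapse_sv_calls <- function(calls, tol = 10L) {
  sv <- which(calls$var_type == "sv" & !is.na(calls$pos) &
                !(!is.na(calls$unmapped) & calls$unmapped))
  if (length(sv) < 2L) return(calls)
  bps <- lapply(seq_len(nrow(calls)), function(i)
    stats::na.omit(c(calls$pos[i], calls$pos2[i])))
  kept <- integer(0)
  drop <- integer(0)
  for (i in sv[order(-calls$phred[sv])]) {
    dup <- any(vapply(kept, function(j)
      min(abs(outer(bps[[i]], bps[[j]], "-"))) <= tol, logical(1)))
    if (dup) drop <- c(drop, i) else kept <- c(kept, i)
  }
  if (length(drop)) calls[-drop, , drop = FALSE] else calls
}

#' Simulate a matched dataset (CLI backend)
#'
#' @param outdir output directory.
#' @param config_file optional flat `key=value` file overriding
#'   [sim_config()] defaults.
#' @param ... direct overrides of [sim_config()] fields.
#' @export
run_simulate <- function(outdir, config_file = NULL, ...) {
  over <- list(...)
  if (!is.null(config_file)) {
    lines <- readLines(config_file)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    kv <- strsplit(lines, "=", fixed = TRUE)
    for (x in kv) {
      key <- trimws(x[1])
      val <- trimws(x[2])
      over[[key]] <- if (key %in% c("paired")) as.logical(val)
                     else if (grepl("^[-0-9.e,]+$", val)) {
                       v <- as.numeric(strsplit(val, ",")[[1]])
                       if (length(v) > 1) v else v
                     } else val
    }
  }
  cfg <- do.call(sim_config, over)
  simulate_dataset(cfg, outdir)
}

#' Evaluate a call VCF against a truth VCF (CLI backend)
#'
#' @param calls_vcf VCF written by [run_call()].
#' @param truth_vcf truth VCF written by the simulator.
#' @param tolerance breakpoint tolerance (default 10).
#' @export
run_evaluate <- function(calls_vcf, truth_vcf, tolerance = 10L) {
  df <- read_vcf_calls(calls_vcf)
  truth <- read_truth_vcf(truth_vcf)
  if (nrow(df)) {
    calls <- data.frame(var_type = df$VTYPE, pos = df$pos,
                        pos2 = if ("POS2" %in% names(df))
                          suppressWarnings(as.integer(df$POS2))
                        else NA_integer_,
                        phred = suppressWarnings(as.numeric(df$PHRED)),
                        unmapped = if ("UNMAPPED" %in% names(df))
                          !is.na(df$UNMAPPED) else FALSE,
                        stringsAsFactors = FALSE)
  } else calls <- data.frame(var_type = character(0), pos = integer(0))
  evaluate_calls(calls, truth, tolerance)
}
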