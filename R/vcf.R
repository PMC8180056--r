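# VCF v4.2 export. Without a genome, CHROM is the contig id and POS the
# 1-based offset in the contig; with a genome, calls carry lifted
# coordinates (place_calls) and unplaceable calls keep contig coordinates
# with the UNMAPPED flag set.

.vcf_header <- function(contig_lines) {
  c("##fileformat=VCFv4.2",
    "##source=kmervar",
    contig_lines,
    "##INFO=<ID=VTYPE,Number=1,Type=String,Description=\"Variant type: mutation, multiple_mutation, indel, sv or unresolved\">",
    "##INFO=<ID=BRANCH,Number=1,Type=String,Description=\"Reference inference branch: ct_merge or read_assembly\">",
    "##INFO=<ID=CSCOUNT,Number=1,Type=Integer,Description=\"Median case count of contig cs-kmers\">",
    "##INFO=<ID=COV,Number=1,Type=Integer,Description=\"Case coverage (cs-count plus median counterpart count, or retrieved reads)\">",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Variant allele frequency cs-count/coverage\">",
    "##INFO=<ID=PHRED,Number=1,Type=Float,Description=\"-10*log10 of the one-sided Fisher exact P-value\">",
    "##INFO=<ID=CTRLCS,Number=1,Type=Integer,Description=\"Median control count of contig cs-kmers\">",
    "##INFO=<ID=CTRLCOV,Number=1,Type=Integer,Description=\"Control coverage\">",
    "##INFO=<ID=MUTCONTIG,Number=1,Type=String,Description=\"Mutant contig sequence\">",
    "##INFO=<ID=REFCONTIG,Number=1,Type=String,Description=\"Inferred reference contig sequence\">",
    "##INFO=<ID=UNMAPPED,Number=0,Type=Flag,Description=\"Could not be placed on the supplied genome\">",
    "##INFO=<ID=POS2,Number=1,Type=Integer,Description=\"Second breakpoint (1-based) for junction calls\">",
    "##ALT=<ID=SV,Description=\"Structural variant junction\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
}

#' Write calls as a VCF v4.2 file
#'
#' @param calls a `variant_calls` data frame ([type_contigs()], optionally
#'   [place_calls()]).
#' @param path output file.
#' @param genome optional genome sequence or FASTA path; when supplied and
#'   the calls are not yet placed, [place_calls()] is run first.
#' @param chrom chromosome name for placed calls.
#' @param filter_label FILTER column value (default `"PASS"`).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path, genome = NULL, chrom = NULL,
                      filter_label = "PASS") {
  if (!is.null(genome) && nrow(calls) && all(is.na(calls$pos)))
    calls <- place_calls(calls, genome, chrom)
  n <- nrow(calls)
  if (n) {
    placed <- !is.na(calls$pos) & !identical(calls$chrom, calls$contig_id)
    chrom_col <- ifelse(is.na(calls$chrom), calls$contig_id, calls$chrom)
    pos_col <- ifelse(is.na(calls$pos), calls$pos_in_contig + 1L, calls$pos)
    ref <- calls$ref_allele
    alt <- calls$alt_allele
    bad <- !grepl("^[ACGTN]+$", ref)
    ref[bad] <- "N"
    bad_alt <- !(grepl("^[ACGTN]+$", alt) | grepl("^<.+>$", alt))
    alt[bad_alt] <- "<SV>"
    info <- sprintf(
      "VTYPE=%s;BRANCH=%s;CSCOUNT=%d;COV=%d;AF=%.4f;PHRED=%.4f;CTRLCS=%d;CTRLCOV=%d;MUTCONTIG=%s;REFCONTIG=%s",
      calls$var_type, calls$branch, calls$cs_count, calls$coverage,
      calls$af, calls$phred, calls$control_cs_count, calls$control_coverage,
      calls$mutant_seq,
      ifelse(is.na(calls$ref_seq), ".", calls$ref_seq))
    info <- ifelse(!is.na(calls$pos2), paste0(info, ";POS2=", calls$pos2),
                   info)
    info <- ifelse(!is.na(calls$unmapped) & calls$unmapped,
                   paste0(info, ";UNMAPPED"), info)
    body <- data.frame(chrom = chrom_col, pos = pos_col, id = calls$contig_id,
                       ref = ref, alt = alt,
                       qual = sprintf("%.2f", calls$phred),
                       filter = filter_label, info = info)
    body <- body[order(body$chrom, body$pos), , drop = FALSE]
    contig_lines <- sprintf("##contig=<ID=%s>", unique(body$chrom))
    lines <- c(.vcf_header(contig_lines),
               sprintf("%s\t%d\t%s\t%s\t%s\t%s\t%s\t%s",
                       body$chrom, body$pos, body$id, body$ref, body$alt,
                       body$qual, body$filter, body$info))
  } else {
    lines <- .vcf_header(character(0))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a kmervar VCF back into a call table
#'
#' Lightweight reader for the files produced by [write_vcf()] (and for the
#' simulator's truth VCF); used by the `evaluate` subcommand.
#'
#' @param path VCF file.
#' @return data frame with `chrom`, `pos`, `id`, `ref`, `alt`, `qual`,
#'   `filter` and all INFO key=value fields as character columns.
#' @export
read_vcf_calls <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines))
    return(data.frame(chrom = character(0), pos = integer(0)))
  f <- strsplit(lines, "\t", fixed = TRUE)
  df <- data.frame(chrom = vapply(f, `[`, "", 1),
                   pos = as.integer(vapply(f, `[`, "", 2)),
                   id = vapply(f, `[`, "", 3),
                   ref = vapply(f, `[`, "", 4),
                   alt = vapply(f, `[`, "", 5),
                   qual = vapply(f, `[`, "", 6),
                   filter = vapply(f, `[`, "", 7),
                   stringsAsFactors = FALSE)
  info <- vapply(f, `[`, "", 8)
  kvs <- strsplit(info, ";", fixed = TRUE)
  keys <- unique(sub("=.*", "", unlist(kvs)))
  for (key in keys) {
    df[[key]] <- vapply(kvs, function(x) {
      hit <- x[startsWith(x, paste0(key, "=")) | x == key]
      if (!length(hit)) NA_character_
      else if (hit[1] == key) "TRUE"
      else sub("^[^=]*=", "", hit[1])
    }, "")
  }
  df
}

#' Write contig/reference alignments as plain text
#'
#' @param calls a `variant_calls` data frame.
#' @param path output file.
#' @export
write_alignments <- function(calls, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(calls))) {
    writeLines(sprintf(">%s type=%s", calls$contig_id[i], calls$var_type[i]),
               con)
    if (is.na(calls$ref_used[i])) {
      writeLines(c(calls$mutant_seq[i], "(no reference assembled)"), con)
    } else {
      aln <- align_contig_pair(calls$mutant_seq[i], calls$ref_used[i])
      mid <- paste(ifelse(strsplit(aln$pattern, "")[[1]] ==
                            strsplit(aln$subject, "")[[1]], "|", " "),
                   collapse = "")
      writeLines(c(aln$pattern, mid, aln$subject), con)
    }
  }
  invisible(path)
}
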