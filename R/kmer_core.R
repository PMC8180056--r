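#' Reverse complement of DNA strings
#'
#' Vectorised; `N` maps to `N`.
#' @param x character vector of DNA strings.
#' @export
revcomp_dna <- function(x) cpp_revcomp(x)

#' Canonical form of k-mers
#'
#' Returns the lexicographically smaller of each k-mer and its reverse
#' complement, so that both strands of a molecule contribute to the same
#' count. k-mers containing non-ACGT characters are rejected (windows with
#' `N` never reach canonicalisation in the counting path).
#'
#' @param x character vector of ACGT k-mers.
#' @export
canonicalize <- function(x) cpp_canonical(x)

#' Construct a k-mer count table
#'
#' @param k odd k-mer length in `[5, 31]`.
#' @param kmer character vector of canonical k-mers.
#' @param count positive integer counts.
#' @return An object of class `kmer_table` with fields `k`, `kmer`, `count`.
#' @export
kmer_table <- function(k, kmer = character(0), count = integer(0)) {
  k <- as.integer(k)
  if (k < 5L || k > 31L || k %% 2L == 0L) stop("k must be odd and in [5, 31]")
  stopifnot(length(kmer) == length(count))
  if (length(kmer)) {
    if (any(nchar(kmer) != k)) stop("all k-mers must have length k")
    if (any(count < 1L)) stop("all counts must be >= 1")
    if (any(kmer != cpp_canonical(kmer))) stop("all k-mers must be canonical")
  }
  structure(list(k = k, kmer = as.character(kmer), count = as.integer(count)),
            class = "kmer_table")
}

#' @export
length.kmer_table <- function(x) length(x$kmer)

#' @export
print.kmer_table <- function(x, ...) {
  cat("kmer_table: ", length(x), " canonical ", x$k, "-mers\n", sep = "")
  invisible(x)
}

#' Count canonical k-mers in a library
#'
#' Every length-`k` window of every read that contains no `N` (or other
#' non-ACGT character) contributes 1 to the count of its canonical form;
#' windows containing `N` contribute nothing. Counting is in-memory over
#' 2-bit encoded k-mers, which limits `k` to 31 (the default and the value
#' used throughout).
#'
#' @param reads a `read_set`, or a character vector of sequences.
#' @param k odd k-mer length in `[5, 31]` (default 31).
#' @return A `kmer_table`, sorted by encoded k-mer for determinism.
#' @export
count_kmers <- function(reads, k = 31L) {
  seqs <- if (inherits(reads, "read_set")) reads$seq else as.character(reads)
  res <- cpp_count_kmers(seqs, as.integer(k))
  kmer_table(k, res$kmer, res$count)
}

#' Remove low-abundance k-mers
#'
#' Retains exactly the k-mers with `count >= min_count`. Low-abundance
#' k-mers are assumed to stem from sequencing errors (or off-target capture
#' in exome data).
#'
#' @param table a `kmer_table`.
#' @param min_count abundance cutoff (default 3); k-mers with counts
#'   strictly below it are removed.
#' @export
filter_low_count <- function(table, min_count = 3L) {
  stopifnot(inherits(table, "kmer_table"), min_count >= 1)
  keep <- table$count >= min_count
  kmer_table(table$k, table$kmer[keep], table$count[keep])
}

#' Extract case-specific k-mers
#'
#' A cs-kmer is present in the abundance-filtered case table, absent from
#' the abundance-filtered control table, and has a raw (unfiltered) control
#' count of at most `max_control_count`. The raw-count guard reproduces the
#' behaviour of taking the set difference against a filtered control list
#' while exposing the implied contamination tolerance as a parameter.
#'
#' @param case_filtered,control_filtered abundance-filtered `kmer_table`s.
#' @param control_raw the unfiltered control `kmer_table`.
#' @param max_control_count maximum tolerated raw control count (default 2,
#'   i.e. the default `min_count - 1`).
#' @return An object of class `cs_kmer_set` with fields `k`, `kmer`,
#'   `case_count`, `control_raw`.
#' @export
extract_cs_kmers <- function(case_filtered, control_filtered, control_raw,
                             max_control_count = 2L) {
  stopifnot(inherits(case_filtered, "kmer_table"),
            inherits(control_filtered, "kmer_table"),
            inherits(control_raw, "kmer_table"))
  if (case_filtered$k != control_filtered$k || case_filtered$k != control_raw$k)
    stop("all tables must be built with the same k")
  res <- cpp_extract_cs(case_filtered$kmer, case_filtered$count,
                        control_filtered$kmer,
                        control_raw$kmer, control_raw$count,
                        case_filtered$k, as.integer(max_control_count))
  cs_kmer_set(case_filtered$k, res$kmer, res$case_count, res$control_raw)
}

#' @rdname extract_cs_kmers
#' @param k,kmer,case_count,control_raw fields, see above.
#' @export
cs_kmer_set <- function(k, kmer, case_count, control_raw) {
  stopifnot(length(kmer) == length(case_count),
            length(kmer) == length(control_raw))
  structure(list(k = as.integer(k), kmer = as.character(kmer),
                 case_count = as.integer(case_count),
                 control_raw = as.integer(control_raw)),
            class = "cs_kmer_set")
}

#' @export
length.cs_kmer_set <- function(x) length(x$kmer)

#' @export
print.cs_kmer_set <- function(x, ...) {
  cat("cs_kmer_set: ", length(x), " case-specific ", x$k, "-mers\n", sep = "")
  invisible(x)
}

#' Exclude k-mers recurring across a panel of normals
#'
#' Removes cs-kmers present (count >= 1) in strictly more than
#' `max_normals` of the supplied normal-library tables; with the default
#' `max_normals = 1` this drops any k-mer seen in at least two normals,
#' the usual germline/artifact exclusion rule.
#'
#' @param cs a `cs_kmer_set`.
#' @param normal_tables list of `kmer_table`s from unrelated normals.
#' @param max_normals maximum tolerated number of normals containing the
#'   k-mer (default 1).
#' @export
filter_panel_of_normals <- function(cs, normal_tables, max_normals = 1L) {
  stopifnot(inherits(cs, "cs_kmer_set"))
  if (!length(normal_tables) || !length(cs)) return(cs)
  hits <- integer(length(cs))
  for (tab in normal_tables) {
    stopifnot(inherits(tab, "kmer_table"))
    if (tab$k != cs$k) stop("panel tables must share k with the cs-kmer set")
    hits <- hits + as.integer(cpp_in_table(tab$kmer, cs$kmer, cs$k))
  }
  keep <- hits <= max_normals
  cs_kmer_set(cs$k, cs$kmer[keep], cs$case_count[keep], cs$control_raw[keep])
}

#' Dump a k-mer table as two-column TSV
#'
#' @param table a `kmer_table`.
#' @param path output file.
#' @export
write_kmer_tsv <- function(table, path) {
  utils::write.table(data.frame(kmer = table$kmer, count = table$count),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Look up canonical counts for arbitrary k-mers
#'
#' Queries are canonicalised internally; absent k-mers return 0.
#' @param table a `kmer_table`.
#' @param kmers character vector of k-mers (any orientation).
#' @keywords internal
lookup_counts <- function(table, kmers) {
  if (!length(kmers)) return(integer(0))
  cpp_lookup_counts(table$kmer, table$count, kmers, table$k)
}
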