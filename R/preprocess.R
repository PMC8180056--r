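#' Construct a read set
#'
#' A `read_set` is the package's in-memory container for one sequencing
#' library: parallel character vectors of read identifiers, base strings
#' over `{A,C,G,T,N}` and Phred+33-encoded quality strings.
#'
#' @param id character vector of read identifiers.
#' @param seq character vector of base strings.
#' @param qual character vector of Phred+33 quality strings, same lengths
#'   as `seq`.
#' @return An object of class `read_set`.
#' @export
read_set <- function(id, seq, qual) {
  stopifnot(length(id) == length(seq), length(seq) == length(qual))
  if (length(seq) && any(nchar(seq) != nchar(qual)))
    stop("bases and qualities must have equal length for every read")
  structure(list(id = as.character(id), seq = as.character(seq),
                 qual = as.character(qual)),
            class = "read_set")
}

#' @export
length.read_set <- function(x) length(x$seq)

#' @export
print.read_set <- function(x, ...) {
  cat("read_set with", length(x), "reads\n")
  invisible(x)
}

#' Convert integer Phred scores to a Phred+33 string (and back)
#'
#' @param q integer vector of Phred scores in `[0, 93]`.
#' @return `phred_to_qual()` returns a single quality string;
#'   `qual_to_phred()` returns an integer vector.
#' @export
phred_to_qual <- function(q) {
  stopifnot(all(q >= 0 & q <= 93))
  intToUtf8(q + 33L)
}

#' @rdname phred_to_qual
#' @param s a Phred+33 quality string.
#' @export
qual_to_phred <- function(s) {
  if (!nchar(s)) return(integer(0))
  utf8ToInt(s) - 33L
}

#' Read / write FASTQ
#'
#' Thin wrappers around [Biostrings::readDNAStringSet()] /
#' [Biostrings::writeXStringSet()] producing and consuming `read_set`
#' objects. Gzipped files are handled transparently. The quality encoding
#' is fixed to Phred+33; scores above 93 (which would indicate Phred+64
#' input) are rejected.
#'
#' @param path FASTQ file, plain or gzipped.
#' @return A `read_set`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  qual <- as.character(S4Vectors::mcols(x)$qualities)
  seqs <- as.character(x)
  if (length(qual)) {
    mx <- max(vapply(qual, function(s) if (nchar(s)) max(utf8ToInt(s)) else 33L,
                     integer(1)))
    if (mx - 33L > 93L)
      stop("quality scores exceed Phred+33 range; Phred+64 input is not supported")
  }
  read_set(names(x), seqs, qual)
}

#' @rdname read_fastq
#' @param reads a `read_set`.
#' @param compress write gzip output (also implied by a `.gz` path).
#' @export
write_fastq <- function(reads, path, compress = grepl("\\.gz$", path)) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  q <- Biostrings::BStringSet(reads$qual)
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q,
                              compress = compress)
  invisible(path)
}

#' Quality-trim read ends
#'
#' Trims the 3' end of each read with the BWA-style running-sum rule: the
#' read is cut at the suffix start that maximises the accumulated sum of
#' `cutoff - q` taken from the 3' end (ties keep more bases). With
#' `five_prime = TRUE` the mirrored rule is applied to the 5' end first.
#'
#' @param reads a `read_set`.
#' @param cutoff Phred cutoff (default 10).
#' @param five_prime also trim the 5' end (default `FALSE`).
#' @return A trimmed `read_set` (ids preserved; reads may become empty).
#' @export
trim_quality_ends <- function(reads, cutoff = 10L, five_prime = FALSE) {
  stopifnot(cutoff >= 0)
  out <- cpp_trim_quality(reads$seq, reads$qual, as.integer(cutoff), five_prime)
  read_set(reads$id, out$seq, out$qual)
}

#' Mask low-quality bases as N
#'
#' Every base whose Phred score is strictly below `threshold` is replaced
#' by `N`; qualities and read lengths are unchanged. Masked bases can never
#' enter k-mer space because k-mer windows containing `N` are discarded.
#'
#' @inheritParams trim_quality_ends
#' @param threshold Phred threshold (default 10); bases with `q < threshold`
#'   are masked.
#' @return A `read_set` with masked bases.
#' @export
override_n <- function(reads, threshold = 10L) {
  stopifnot(threshold >= 0)
  seq <- cpp_mask_low_quality(reads$seq, reads$qual, as.integer(threshold))
  read_set(reads$id, seq, reads$qual)
}

#' Clean a library: trim then mask
#'
#' Applies [trim_quality_ends()] followed by [override_n()], the standard
#' cleaning applied identically to both case and control libraries.
#'
#' @inheritParams trim_quality_ends
#' @param mask_threshold Phred threshold for N-masking (default 10).
#' @export
clean_reads <- function(reads, cutoff = 10L, mask_threshold = 10L,
                        five_prime = FALSE) {
  override_n(trim_quality_ends(reads, cutoff, five_prime), mask_threshold)
}
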