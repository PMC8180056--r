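#' One-sided Fisher exact test for case enrichment of the variant allele
#'
#' Tests the 2x2 table with rows (variant support, reference support) =
#' `(cs, cov - cs)` and columns (case, control). The one-sided P-value is
#' the hypergeometric upper tail for enrichment in the case library: only
#' case-specific variants are admissible in this design, so the one-sided
#' test is the default; a two-sided value is available behind `two_sided`.
#'
#' @param cs_case,cov_case variant-supporting count and coverage in the
#'   case library (`cov_case >= cs_case >= 0`).
#' @param cs_ctrl,cov_ctrl the same for the control library.
#' @param two_sided use the two-sided Fisher test instead.
#' @return P-value in `(0, 1]`; an all-zero table returns 1. Vectorised
#'   over the four count arguments (one-sided path).
#' @export
fisher_pvalue <- function(cs_case, cov_case, cs_ctrl, cov_ctrl,
                          two_sided = FALSE) {
  stopifnot(all(cov_case >= cs_case), all(cs_case >= 0),
            all(cov_ctrl >= cs_ctrl), all(cs_ctrl >= 0))
  if (two_sided) {
    return(mapply(function(a, na, b, nb) {
      if (na + nb == 0) return(1)
      stats::fisher.test(matrix(c(a, na - a, b, nb - b), 2,
                                byrow = TRUE))$p.value
    }, cs_case, cov_case, cs_ctrl, cov_ctrl))
  }
  # upper tail P(X >= cs_case), X ~ Hypergeometric drawing cov_case from
  # cs_case+cs_ctrl variant and (cov_case-cs_case)+(cov_ctrl-cs_ctrl)
  # reference observations
  p <- stats::phyper(cs_case - 1, cs_case + cs_ctrl,
                     (cov_case - cs_case) + (cov_ctrl - cs_ctrl),
                     cov_case, lower.tail = FALSE)
  pmin(pmax(p, 0), 1)
}

#' Phred quality from a P-value
#'
#' `-10 * log10(p)`, with `p` floored at 1e-300 so the score is capped at
#' 3000.
#' @param p P-values in `(0, 1]`.
#' @export
phred_score <- function(p) {
  stopifnot(all(p <= 1))
  -10 * log10(pmax(p, 1e-300))
}

#' Default variant filters
#'
#' A call passes when `cs_count >= min_cs`, `coverage >= min_cov`,
#' `af >= min_af` and `phred >= min_phred` (all inclusive). Defaults are
#' 3, 10, 0.05 and 5.
#'
#' @param stats a data frame or list with numeric fields `cs_count`,
#'   `coverage`, `af`, `phred` (vectorised).
#' @param min_cs,min_cov,min_af,min_phred inclusive thresholds.
#' @return logical vector, `TRUE` for calls that pass.
#' @export
apply_filters <- function(stats, min_cs = 3L, min_cov = 10L,
                          min_af = 0.05, min_phred = 5) {
  stats$cs_count >= min_cs & stats$coverage >= min_cov &
    stats$af >= min_af & stats$phred >= min_phred
}

#' Score contigs with allele frequency, Fisher P and Phred
#'
#' Adds `af` (case `cs_count / coverage`, 0 when coverage is 0), `p_value`
#' and `phred` to every contig in a `contig_set` that already carries
#' k-mer statistics (see [infer_references()]).
#'
#' @param contigs a `contig_set` after [infer_references()].
#' @param two_sided passed to [fisher_pvalue()].
#' @export
score_contigs <- function(contigs, two_sided = FALSE) {
  for (i in seq_along(contigs)) {
    ctg <- contigs[[i]]
    ctg$af <- if (ctg$coverage_case > 0) ctg$cs_count_case / ctg$coverage_case else 0
    ctg$p_value <- fisher_pvalue(ctg$cs_count_case, ctg$coverage_case,
                                 ctg$cs_count_control, ctg$coverage_control,
                                 two_sided = two_sided)
    ctg$phred <- phred_score(ctg$p_value)
    contigs[[i]] <- ctg
  }
  contigs
}
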