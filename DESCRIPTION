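Package: kmervar
Title: Mapping-Free Somatic Variant Calling from Matched Samples via
    Case-Specific k-mers
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects case-specific variants (point mutations, small indels
    and structural variant junctions) directly from raw reads of two matched
    DNA-seq libraries (case/tumour versus control/normal), without aligning
    to a reference genome. Reads are quality-cleaned, canonical k-mers are
    counted per library, and k-mers private to the case library (cs-kmers)
    are paired with their Hamming-distance-1 wild-type counterparts from the
    control library via a split-key bucket search. cs-kmers are assembled
    into mutant contigs, a putative reference contig is inferred per mutant
    contig (from counterpart k-mers, or from locally assembled control
    reads), and each contig pair is scored with a one-sided Fisher exact
    test, typed by global pairwise alignment, filtered and exported as VCF.
    Includes a matched tumour/normal read simulator with planted SNVs,
    indels and structural variants, and a truth-based evaluator reporting
    recall, FDR, precision and F1.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    S4Vectors,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    BiocGenerics,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
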