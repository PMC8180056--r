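# kmervar

Mapping-free somatic variant calling from two matched DNA-seq libraries.

## The problem

Standard variant callers align reads to a reference genome and then compare
tumour and normal pileups. Alignment fails exactly where many interesting
variants live: repetitive or low-mappability regions, loci diverged from the
reference, and novel junctions created by structural rearrangement. `kmervar`
takes the opposite route: it never maps a read. Given a **case** library
(tumour / mutant) and a matched **control** library (normal / wild-type), it
detects sequences private to the case sample directly in k-mer space and
reconstructs, for each one, both the mutant sequence and its wild-type
counterpart — so point mutations, small indels and structural-variant
junctions are called with no reference genome at all (a genome FASTA may
optionally be supplied purely to lift calls onto coordinates).

## The method

1. **Cleaning.** Reads are 3'-quality-trimmed (BWA-style running-sum rule,
   cutoff Q10) and every remaining base below Q10 is masked to `N`, so
   low-quality bases can never enter k-mer space.
2. **Counting.** Canonical 31-mers (lexicographic minimum of a k-mer and its
   reverse complement) are counted per library; k-mers with count < 3 are
   dropped as likely sequencing errors.
3. **cs-kmers.** K-mers present in the filtered case table, absent from the
   filtered control table and with raw control count ≤ 2 are *case-specific
   k-mers*. An optional panel of normals removes any k-mer seen in ≥ 2
   unrelated normals.
4. **Counterpart matching.** Each cs-kmer is paired with a control k-mer at
   Hamming distance exactly 1 (its wild-type counterpart, *ct-kmer*) using a
   split-key bucket index: the 15-base prefix and suffix of every cs-kmer
   (both orientations) key buckets of candidate k-mers. A single substitution
   cannot destroy both end keys, so the bucket search provably finds every
   Hamming-1 pair.
5. **Assembly.** cs-kmers are merged into mutant contigs by iterative
   unambiguous overlap, with the overlap length decreasing from 30 to 25.
6. **Reference inference.** A contig with > 50% matched members gets its
   reference by merging the ct-kmers; otherwise control reads within one
   mismatch of any member k-mer are retrieved and assembled by greedy
   overlap consensus. Per-contig support is summarised as
   `cs-count` (median cs-kmer count) and `coverage` (cs-count + median
   ct-kmer count, or retrieved-read count).
7. **Scoring and filtering.** Each contig/reference pair is scored with a
   one-sided Fisher exact test on the 2×2 table
   (variant support, reference support) × (case, control); the Phred quality
   is `-10·log10(P)`. Default filters: cs-count ≥ 3, coverage ≥ 10,
   allele frequency ≥ 0.05, Phred ≥ 5.
8. **Typing and export.** Mutant and reference contigs are globally aligned
   (match +2, mismatch −1, gap open −2, extend −0.5) and classified as
   `mutation`, `multiple_mutation`, `indel` (net gap 1–49) or `sv`
   (junction evidence or gap ≥ 50 bp); calls are exported as VCF v4.2.

A matched-sample simulator (`simulate` subcommand) plants SNVs, 1–10 bp
indels and > 50 bp structural variants (deletions, tandem duplications,
translocation junctions) at configurable VAF into a synthetic genome and
generates paired reads; `evaluate` scores a call VCF against the truth VCF
(recall, FDR, precision, F1).

## Worked example

Simulate a 50 kb tumour/normal pair at 50× with 10 planted variants, call,
and evaluate (this is the code in `?run_call`, runs in ~20 s):

```r
library(kmervar)
cfg <- sim_config(genome_len = 50000, seed = 42, coverage = 50,
                  sv_events = default_sv_events(3))
sim <- simulate_dataset(cfg, outdir = "sim")
res <- run_call(case    = file.path("sim", c("case_R1.fastq.gz", "case_R2.fastq.gz")),
                control = file.path("sim", c("control_R1.fastq.gz", "control_R2.fastq.gz")),
                outdir = "out", genome = "sim/genome.fa")
res$passing[, c("contig_id", "var_type", "pos", "cs_count", "coverage", "af", "phred")]
```

```
    contig_id var_type   pos cs_count coverage        af      phred
 contig_00001       sv 31987       25       33 0.7575758 171.928286
 contig_00002       sv  8453       21       61 0.3442623  82.305270
 contig_00003 mutation 42285       14       32 0.4375000  46.790064
 contig_00004    indel 27006       13       25 0.5200000  75.481904
 contig_00005       sv 25002        8       38 0.2105263  39.878025
 contig_00006 mutation  2880        7       36 0.1944444  24.595147
 ...
```

Each row is one mutant contig: `cs_count` case reads supporting the variant
allele (median member k-mer count), `coverage` support for both alleles,
`af = cs_count/coverage` the variant allele frequency, and `phred` the
Fisher-test quality. The planted truth here was 6 SNVs, 1 insertion and
3 SVs — all ten pass the default filters with the right type, e.g. the VCF
record for the weakest SNV call:

```
chr1  1611  contig_00010  C  A  9.03  PASS  VTYPE=mutation;BRANCH=ct_merge;CSCOUNT=3;COV=40;AF=0.0750;...
```

Scoring against the truth (`run_evaluate("out/calls.vcf", "sim/truth.vcf")`
or the `evaluate` CLI subcommand) prints recall/FDR/precision/F1 per
category.

The same workflow is scriptable from the shell via `exec/kmervar`:

```sh
kmervar simulate -o sim --seed 42 --genome-len 50000
kmervar call --case sim/case_R1.fastq.gz,sim/case_R2.fastq.gz \
             --control sim/control_R1.fastq.gz,sim/control_R2.fastq.gz \
             --genome sim/genome.fa -o out
kmervar evaluate --calls out/calls.vcf --truth sim/truth.vcf
```

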