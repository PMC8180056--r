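---
title: "kmervar: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{kmervar: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`kmervar` calls variants private to a *case* DNA-seq library relative to a
matched *control* library without aligning reads to a reference. The object
of inference is a pair of local sequences per event: a **mutant contig**
(the variant plus its sequence context, assembled from case-specific
k-mers) and a **reference contig** (the wild-type counterpart, inferred
from the control library). All statistics are computed on k-mer or read
counts; a genome, when supplied, is used only to translate finished calls
into coordinates.

The causal chain behind the method: a germline-identical locus yields the
same k-mers in both libraries; a somatic substitution creates a run of up
to *k* novel k-mers in the case library, each at Hamming distance exactly 1
from its wild-type counterpart; indels and junctions create novel k-mers
with *no* Hamming-1 counterpart. This trichotomy drives the pipeline:
case-specific k-mers are extracted by set difference, substitutions are
recognised by counterpart matching, everything else is routed to a
read-based reference reconstruction.

Assumptions worth stating explicitly:

* the control is variant-free at the loci of interest (a contaminated
  control hides true somatic variants; the `max_control_count` guard
  tolerates a bounded amount of contamination);
* coverage is high enough that true variant k-mers recur (abundance
  filtering at `min_count` removes singletons, so variants supported by
  fewer than `min_count` reads are invisible by construction);
* sequencing errors are approximately independent substitutions, so that
  error k-mers rarely recur `min_count` times at the same position and,
  when they do, are penalised by the allele-frequency and Fisher filters.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `k` | 31 | bases | k-mer size; odd so the split-key scheme is complete; 2-bit encoding caps it at 31 |
| `quality_cutoff` | 10 | Phred | 3' end trim threshold (running-sum rule) |
| `mask_threshold` | 10 | Phred | internal bases below this become `N` and never enter k-mer space |
| `min_count` | 3 | count | abundance cutoff per library; errors mostly occur once or twice |
| `max_control_count` | `min_count - 1` | count | raw control count tolerated for a cs-kmer; the knob for control contamination |
| `min_overlap` | 25 | bases | smallest merge overlap in contig assembly (overlap sweeps 30 → 25 at k = 31) |
| `min_read_overlap` | 30 | bases | exact suffix–prefix overlap for control-read consensus assembly |
| `min_cs`, `min_cov`, `min_af`, `min_phred` | 3, 10, 0.05, 5 | counts / fraction / Phred | inclusive call filters |
| `max_normals` | 1 | libraries | panel-of-normals tolerance: k-mers in ≥ 2 normals are excluded |

## Numerical and algorithmic choices

**Quality trimming.** The cleaning step names a parameter, not an
algorithm; we adopt the BWA-style rule: cut at the 3' position maximising
the running sum of `cutoff − q` accumulated from the read end, ties keeping
more bases. 5' trimming is available behind a flag (`five_prime`) but off
by default. Quality encoding is fixed to Phred+33; Phred+64 input is
rejected rather than guessed.

**Counterpart search.** Keys are the `(k−1)/2`-base prefix and suffix of
each cs-kmer in both orientations; control k-mers (both orientations)
sharing a key join the bucket. Because one substitution cannot hit both
end keys, every Hamming-1 pair shares a bucket — the completeness the test
suite verifies against an all-pairs oracle, including reverse-complemented
counterparts. When several counterparts exist the one with the highest
control count wins (the likeliest wild-type allele); ties break to the
lexicographically smallest counterpart so results are order-free. Both an
R reference implementation (`build_key_index` + `find_pairs`) and the C++
production path (`match_counterparts`) exist and are asserted equivalent.

**Assembly determinism.** Merging is attempted at overlap length L from
k−1 down to `min_overlap`; a merge requires a unique candidate extension
*and* a unique incoming sequence at that L, otherwise the end is left
unextended (ambiguity rule). Contigs are processed in descending
best-member-count order with lexicographic tie-breaks, so output is
invariant under input permutation. Merging is orientation-aware — canonical
k-mers from one locus arrive in mixed orientations — which means a contig
is only defined up to reverse complement; placement re-orients calls to
the genome's forward strand.

**Median convention.** `cs-count` and `coverage` use medians of member
k-mer counts (robust to repeat-inflated counts). For even-sized sets the
mean of the two middle values is rounded *half down* to an integer; one
convention, used everywhere, checked against a sort-based oracle.

**Read-assembly branch.** Contigs with matched fraction ≤ 0.5 (strict
"more than half" routing) get their reference from control reads within
one mismatch of any member k-mer (precomputed Hamming ≤ 1 neighbourhoods,
single pass over the control library). The greedy consensus assembler
merges the pair of sequences with the longest exact suffix–prefix overlap
≥ `min_read_overlap`, either orientation, treating `N` as a wildcard, with
per-column majority vote; three junction types per ordered pair are tested
(`a→b`, `a→rc(b)`, `rc(a)→b` — the fourth is the reverse complement of
`b→a`). Reads fed to the assembler are capped at 120 per contig (ample at
50×; the full retrieved-read count is still reported as this branch's
control coverage). A failed counterpart merge falls back to this branch so
every contig gets a reference attempt. For this branch the control-side
coverage in the Fisher table is the retrieved-read count, and the case
coverage falls back to k-mer statistics — an interpretation the source
text leaves open, flagged here.

**Fisher test.** One-sided (case enrichment), because only case-specific
variants are admissible in this design; a two-sided option exists behind a
flag. The 2×2 table is (variant support, reference support) × (case,
control); the implementation uses the hypergeometric tail
(`stats::phyper`), and the tests compare it against an independent
log-factorial enumeration on every table with coverages up to 60
(relative error < 1e-9). The all-zero table returns P = 1; Phred scores
cap at 3000 by flooring P at 1e-300.

**Alignment and classification.** Mutant and reference contigs are aligned
globally with match +2, mismatch −1, gap open −2, extend −0.5 (first gap
base charged the opening penalty), implemented via
`Biostrings::pairwiseAlignment` with `gapOpening = 1.5, gapExtension =
0.5`, and checked against a brute-force Gotoh DP on short strings. The
classifier works on the alignment's *core*, delimited by the first and
last solid run of ≥ 8 identical bases: global alignment of a junction
contig against a one-flank reference otherwise scatters the foreign half
into coincidental 1–3 base matches that masquerade as internal gaps.
Decision order: internal gap run ≥ 50 → `sv`; ≥ 20 contig bases clipped
outside the core at one end → `sv`; ≥ 8 substitutions, substitution
density > 0.15, or ≥ 3 gap runs totalling ≥ 15 bases (a real 1–10 bp indel
produces one run) → `sv`; any remaining internal gap → `indel` (anchored,
left-shifted per VCF convention); one substitution → `mutation`; several →
`multiple_mutation`; an identical pair → `unresolved`. No reference
assembled → `sv` (candidate junction). The thresholds are artefact
plumbing around the one hard number in the definition — events ≥ 50 bp are
structural — and classification is invariant under reverse-complementing
both sequences (tested).

**Placement.** Point and indel calls are placed through their wild-type
reference by unique-31-mer anchor voting on both strands; junction calls
are placed by exact extension of each flank from a unique 15-mer anchor
(31-mer anchors would all cross the junction), reporting both breakpoints.
Minus-strand placements flip the call to forward orientation and re-type
it. Calls that cannot be anchored keep contig coordinates and carry the
`UNMAPPED` flag — they count as false positives in evaluation rather than
being silently dropped. Because one junction can seed two contigs, placed
`sv` calls sharing a breakpoint within 10 bp are collapsed onto the
highest-Phred call.

## What the simulator does and does not emulate

The generator reproduces the benchmark protocol this package targets: case
mutation rate 1e-4 per base against a variant-free control, 20% of small
variants drawn as 1–10 bp indels, VAF sampled from {0.1, …, 0.5} and
realised by local haplotype mixing at fragment level, 50× mean coverage
with 2×100 bp reads (insert 350 ± 30), per-base substitution errors at
1e-3 (error bases emitted at Q10, everything else Q30, so cleaning
interacts realistically with errors), and structural variants longer than
50 bp — deletions, tandem duplications, and translocations modelled as a
single junction joining two distant loci. Small-indel lengths are uniform
on 1–10 (the original protocol does not state its distribution). Planted
events are kept ≥ 150 bp apart so they stay unlinked.

It deliberately does **not** emulate: a real (repetitive, GC-biased)
genome — the synthetic genome is uniform i.i.d. sequence, which makes both
assembly and placement easier than on human data; exome capture bias;
indel or quality-profile error models; linked variants on one haplotype.
A green simulation benchmark therefore establishes the pipeline's
correctness on its own stated world and lower-bounds nothing about
repeat-rich genomes; the published human-data figures are used as lower
bounds precisely because the synthetic genome is the easier case.

## Degenerate inputs and edge behaviour

Empty reads survive cleaning as empty reads; `k` longer than every read
yields an empty table; identical case/control libraries yield zero
cs-kmers and an empty (but valid) VCF; a contig whose retrieved-read set is
empty is reported without a reference as a candidate `sv`; evaluation with
zero calls reports recall 0 with a `degenerate` flag instead of NaN.
Thread counts are accepted for interface compatibility but execution is
serial, so thread-count invariance of every output holds trivially.

## Known limitations

* Sensitivity for structural variants is bounded by junction k-mer
  support: only events with enough reads crossing a breakpoint are seen,
  and low-VAF (0.1) junctions at 50× sit near the `min_count` floor.
* A fixed `max_control_count` is a blunt instrument against control
  contamination; a probabilistic treatment is future work.
* `multiple_mutation` calls report the substituted span only; phasing of
  nearby substitutions beyond one contig is out of scope.
* Placement requires unique anchors; calls in perfectly repeated genome
  segments stay `UNMAPPED` by design.
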