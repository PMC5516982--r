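---
title: "Finishing and analysing a plant mitochondrial master circle with mitocircle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finishing and analysing a plant mitochondrial master circle with mitocircle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocircle)
```

## The problem

Plant mitochondrial genomes are conventionally reported as a single circular
sequence — the *master circle* (MC) — even though the in vivo state is
multipartite: repeat-mediated homologous recombination between large
inverted-repeat (IR) and direct-repeat (DR) pairs continuously generates
sub-genomic circles, inversions and fused forms. Assembling an MC from
whole-genome short reads therefore requires (i) separating mitochondrial
reads from chloroplast and nuclear reads, (ii) resolving the repeats that
collapse in a short-read assembly, and (iii) validating each repeat's
anchoring before committing to one circular arrangement. Downstream, the
finished circle is screened for pseudogenes, plastid-derived insertions
(MTPTs), repeats and ORFs, and RNA-seq is used to quantify transcription and
to call C→U RNA editing sites with per-site editing levels.

`mitocircle` implements this whole workflow as testable R functions, plus a
synthetic-data generator that reproduces the structural features the
analysis depends on, so every stage can be exercised end-to-end with known
truth and no downloads.

## Pipeline model

The pipeline mirrors staged organellar assembly finishing:

1. **Chloroplast subtraction** (`filter_plastid_reads`): a read is
   plastid-derived when it aligns end-to-end (100% of its length) to the
   chloroplast genome at ≥ 98% identity. A pair is discarded only when
   *both* mates match: mitochondrial fragments overlapping a genuine mt/cp
   shared insertion are almost always anchored by a mate outside the
   insertion, so they keep the benefit of the doubt. Reads wholly inside a
   shared region longer than the insert size cannot be assigned at this
   stage and are recovered later by recruitment.
2. **Coverage profiling** (`coverage_profile`): organellar and collapsed
   duplicated regions stand out as abnormal coverage peaks. A contig is
   flagged when its median depth exceeds 1.5× the baseline, taken as the
   lower-quartile per-contig median (an actual observed value): with few
   contigs, a duplicated contig inflates the plain across-contig median
   enough to hide itself. Depth is summarised over the contig interior
   because depth necessarily tapers over one read length at each contig end
   (a read must fit inside the contig to count); without this correction
   short collapsed-repeat contigs — which barely exceed the read length —
   would be systematically under-estimated. Because depth on a
   few-hundred-bp repeat is Poisson-noisy at desk scale, the pipeline
   combines the depth flag with a structural signal when assigning copy
   numbers: a collapsed repeat contig joins two different neighbours at
   each end of the overlap graph, and that degree pattern marks it
   multi-copy independently of coverage.
3. **Baiting and recruitment** (`bait_contigs`, `recruit_reads`): contigs
   carrying a local alignment to a known mitochondrial gene (identity
   ≥ 0.70, expectation value ≤ 1e−10) are retained; reads mapping
   end-to-end to a baited contig (with pair rescue) become the recruited
   mitochondrial read set.
4. **Finishing** (`find_terminal_overlaps`, `iterative_extend`,
   `build_scaffold_graph`, `validate_repeat_anchoring`,
   `select_master_circle`): contigs are joined on terminal overlaps of at
   least 100 bp at > 99% identity; mate-pair (MP) links connect contig ends
   whose reads point at each other within insert range; repeats longer
   than 300 bp must pass a three-criterion validation; the MC is the
   circular walk through the graph that visits every single-copy contig
   once and each validated repeat per its copy number, maximising total
   mate-pair support.
5. **Conformation enumeration** (`enumerate_conformations`): breadth-first
   closure of repeat-mediated recombination events over the segment model
   of the circle.
6. **Annotation screens** (`classify_pseudogene`,
   `find_plastid_insertions`, `find_repeats`, `find_orfs`,
   `category_accounting`).
7. **RNA analyses** (`filter_rna_reads`, `rpkm`, `coverage_breadth`,
   `call_editing_sites`, `validate_editing_table`).

## Read mapping

The simulator's error model is substitution-only (indels belong to the
aligner/technology layer and are out of scope), so mapping reduces to
gap-free placement. `map_reads` proposes candidate placements with exact
20-mer seeds (three per read, via `Biostrings::matchPDict`) and verifies
each candidate by direct base comparison over the full read, both strands,
with circular wrap-around handled by extending the reference. Identity is
matches over read length. With three seeds, an error-free read is always
found; at 1% error a 300 bp read is missed only when all three seeds carry
an error (well under 1%), which the recruitment tests tolerate by
construction.

## Repeat validation

A repeat longer than 300 bp is accepted only when all three criteria hold:

* **Depth**: collapsed repeat copies accumulate the reads of all copies, so
  repeat median depth must exceed `min_depth_ratio` (default 1.25) times the
  single-copy median. The default is deliberately below the theoretical 2×
  of a two-copy repeat: observed ratios in finished plant mtDNA assemblies
  run well below 2 because of baiting bias and alternative genome forms
  at unequal stoichiometry, and a strict >1 test would be a coin flip on
  single-copy noise. The threshold is configurable.
* **Anchoring**: at least 50 paired-end reads and 10 mate pairs must span
  each repeat border (20 bp on both sides for PE; fragment projection
  covering the border for MP).
* **Consensus consistency**: the junction consensus rebuilt base-by-base
  from the spanning reads must reproduce the anchored junction sequence.
  This replaces cross-checking two external assemblers with an internal
  reassembly of the same claim, removing the external-tool dependency while
  testing the same property.

## Master-circle selection

The scaffold graph has a node per contig and two kinds of edges between
contig *ends*: sequence-overlap joins and MP-link edges. MP links record
the *implied gap* between the two ends (insert mean minus the reads'
distances to the ends they point at). This matters at desk scale: when the
insert (3.5 kbp) exceeds an arc or repeat length, mate pairs legitimately
link ends that are *not* adjacent — they skip over intervening contigs. A
link therefore only corroborates a direct join when its implied gap matches
the (negative) overlap, and only supports a repeat traversal X→R→Y when its
implied gap matches R's length within 3 insert standard deviations.

Circle search is exhaustive over closed end-walks (the graphs after
collapsing repeats are small), visiting each single-copy contig once and
each repeat by copy number, each edge at most once. Overlap edges are tried
first; MP-only edges are second-class and used only when no overlap-only
circle exists, with their use reported. Ties are broken by mean overlap
identity, then by lexicographically smallest canonical sequence. When no
circle satisfies the quotas the result is an explicit `no_circle`
diagnostic with per-component candidate circles — never a silently wrong
circle. Junctions closed only by MP edges are emitted as N-runs (gap
closing is out of scope) and the N count is reported.

Because a circular genome has no defined start or strand, sequences are
compared in *canonical circular form*: the lexicographically smallest
rotation of the sequence or its reverse complement (Booth's least-rotation
algorithm).

## Conformation enumeration

The master circle is partitioned into segments at repeat-copy endpoints;
each copy becomes a shared-label segment and each inter-repeat arc a unique
segment. A conformation is a multiset of circles of oriented segments.
Recombination between two copies follows their geometry: same circle and
same orientation → excision of a sub-circle; same circle and opposite
orientation → inversion of either intervening arc (two distinct outcomes);
two circles → fusion. Circles are canonicalised by *rotation only*: strand
is preserved, so the two arc reversals of an inverted pair are distinct
states. This convention makes a one-IR, one-DR master circle reach at
least four alternative conformations within two events, consistent with
the multipartite behaviour expected of repeat-bearing plant mtDNA; merging
strands would halve the inversion states and is switchable in principle
but not the default. Crossovers are modelled as clean exchanges (repeat
divergence is ignored at this level), and stoichiometric frequencies of
the forms are explicitly not modelled.

## Annotation screens

* **Pseudogenes**: a candidate is aligned globally (within a local window
  of the reference CDS) and called a pseudogene when any of the four
  criteria triggers: in-frame internal stop, missing start and/or stop
  codon, net indel not a multiple of 3, or aligned coverage below 80% of
  the reference. "Missing at least 20% of the coding region" is encoded as
  that 0.80 coverage floor.
* **Plastid insertions and repeats**: BLASTn (the field's standard for
  these screens) at expectation value ≤ 1e−10 and identity ≥ 90%;
  self-alignment for repeats excludes the trivial diagonal and reports each
  pair once, with opposite-strand hits classified inverted. Overlapping
  insertion hits are merged before counting so no base is double-counted.
  The expectation value is computed by BLAST itself; at 90% identity the
  practical filter is identity and length.
* **ORFs**: a plain six-frame ATG→stop scanner (length includes the stop
  codon) with an 89 bp default floor, circular wrap permitted, and nested
  same-frame ORFs suppressed (first ATG after the previous stop claims the
  stop).
* **Category accounting**: bases are attributed by strict precedence
  (genes < ORFs < mitovirus < plastid-derived < repeats < TEs, the
  externally supplied tracks last), remainder intergenic; the reported
  totals sum to the genome length exactly, by construction and by test.

## RNA editing

Stage 1 keeps reads with an end-to-end match to the circular genome *or* to
a spliced gene model — reads spanning intron junctions cannot match the
genome full-length, and dropping them would censor exactly the reads that
prove splicing. Stage 2 places survivors on spliced gene models at ≥ 98%
identity with aligned fraction ≥ 0.90 (a strict mode requires full-length
placements, matching the stricter wording used for transcription evidence
of pseudogenes). Uniqueness is defined by the best placement beating every
alternative; only unique placements feed RPKM
(`counts × 10⁹ / (total × length)`) and the editing pileups.

For every CDS position whose transcript-space base is C, the editing level
is `100 × U/(U+C)` over the filtered reads; a site is reported at depth ≥ 5
and level ≥ 10%. The depth floor borrows the ≥ 5-read transcription
evidence cutoff used for ORFs; the 10% floor sits just below the smallest
printed level (11%) in the published editing table this package can
validate, so the full printed range is admissible. Minus-strand sites are
genomic G→A events reported 1-based on the genome. `annotate_edit` is a
pure function over the standard genetic code (tested exhaustively over all
48 C-containing codon/position combinations), and
`validate_editing_table` re-derives every row of a published editing table
by codon arithmetic — it flags internally inconsistent printed rows but
never alters the row counts or guesses intended values. Only CDS positions
are interrogated by default, matching the protein-coding scope of
published organellar editing tables.

## The synthetic-data generator

`genome_blueprint`/`build_genome` produce a circular genome with: a long
inverted-repeat pair and a short direct-repeat pair (exact copies by
default, divergence configurable), plastid-derived insertions copied
verbatim from a synthetic donor (so contamination and MTPT detection have
a shared-sequence substrate), about 20 protein-coding gene models on both
strands (two of them two-exon), and C→U editing sites with per-site levels.
Editing specifications are prescriptive: the builder writes a
transcript-space C at each requested position, because the backbone is
random sequence and the specification must be realisable; requesting a
site outside the spliced CDS, or simulating against an explicit genome
where the target is not a C, is an error.

Read layouts follow common organellar sequencing designs: paired-end
2×300 bp with ~600 bp inserts (inward), mate-pair 2×100 bp with ~3,500 bp
inserts (outward, the jumping-library convention; orientation is
configurable since libraries differ), and single-end ~200 bp RNA reads.
Fragment lengths are normal with a hard floor of one read length:
fragments shorter than twice the read length simply give overlapping
mates, as they do in real short-insert libraries, so the 600 ± 60 bp
distribution is not truncated at 600.
Fragments are uniform on the circle, from either strand; errors are i.i.d.
substitutions. Every simulation records per-read truth (origin, position,
strand, fragment size, spike-in source) in the `ReadSet` metadata and can
export it as TSV, so recruitment and assembly tests score against ground
truth rather than against the implementation.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: indels and quality-score structure, PCR/GC bias,
chimeric fragments, heteroplasmy and stoichiometric mixtures of genome
forms, nuclear copies of mitochondrial segments (NUMTs), and real
intron/exon structure beyond simple two-exon models. Results on real
libraries depend on an upstream trimmer and assembler that are out of
scope here (finishing starts from contigs).

## Problem sizes and numerical choices

The package's own test and acceptance runs use desk-scale genomes chosen to
preserve the structural motifs at interactive runtimes: the default
blueprint is a 100 kbp circle (IR 2.5 kbp, DR 320 bp, ~20 genes), a 10×
scale-down of a large plant mtDNA; the multi-seed master-circle recovery
property runs 20 seeds at 12 kbp (IR 1.2 kbp, DR 320 bp) with 600 mate
pairs, and editing recovery runs 20 seeds at 12 kbp with 900 RNA reads.
Editing-level recovery at a single site uses 10,000 covering reads, at
which depth the binomial standard error of an 85% level is about 0.36
percentage points. Coordinates are 1-based inclusive throughout the R API
and in GFF3 output; features spanning the circular origin are written as
two GFF3 parts sharing an ID and rejoined on read. All randomness is
seeded, and identical blueprint + seed yields byte-identical output.

## Known limitations

* The circle search is exhaustive and intended for finishing-scale graphs
  (tens of contigs after repeat collapse), not for raw assembly graphs.
* The mapper is substitution-only; real indel-bearing reads would need an
  external aligner in front of the pileup stage.
* The depth criterion of repeat validation assumes reasonably uniform
  coverage; strong coverage bias would require recalibrating
  `min_depth_ratio`.
* Editing calls outside CDS regions (tRNA/rRNA/intergenic) are out of
  scope, as is predictive (sequence-context) editing-site prediction.
* `find_repeats` totals depend on BLAST word size and masking; the package
  reports what BLASTn finds at the configured thresholds and does not
  target any particular published repeat census.
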