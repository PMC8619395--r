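---
title: "Methods: mining and comparing microsatellite landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mining and comparing microsatellite landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrsurvey)
```

## The survey model

Microsatellites (simple sequence repeats, SSRs) are perfect tandem
repeats of a 1–6 bp motif. A locus qualifies when its repeat count
reaches a per-motif-length minimum; the defaults — 6 repeats for
mononucleotides and 3 for di- through hexanucleotides — are the settings
commonly used for small prokaryote genomes, where longer thresholds
would leave too few loci for comparison. Compound microsatellites
(CSSRs) are maximal chains of two or more SSRs in which every
interruption between consecutive members is at most `dmax` bp
(default 10, tested inclusively). The per-genome summary couples counts
(`nSSR`, `nCSSR`, and the compound-member count `ncSSR`) with
size-normalized measures:

* relative abundance `RA = count / kb`,
* relative density `RD = repeat bp / kb`,
* compound share `cSSR% = 100 · ncSSR / nSSR`.

Compound representation across a panel is scored by the Z index. With
panel mean complexity

$$\bar C = \frac{1}{n}\sum_{i=1}^{n} \frac{ncSSR_i}{nCSSR_i},$$

a genome's expected CSSR count is $nCSSR_{exp} = ncSSR_i/\bar C$ and

$$Z = \frac{nCSSR_{obs} - nCSSR_{exp}}{\sqrt{nCSSR_{exp}}}.$$

Z is positive when the genome's compound-member SSRs coalesce into more
(hence smaller) compound loci than the panel average predicts, negative
when they concentrate into fewer, more complex ones. $\bar C$ is carried
at full numerical precision throughout; we verified on the bundled
46-genome fixture that the published Z column is reproducible only under
full precision (rounding $\bar C$ to three decimals first changes 14 of
46 values in the second decimal place). Tables report two decimals
(three for $\bar C$), computation is never rounded internally.

## Scanning rules

The scanner is deterministic. Candidates are maximal runs: the base
before the start and the first full unit after the end would break the
periodicity, and a partial trailing unit is never counted (perfect
repeats only). At a given start position, motif lengths are tried in
ascending order and the first qualifying length wins, so a run of six A
is always `(A)6` and never `(AA)3`; scanning resumes after the accepted
record, which guarantees non-overlap. Motifs must be primitive (`"ACAC"`
is not a motif). `N` breaks every run, so no record ever spans a contig
join or an assembly gap; other IUPAC ambiguity codes are mapped to `N`
with a warning rather than rejected, and soft-masking (lowercase) is
ignored since repeat masking would otherwise hide exactly the loci this
survey counts.

Motif classes merge a motif with its rotations and the rotations of its
reverse complement; the representative is the lexicographic minimum, so
mononucleotide classes are `A` and `C`, and e.g. `GA`, `TC` and `CT` all
report as `AG`. This makes cross-genome abundance comparisons
orientation-independent. Compound motif strings (`"CCG-AG-A"`) use the
standardized member motifs for the same reason; the uniqueness
comparison between genomes is therefore also orientation-independent,
which we consider the only defensible convention even though raw-motif
comparison would inflate unique counts.

Two open conventions had to be fixed:

* **Nested periodicities.** Ascending motif-length precedence at each
  start position is our fixed tie-break; it is the convention under
  which a homopolymer is a mononucleotide run, and it makes the scan
  provably deterministic.
* **Same-motif neighbours.** Two `(A)6` runs 3 bp apart chain into a
  compound locus by default — no motif-distinctness condition is imposed
  — because an interrupted homogeneous repeat is still a compound
  structure operationally. `build_cssrs(..., chain_same_motif = FALSE)`
  exposes the opposite convention.

## Coding classification

Coding regions are CDS features of the GFF3 annotation, both strands
pooled and overlapping features merged (`GenomicRanges::reduce`), so
overlapping genes simply produce one merged interval. Gene or mRNA
spans are deliberately not used: untranslated stretches inside genes
count as non-coding. A locus straddling a CDS boundary is coding under
the default `"any"` rule (≥ 1 bp of overlap); the `"majority"` rule
(strictly more than half the locus covered) is available because no
single convention for boundary-straddling loci is universal. The GFF3
reader is intentionally tolerant — malformed lines are skipped with a
warning and an annotation without CDS features classifies everything
non-coding with a warning — so a draft annotation degrades a survey
instead of aborting it.

## The synthetic validation genomes

`generate_synthetic()` produces contigs in which every repeat locus is
planted at a known coordinate, so the miner, the chainer and the
annotation mapper can be validated for exact recovery with zero false
positives. Defaults emulate the conditions of cyanobacterial panel
surveys: background GC 52% (panels span roughly 46–59%), about 2.9
planted SSRs per kb (panels span about 2.0–3.3), a motif spectrum
dominated by mono- and dinucleotides, compound chains of complexity 2–3,
CDS covering 75% of the sequence, and 20 bp minimum spacers (kept above
`dmax` so planted singletons never chain with neighbours).

Spacers are drawn from the background base distribution and then
*repaired*: the spacer, flanked by 17 bp of its real neighbours, is
mined with the survey policy, and any window that forms a qualifying run
or extends a planted element is resampled until none remains. The 17 bp
flank is sufficient because a qualifying run that touches at least one
spacer base can extend at most 17 bp into a neighbouring element (the
longest minimal qualifying run is a hexanucleotide triplet, 18 bp).
Chain interruption strings are rejection-sampled the same way and each
chain is re-mined in isolation before use; a chain whose members merge
at every draw (e.g. a gap-0 junction between compatible motifs) is
reported as infeasible rather than silently altered. As a final guard
the generator mines its own output and refuses to return if recovery is
not exact. Generation is fully determined by the seed.

What the generator does *not* emulate: real gene models and codon usage,
mutation-driven imperfect repeats, repeat-density clustering along the
replichore, and genome-scale contigs (tests use 10–60 kb contigs; the
scanner itself handles Mb-scale contigs in a few seconds). Recovery
tests therefore demonstrate correctness of the algorithms under the
stated densities, not biological realism of the sequence background.

## Numerical and degenerate-input choices

* GC content excludes `N` from numerator and denominator; an all-`N`
  sequence is an error, not 0%.
* The RA/RD denominator is the full assembly length including `N`
  (surveys normalize by reported genome size); `include_n_in_size =
  FALSE` switches to unambiguous length only.
* A genome without CSSRs is excluded from $\bar C$ with a warning and
  gets `NA` for Z rather than a fabricated value.
* Pearson correlations use the two-sided t test on $n-2$ degrees of
  freedom with significance flagged at 0.05 and 0.01 and no
  multiple-testing correction, matching how such survey tables are
  presented; a constant column is an error for the statistics function,
  and the pipeline driver downgrades it to a warning and omits the
  correlation report.
* Empty sequences, plant-free synthetic specs and annotation-free
  genomes all produce empty-but-well-formed results, never errors.

## Validation design and problem sizes

The test suite validates every stage against an independent oracle
rather than against itself: a character-by-character brute-force scanner
(record-identical agreement on 200 random sequences up to 5 kb at three
GC levels), exhaustive rotation/reverse-complement enumeration for motif
classes up to length 4, naive pairwise set comparison for unique motifs,
per-base membership for coding classification, and a textbook two-pass
formula for correlations. Recovery tests plant 580 SSRs and 56 chains
across four 60 kb contigs and require exact coordinates with zero false
positives. The statistics stage is additionally validated against a
bundled transcription of a published 46-genome survey table: recomputing
from its raw integer columns reproduces the printed derived columns to
their printed precision ($\bar C$ = 2.069, the full Z column to two
decimals, and the four headline correlations 0.81, −0.30, 0.52, 0.89).
One printed RA cell in that table is inconsistent with its own integer
columns (row S20: 15,873 loci in 7.87 Mb is 2.02/kb, printed 2.09) and
is excluded from the comparison.

## Known limitations

Only perfect repeats are mined; imperfect or approximate repeats and
motifs above 6 bp are out of scope. Frame-aware analysis of triplet
repeats inside CDS and strand-specific reporting are not provided.
Polymorphism scoring and primer design around compound loci are outside
the package's purpose.
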