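---
title: "Methods: genome-streamlining metrics, intron evolution and family dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome-streamlining metrics, intron evolution and family dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(streamgenome)
```

`streamgenome` quantifies how far a genome has been streamlined: how much
of the assembly is still coding, how many introns survive and where, how
gene families have contracted, whether foreign genes have been acquired,
and how much of the assembly is repeat-derived. This vignette documents
the models, conventions and numerical choices; everything stated here is
computed by the test suite or the examples, nothing is quoted from
external results.

## Genome architecture

**Model.** Every assembly base receives exactly one of three labels with
priority *coding > intronic > intergenic*. Coding bases are those covered
by the merged union of CDS segments of each gene's representative
(longest-CDS) isoform, irrespective of strand, so overlapping genes are
never double-counted. Bases inside a gene span (minimum CDS start to
maximum CDS end of the representative) but outside the CDS union are
intronic. Everything else — including scaffold-terminal stretches — is
intergenic. A gene nested inside another gene's intron therefore
contributes its CDS as coding while the remaining host-intron bases stay
intronic. The three counts sum to the assembly length exactly, by
construction, and the implementation (interval arithmetic on `IRanges`)
is tested against a per-base brute-force labeler on 50 seeded synthetic
genomes.

**Conventions that the data forced us to fix.**

* Coordinates are GFF3 1-based inclusive; every length is
  `end − start + 1`.
* Isoform length is summed CDS bp, not protein length; ties go to the
  lexicographically smallest transcript id, making selection
  order-independent.
* The GFF3 phase column is ignored; intron phase is recomputed from CDS
  lengths. Annotations differ wildly in phase-column reliability, the
  arithmetic does not.
* UTR introns are ignored: untranslated-region predictions are too
  unreliable across annotations, so only gaps between CDS segments of
  the representative isoform count as introns.
* Book-ended coding intervals merge; there are no zero-length intergenic
  slivers.
* Gene spans use CDS extent, not the `gene` feature's coordinates.
* Scaffold-terminal regions count as intergenic in the partition (the
  three fractions must sum to 100%) but are excluded from the
  intergenic-gap median; overlapping adjacent genes contribute a clamped
  gap of 0 (configurable to exclude instead).
* Median of an even-count multiset is the mean of the two central
  values (`stats::median`); an alternative lower-median convention would
  only matter for even counts and is not exposed.
* A CDS feature directly under a `gene` (no mRNA level) is accepted as an
  implicit single transcript — a common GFF3 dialect. A CDS strand of
  `.`/`?` is an error: positional statistics are undefined without it.

**Intron position.** An intron after `c` coding nucleotides (counted in
transcription direction; minus-strand transcripts are traversed from the
genomically rightmost segment) has phase `p = c mod 3` and relative
position `r = c / L` for coding length `L`, with `0 < c < L`. The
`relative_intron_positions()` histogram and `fraction_5prime_half`
(`r < 0.5`) summarize 5' bias; under uniform placement the fraction is
0.5 in expectation, and 3'-biased intron loss (as predicted by
reverse-transcriptase-mediated loss) pushes it up.

## Intron sites in alignments and Dollo parsimony

**Coordinate convention.** Protein coordinates derive from `c`:
`s = floor(c / 3)` is the 0-based residue index; a phase-0 intron sits
before residue `s`, a phase-1/2 intron interrupts residue `s`'s codon.
A site in an aligned orthogroup is the pair *(alignment column of
residue `s`, phase)* — a phase-0 and a phase-1 intron in the same column
are different sites. This is the one convention that makes per-sequence
annotations of the same ancestral intron coincide after alignment, and
it is applied uniformly.

**Ambiguity is not absence.** A species missing from a cluster is
ambiguous at every site. The flank rule marks a species ambiguous at a
site when its sequence does not have `min_flank` (default 5) non-gap
residues in the alignment columns immediately on each side of the site
column (the site column itself must also be non-gap). Sites are retained
when the focal species and at least `min_other_species` (default 11)
others are unambiguous; with `min_flank = 0` and
`min_other_species = 1` everything survives. The rule is deliberately a
window over *alignment columns* rather than a count over the whole
sequence: a five-residue gap next to the site is exactly the
misalignment signal the filter exists to catch. Raising either threshold
can only remove sites (tested).

**Dollo parsimony.** Each site has a single origin, placed at the MRCA
of all species carrying the intron; losses are then the minimum set of
branches in that subtree such that every absent species lies below a
loss and no present species does. A postorder sweep computes this in
linear time: a loss is charged to every wholly-absent child clade of a
node that still carries the intron; ambiguous leaves take whichever
state avoids a loss. The implementation is checked against exhaustive
enumeration of all single-gain state assignments (internal nodes plus
ambiguous tips free; exactly one 0→1 transition, root presence counting
as the gain) on 1000 random patterns over random rooted trees of up to 8
leaves. This replaces a probabilistic gain/loss rate model: branch
*rates* are out of scope, only event counts are produced.

**Loss precision.** For a site absent in the focal species but present
elsewhere, the focal row is compared with the intron-bearing rows within
±`window` (default 5) columns of the site. A column is discordant when
the focal sequence has a residue where at least half of the bearers have
gaps, or vice versa; zero discordant columns means a *precise* loss
(clean excision), otherwise the count estimates the indel size. The
original classification of this kind of event was by manual alignment
inspection, so the window rule is a documented, configurable surrogate,
not a claimed replica.

## Orthogroup filters

All filters are deterministic set comprehensions over a nonnegative
orthogroup × species count matrix (OrthoFinder `Orthogroups.GeneCount`
layout) and are tested against literal one-line oracles on 500 random
matrices. Threshold readings, fixed once: "no less than 10 species" is
`≥ 10`; "more than five members" is strict `> 5`; "twofold more than the
average of the two relatives" is inclusive `≥ 2 × mean`; "fewer than 100
copies in any species" is strict `< 100`. All thresholds are function
parameters. Species class labels (e.g. which columns are arthropods) are
caller-supplied, never inferred from names. The birth–death likelihood
machinery the prepared sets feed into is explicitly not implemented.

## HGT screen

`h = best_nonmetazoan − best_metazoan` per query, candidates requiring
`best_nonmetazoan ≥ 75` and `h ≥ 30` (both inclusive — a query at
exactly 75/30 is a candidate). A missing metazoan best hit is treated as
bitscore 0: the permissive convention that cannot miss a true candidate
at the screen stage. Queries with no non-metazoan hit are skipped, not
called negative at `h = −∞`. Subject databases are identified by the
`sseqid` prefix before the first `|`; the class map must exclude the
focal proteome itself (self-hits are an input-preparation concern, not a
runtime taxonomy lookup). Downstream phylogenetic validation is out of
scope; output is labeled *candidates*.

## Repeat coverage

Overlapping RepeatMasker hits are resolved per base in favour of the
highest Smith–Waterman score, ties to the earlier row — the standard
parsing convention for these files — so per-class masked bp always sum
to the total with no double counting. The denominator is the supplied
assembly length; non-TE classes (`Simple_repeat`, `Low_complexity`)
are excluded via `class_filter` rather than silently, since both the
TE-only and all-repeat numbers are legitimate summaries.

## What the synthetic data does and does not emulate

The genome generator places genes left to right with sampled log-normal
intergenic gaps (median ≈ 538 bp), log-normal intron lengths (median
170 bp), a geometric intron count for intron-bearing genes, an exact
planted intronless count (default fraction 0.837), occasional nesting of
an intronless gene inside the previous gene's largest intron, and an
even strand mixture. These defaults are the streamlined-genome regime
the package targets; where no value was dictated, one realistic value
was chosen once (exon lengths log-normal around 350 bp, nesting
probability 0.05) and not revisited. Sequence content is uniform random:
no pipeline stage inspects composition, so a green test establishes
coordinate arithmetic, not biological realism. There is no sequence
evolution, no substitution model, no realistic repeat sequences.

The intron-history generator evolves each site from a uniformly sampled
origin branch with independent per-branch loss; a loss silences the
whole subtree, so there is at most one event per branch per site. Sites
whose simulated history is *not* the unique minimum-loss single-origin
explanation of the resulting leaf pattern are resampled ("canonical"
mode, default): without this, parsimony provably cannot recover the
ledger (losses on both children of the origin relocate the inferred
gain), and the recovery test would be measuring sampling luck rather
than correctness. The independence of the Dollo implementation is
established separately by the exhaustive-search oracle, not by ledger
recovery.

The HGT and repeat generators plant candidates/coverage with explicit
margins and emit the same file formats the parsers read, including
overlapping repeat-hit pairs that exercise score-based resolution.

## Degenerate inputs and numerical notes

* Zero genes: `architecture_summary()` errors; the partition of an
  empty annotation is 100% intergenic.
* A transcript with book-ended CDS segments (zero-length intron) is a
  validation error, as are overlapping segments.
* `c = 0` or `c = L` (intron outside the coding sequence) is rejected.
* Coding lengths not divisible by 3 error unless
  `allow_partial_codon = TRUE` (trailing partial codons occur in real
  annotations).
* All base counts are exact integers (stored as doubles only where
  assembly sums may exceed `.Machine$integer.max`); percentages are
  derived, never accumulated.

## Known limitations

* Dollo parsimony undercounts events relative to rate-based inference
  when parallel loss is rampant; only event counts, not branch rates,
  are produced.
* The flank rule is one defensible reading of "five amino acids present
  on either side"; other tools' internal ambiguity semantics may differ,
  which is why both parameters are exposed.
* The loss-precision classifier sees only the alignment; a precise call
  cannot distinguish clean excision from an indel exactly replaced by
  alignment-identical residues.
* `mini_expansions` compares against exactly two relatives by
  arithmetic mean, as defined; it is not a general outlier test.
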