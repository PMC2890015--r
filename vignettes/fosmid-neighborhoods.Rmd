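---
title: "Annotating fosmid gene neighborhoods: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating fosmid gene neighborhoods: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fosmidann)
```

This vignette is the package's own account of the methods it implements:
the models and rules of each stage, the parameters that matter and why
their defaults are what they are, the numerical conventions, what the
synthetic-data generator emulates (and what it does not), and the design
choices made where the problem left the design genuinely open.

## The setting

Large-insert clones (fosmids, ~30–45 kb) sample a genome one
neighborhood at a time. In a gene-dense plant genome such as diploid
strawberry — roughly one protein-coding gene per 6 kb and little
repetitive DNA — a single insert typically carries half a dozen genes,
a handful of microsatellites, and occasionally a transposable-element
(TE) relic. Annotating such a neighborhood means reconciling four
independent evidence layers over one coordinate frame: ab initio gene
predictions, protein homology (blastx-style hits), transcript evidence
(EST alignments), and simple-sequence-repeat structure. The package
operates on exactly those layers, consumed as standard files (FASTA,
GFF3, 12-column BLAST tabular), and works uniformly in 1-based inclusive
coordinates with strand carried as `+`/`-`.

Multi-contig inserts are analyzed in a single concatenated frame with
`N` padding (default `gap_pad = 100` bp) between ordered contigs and a
gap sentinel recorded at each junction. No feature call ever reads
across a sentinel; sites intersecting one are flagged `contig_break` and
their codons left undetermined. The nominal pad length is a free
parameter — the true gap sizes are unknown — and only affects reported
coordinates downstream of a gap, never lengths or counts
(`total_length` always excludes padding).

## SSR detection and operational loci

A tract qualifies when a primitive unit of 2–5 bp repeats uninterrupted
at least 5 times (`ssr_params()`). The scanner finds maximal periodic
regions by lag-k run-length analysis: a region of period *k* anchored
where the periodicity begins, reported over whole units only, so
`end − start + 1 = unit_length × repeat_count`. Primitivity suppresses
double counting ((AT)₁₀ is never also (ATAT)₅); an `N` or a single
interrupting base terminates the region, which is why
`(TCC)₆ TCT (TCC)₅` is two tracts. Mononucleotide runs are excluded
(`min_unit = 2`): homopolymers are poor markers and the conventional
dinucleotide-and-up survey omits them.

Motif classes fold rotations together; dinucleotides additionally fold
reverse complements (AG = AG/GA/CT/TC), while trinucleotides do not
(ACT and AGT stay distinct), reproducing the mixed grouping conventional
in SSR marker tables (`canonical_mode = "per_unit_length"`).

Tracts closer than 100 bp — strictly less; a gap of exactly 100 bp does
not merge — chain into one *operational locus* by single linkage: the
unit a single PCR primer pair would amplify. Densities are reported at
the printed precisions of marker surveys: per-Mb counts to the nearest
integer, spacings to 0.1 kb, and the genetic-map extrapolation through a
genome context (defaults 206 Mb, 424 cM, hence 486 kb/cM). One caveat
is documented rather than resolved: with 144 loci in 708,363 bp and
486 kb/cM the formula gives ≈ 98.8 loci/cM, while the narrative figure
in the source survey is "about 92"; the package returns the computed
value.

## Homology-based gene sites

Hits are filtered at a relaxed cutoff (`e_relaxed = 1e-5`), grouped by
subject and strand, and chained along the insert when consecutive hits
are ≤ `max_chain_gap = 2 kb` apart. The chain gap is set by intron
biology: observed introns in such genomes reach ~900 bp, so 2 kb chains
the exons of one gene without bridging neighbors at one-gene-per-6-kb
spacing. Chains of *different* subjects covering the same physical
interval (overlap ≥ 50% of the shorter, same strand) merge, so a pair of
paralogous database subjects cannot double-count one site. Each site is
tiered `strict` if its best E-value passes `e_strict = 1e-10`, else
`relaxed`; the two tiers partition the admitted set.

Start and stop codons are then inferred by frame-anchored scans of the
insert sequence, in transcript orientation:

- **Stop**: the first in-frame TAA/TAG/TGA at or 3′ of the homology 3′
  end. The frame is anchored at the 3′-terminal hit of the site
  (carried as `frame_anchor3`), *not* at the 5′ end: intron lengths are
  not multiples of three, so a 5′-anchored frame is wrong for most
  multi-exon genes. This is the one place the implementation sharpens
  the naive rule, and it is what manual reading-frame inspection
  actually does — read on from the last aligned exon.
- **Start**: if the homology region begins exactly at an in-frame ATG,
  that ATG (the alignment already reaches the N-terminus); otherwise the
  farthest upstream in-frame ATG reachable without crossing an in-frame
  stop — the ATG opening the longest open stretch into the homology
  region.
- When a top-tier EST overlaps the site and extends past a boundary, the
  scan is confined to the transcribed extent the EST implies.
- Scans that run off the insert or into a contig gap leave the codon
  undetermined — truncation, not evidence.

Truncation flags: a site edge within `boundary_margin = 50` bp of the
insert end (in transcript orientation) is `artifactual_5p`/`_3p`; a gap
sentinel inside the site is `contig_break`; an interior site whose
predicted protein is < 70% of its homolog's length
(`biological_truncation_ratio = 0.7`) with no artifactual explanation is
`biological` — pseudogene-like shortening. The margin and ratio are
judgment calls (the curation practice they mirror states no numbers):
50 bp is small against ~35 kb inserts yet tolerant of ragged alignment
ends, and 0.7 separates "substantially shortened" from alignment noise.

Tandem duplicates are pairs of non-overlapping sites with the same best
subject (or same family label), at most `max_intervening = 1` site
apart, classified by strand pattern in insert order: same strand
head-to-tail; minus-then-plus head-to-head (divergent); plus-then-minus
tail-to-tail (convergent).

## EST tiers, coverage, and gene models

Identity bands partition: top tier ≥ 95%, second tier 85–94.999…%,
below that unclassified. The boundary semantics follow marker-study
usage, where 95.08% is "marginally top-tier" and 94% is excluded.

Coverage of a coding extent is assessed at base level against top-tier
evidence, with one rule that matters for spliced alignments: a gap
*internal to a single EST* (up to `max_intron = 2 kb`) counts as
covered, because the transcript necessarily spans its own introns. A gap
*between* two different ESTs is never credited — two ESTs touching only
the 5′ and 3′ ends of a gene leave it `partial`. `complete` therefore
means the pooled spliced evidence tiles every coding base. Adding an EST
can never demote the class.

Gene models are built only from complete coverage with both codons
determined: exons are the union of top-tier spliced segments clipped to
the coding span, introns the gaps between them. Splice conflicts —
one EST's exon segment covering another EST's implied intron — are an
error surface, never auto-resolved; such cases need curation. Intron
statistics report total and per-gene counts (mean to 2 decimals),
length mean (integer bp) and counts under a threshold (default 150 bp)
and under the mean.

## Reconciling ab initio predictions

Support is same-strand overlap of ≥ 1 bp between a predicted gene and
an evidence site — the most permissive reading, and a knob
(`min_overlap`). Each prediction is exactly one of:

- `unsupported` — overlaps no site. EST-only sites count as support
  (transcription is evidence), so a prediction over one is *not*
  unsupported.
- `merger` — spans ≥ 2 countable sites. TE-related and EST-only sites
  are not countable for mergers (configurable via `count_te`), keeping
  the merger tally about protein-coding gene fusion.
- `split` — shares one site with another prediction, when no party is a
  merger (merger takes precedence, so each prediction gets one label).
- `simple` — the 1:1 case.

Codon validation is exact coordinate equality between a predicted
boundary and an inferred boundary of an overlapped same-strand site
(`tolerance = 0`; a knob exists but "agreement" means exact). Sites with
undetermined codons contribute nothing. The per-model report row is
predicted genes, unsupported, mergers, genes merged, splits, validated
starts, validated stops, and their sum — with the invariants
`validated_total = starts + stops` and `genes_merged ≥ 2 × mergers`.

## Microsynteny

AGI-style locus codes (`At3g54340`) encode chromosome and an ordered
numeric position at nominal steps of 10, so a reference gene order can
be recovered from codes alone — no downloaded physical map — and an
explicit order table overrides the codes when supplied. Walking site
pairs in insert order (TE-related and EST-only sites skipped), a pair
qualifies when both loci share a chromosome and differ by 1–3 steps
(`max_step = 3`) with at most 2 retained sites between
(`max_intervening = 2`); those bounds admit every published instance the
package's fixtures encode (the largest observed step is 3) while
staying local. Strictly adjacent sites on strictly consecutive loci are
`colinear`; every other qualifying pair is `conserved_microsynteny`.
Pairs touching a locus shared by several sites are annotated
`family_cluster` — proximal multigene families (NBS-LRR clusters being
the canonical case) are weak synteny evidence.

## The synthetic-data generator

`simulate_study()` exists so that every stage can be tested against
known truth without any downloads. Its defaults *are* the study
conditions: 20 inserts of 29–45 kb; a mean of 6.6 genes per insert
(one per ~5.9 kb at typical insert size) with intron counts 0–9
(Poisson-weighted around 2.87) and intron lengths 84–933 bp; ~8 SSR
tracts per insert (one per ~4.5 kb) with motif classes drawn by the
dinucleotide-dominated weights of the published class table and repeat
counts 5–38; TE-related genes on 13/20 inserts; multi-contig assemblies
for 7/20 (2 vs 3 contigs at 2:5); a 25% tandem-duplication rate for the
targeted gene; EST coverage classes complete/partial/none at
15/131, 40/131, 76/131. Corruption rates for the six prediction tracks
(merge 0.15, split 0.10, miss 0.05, codon jitter 0.25, one spurious
prediction per insert per model on average) were chosen once as
plausible magnitudes of the failure modes real predictors show.

Construction guarantees make the recovery tests exact rather than
statistical:

- The background is uniform random sequence *scrubbed* of accidental
  qualifying SSRs by an independent PCRE backreference finder (a
  different mechanism from the scanner under test); planted tracts get
  flank-breaking bases so they are maximal by construction. The planted
  set is therefore provably the only set of qualifying tracts.
- Genes are non-overlapping, ≥ 500 bp apart (> 2 kb when neighbors
  share a subject, so evidence chaining keeps tandem copies distinct),
  with introns planted at codon boundaries. Simulated hits cover exons
  minus the stop codon, as protein alignments do.
- Every corruption event is logged, and the expected reconciliation
  table is computed from the log alone; jittered codons are forced to
  differ from every planted codon, so validation counts are exact.

What the generator does **not** emulate — and hence what passing tests
do not show about real data: realistic nucleotide composition, TE
sequence models, sequencing error, imperfect/compound SSRs, phase-1/2
introns (planted introns sit at codon boundaries), alignment noise at
exon edges, chimeric or mis-oriented ESTs, and genes truncated by insert
ends (tested via hand-built fixtures instead). On real inserts the
chaining/merging heuristics face ragged evidence the simulator does not
produce; the defaults are reasonable, not proven optimal.

## Numerical conventions and degenerate inputs

Rounding reproduces printed precisions: spacings to 0.1 kb, per-Mb and
kb/cM to integers, mean introns per gene to 2 decimals. Zero SSR loci
yield an `NA` spacing sentinel, never a division error; empty hit or
EST tables flow through as empty results; an empty contig list, a
malformed locus code, an orphan GFF child, or a non-12/13-column hit
line is an error naming the offending record. All pipeline outputs are
deterministic functions of their inputs; the simulator is byte-identical
under a fixed `(seed, config)`.

## Problem sizes used in the shipped checks

The test suite and acceptance script run the oracle comparison on 100
random sequences of 0.5–5 kb, and the study-scale recovery checks on a
20-insert simulated study (six prediction tracks, ~150 genes, ~170 SSR
tracts) — sizes matching the study design while keeping a full run in
about a minute on one CPU.

## Known limitations

Start-codon choice beyond the anchored-ATG case depends on upstream open
reading structure and can pick an upstream in-frame ATG that real
curation (with transcript support) would reject; EST-implied boundaries
mitigate this when present. The merger-vs-split precedence makes each
prediction's label unique but means a prediction that both merges two
sites and tiles a third with a partner is counted once, as a merger.
Counts that depended on the original study's unavailable intermediate
files (raw hit tables, curated codon calls) are exercised through the
synthetic truth rather than re-derived from public accessions.
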