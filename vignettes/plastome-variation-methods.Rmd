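---
title: "Methods: comparative plastome variation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative plastome variation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastvar)
```

This vignette explains the models and conventions behind `plastvar`: what
each stage computes, the parameters that matter, the choices made where a
convention was genuinely open, and what the synthetic-data tests do and do
not demonstrate about real data.

## The data model

A plastome is stored as a `PlastomeRecord`: the nucleotide sequence over
{A, C, G, T, N} (other ambiguity codes are rejected at parse time, because
the downstream classifiers assume a four-letter alphabet), a feature table
(exons, tRNAs, rRNAs, with introns derived as the inter-exon gaps of a
`join()` location), and an id. All coordinates are **1-based inclusive**,
the GenBank/IRanges convention; this is used internally and in every
report, so no conversion ever happens between the computation and what a
user reads. The only exception is BED export, which is 0-based half-open
by definition of the format.

Genomes are circular but stored linearised at the published origin.
Intergenic spacers are never read from a file; they are derived as the
gaps between gene loci and named `geneA-geneB` after their flanks.
Same-name features further apart than a plausible intron (3 kb) — IR
duplicates, trans-spliced genes — are treated as separate loci, otherwise
a duplicated gene would swallow everything between its two copies.

## Quadripartite partitioning

`find_quadripartite()` defines the inverted repeat as the longest pair of
**exact** reverse-complement repeats of at least `min_ir` bp (default
10 kb) whose copies do not overlap on the circle; the wrap-around junction
is searched by scanning the doubled sequence. Exactness is a deliberate
choice: plastome IRs are near-perfect, exact matching is deterministic,
and a mismatch-tolerant search would need an arbitrary scoring scheme. Ties
are broken toward the leftmost start. The longer inter-repeat arc is the
LSC by definition; the IR copy that follows the LSC in genome order is
called IRb. The partition always satisfies
`lsc + ssc + 2*ir = genome length`, which the structure constructor
asserts. Genomes without a qualifying repeat raise an error rather than
returning a degenerate partition. Per-region tallies treat both IR copies
as one region class "IR".

## SSR scanning

`scan_ssrs()` reports maximal perfect tandem repeats of unit length 1–6
meeting the copy-number thresholds 10/5/4/3/3/3 — the values plastome
studies conventionally pass to MISA. Conventions:

* Each interval is attributed to the smallest unit whose perfect
  repetition spans it (an A×12 run is a mononucleotide SSR, never AA×6);
  this is enforced by requiring the motif's minimal period to equal the
  unit length.
* Where loci of different unit lengths would overlap (an A-run abutting an
  AG-run can satisfy both), the smaller unit wins and the displaced locus
  is dropped. This keeps the reported set non-overlapping, which the
  per-region and per-context tallies rely on.
* Runs are broken at N; scanning is forward-strand only, and the
  `canonical_class` label (A/T, AG/CT, AT/TA, …) collapses rotation and
  strand so that reporting is strand-symmetric.
* Compound or interrupted repeats are **not** merged: every perfect run is
  its own locus. MISA's compound feature is version-dependent and the
  simple counts are what comparative tables report.

## SNP spectrum

A SNP site is any alignment column that is gap-free and N-free in all
taxa and carries at least two alleles; columns with gaps belong to indel
events and are excluded outright, so no column is double-counted. Each
non-majority allele contributes one directed substitution from the
majority allele to that allele. The directed pair is then pooled with its
reverse complement into one of six classes (A→G/T→C, G→A/C→T, A→C/T→G,
C→A/G→T, A→T/T→A, G→C/C→G); the first two are the transitions.

Polarising direction from the majority allele is a proxy for ancestry: a
four-taxon alignment cannot polarise substitutions without an outgroup,
and majority-rule is the simplest reproducible stand-in. Ties (2:2 splits)
are broken toward the reference allele, then alphabetically; the rule is
deterministic and recorded here rather than hidden. Transition and
transversion totals count substitutions (equal to sites when all sites are
biallelic), and `tv_ts_ratio()` is Tv/Ts to two decimals. Pairwise
difference counts over gap-free columns are reported for every taxon pair.

## Indels

Maximal runs of consecutive columns sharing an identical gap pattern form
one event; adjacent runs with different patterns split at the boundary.
Polarity is "insertion" when the sequence-bearing taxa are the minority,
"deletion" when the gap-bearing taxa are, "unresolved" on 2:2 ties — the
same majority logic as the SNP direction. An event is an **SSR-indel**
when (i) the inserted/deleted sequence is a whole number of copies of a
unit of length ≤ 2 (minimal period enforced) and (ii) the longer allele
carries a perfect run of that unit covering the site whose total copy
number passes the SSR threshold for that unit length; otherwise it is an
**NR-indel**. Condition (ii) is what separates true slippage at a
microsatellite from a coincidental single-base gain; the unit-length cap
of 2 reflects that observed slippage indels are overwhelmingly mono- and
dinucleotide, and is configurable (`max_motif`).

Events are placed in reference coordinates by their first column; a pure
insertion relative to the reference (the reference row is gap) is anchored
at the preceding reference base, so one coordinate frame serves all
events.

## Small inversions

Candidate segments come from clustering nearby variable gap-free columns
(closer than the maximum inversion length). For each candidate segment of
width 2–6 containing the cluster, the caller asks whether some taxon
bipartition splits the rows into exactly two segment strings that are
reverse complements of each other, **and** whether the immediate flanks —
identical and gap-free in all taxa — contain an inverted repeat of at
least `min_flank` (3) bases ending exactly at the segment boundaries.
`flank_repeat_length` is the longest such repeat up to `max_flank` (20).
The stem test replaces thermodynamic hairpin folding: the published stems
are exact inverted repeats, and an exact reverse-complement check is
deterministic and dependency-free.

The smaller inverted subset is reported (tie → the subset excluding the
reference). This is a convention, not an inference: a four-taxon
alignment cannot tell which orientation is ancestral, so a "3-taxon
inversion" and a "1-taxon inversion" of the same segment are the same
observation. Recovery comparisons therefore match unordered bipartitions.
Variable columns inside an accepted inversion are removed from the SNP
list, giving the partition property: every variable column belongs to
exactly one of SNP/indel/inversion.

A single A↔T or C↔G substitution sitting at the centre of a short
self-reverse-complementary context is formally indistinguishable from a
1-mismatch inversion; the caller will report whichever interpretation the
stem test supports. The simulator explicitly avoids planting SNPs in such
contexts so that planted classes stay unambiguous; on real data the two
readings are genuinely confounded and the published analyses resolve them
by hand.

## Nucleotide diversity and hotspots

π is the average proportion of pairwise differences over usable sites
(complete deletion within each window): no Jukes–Cantor correction, which
matches the "Pi" of the standard sliding-window tools at these divergence
levels (< 2%). Windows are 600 columns advancing by 100 (the
conventional plastome marker screen; an 800 bp window is available by
argument), defined over **alignment** columns with midpoints projected to
reference coordinates; the trailing partial window is dropped for
constant-width comparability. Windows with no usable site carry `NA` and
are excluded from `mean_pi`. Consecutive windows with π above the
threshold (default 0.01) merge into one hotspot, annotated with the
reference genes and spacers it overlaps.

## The synthetic quartet generator

`simulate_quartet()` exists so that every stage can be tested against a
known truth without downloads. What it emulates:

* a quadripartite genome at 38.5% GC (exact up to a handful of
  run-breaking edits; base composition is drawn with fixed counts and then
  adjusted by single-base swaps to hit the target),
* IRa planted as the exact reverse complement of IRb, with junction guard
  bases so the planted IR is maximal at exactly its planted length,
* gene/tRNA/rRNA annotation in all regions, IR genes mirrored into both
  copies, the canonical intron-containing genes always given an intron,
* planted SSR loci with guard bases that stop extension, placed in
  requested regions and contexts,
* per-taxon event plans: SNPs by six-class quota (with derived subsets of
  one or two taxa), SSR slippage (copy-number ±1–2 at a planted mono/di
  locus), NR-indels with a 1–5 bp-dominated length mixture and a rare long
  tail, and inversions planted as flank + segment + reverse-complement
  flank with guard bases.

Design choices that make recovery exact rather than merely likely:

* **Isolation.** Events are kept ≥ 10 bp apart across all taxa, so the
  true alignment is unambiguous and is built by construction, never by
  realignment.
* **Repeat hygiene.** Accidental threshold-passing repeats are suppressed
  in the ancestor by rejection sampling, every edit is locally re-scanned,
  NR-indel content is rejected if it would classify as an SSR-indel, and
  each mutant genome's full SSR scan is validated against the expected
  table. The planted loci are therefore the only detectable repeats —
  recall and precision of 1.0 are a property of the construction, and the
  tests verify coordinates, motifs, copy numbers and labels on top of it.
* **Class identifiability.** Complement substitutions are rejected at
  positions where the inversion caller could read them as a 1-mismatch
  hairpin inversion (see above). For derived subsets that tie the majority
  vote and contain the reference, the planted direction is reversed so the
  *called* class equals the planned one under the caller's stated
  tie-break.
* **IR mirroring.** Events planted in IRb are mirrored into IRa
  (complement allele at the mirrored position), preserving IR identity in
  every mutant. The ledger records both sites of a mirrored pair, linked
  by a flag: site-level tallies count both copies (that is what a caller
  sees in the alignment), while the pair count is recoverable from the
  flag.

The full-scale preset (`sorghum_like_config()`) reproduces the scale and
summary statistics of a published four-taxon *Sorghum* plastome
comparison: genome 140,755 bp (LSC 82,686, IR 22,783, SSC 12,503), 651
substitution sites — 518 LSC, 97 SSC, and 18 mirrored IR pairs counted as
36 sites, which is the only reading under which the published per-region
splits are additive with the total — with the six-class quota
179/166/120/106/50/30 (345 Ts : 306 Tv, Tv/Ts = 0.89), 137 indels (43 SSR
/ 94 NR, largest a 165 bp coding deletion in the reference taxon, second a
152 bp insertion in the divergent taxon's rps16-trnQ spacer), nine
inversions with the published length/stem pairs, and four hotspot spacers
(rps16-trnQ, trnG-trnM, rbcL-psaI, rps15-ndhF). One taxon carries the
bulk of the events, and a 17-event derived subset shared by two close
taxa makes the pairwise difference counts span the published 3-to-631
range while keeping the total at 651.

Hotspot SNPs are placed stratified (one per equal-width bin of the
spacer) at 24 per 900 bp spacer, so that every full 600 bp window inside
a hotspot stays above the 0.01 threshold and each designated hotspot is
called as exactly one interval; background SNPs carry a dispersion guard
(rejected where five or more prior SNPs lie within ±300 bp) so no
spurious hotspot arises. The resulting genome-wide mean π is ≈ 0.0025 and
peak window π ≈ 0.012–0.019. A genome-wide mean π in the 0.01 range is
not reachable from 651 mostly taxon-private substitutions on a 140 kb
alignment — the arithmetic gives ≈ 1950 pairwise differences over
6 × 140 kb site-pairs ≈ 0.0023 — so the preset reproduces the count data
and the hotspot structure, and reports the mean as computed.

What the generator does **not** emulate, and what passing tests therefore
do not show: alignment error (the true alignment is given; on real data
indel counts are sensitive to the aligner and its version), overlapping or
adjacent events, homoplasy and back-mutation, rate heterogeneity along the
genome beyond the planted hotspots, IR boundary shifts between taxa, and
imperfect (interrupted) microsatellites. Real-data runs should treat the
SNP/indel/inversion totals as alignment-conditional.

## Problem sizes and numerical conventions

The test suite runs the full pipeline at 20 kb (the default simulation),
the invariant battery on one hundred 10–14 kb quartets, and the
full-scale 140.8 kb preset once; these sizes keep the whole suite in the
minutes range while exercising every code path. Degenerate inputs have
defined behaviour throughout: an all-N sequence has undefined GC (error),
a window with no usable sites has undefined π (`NA`, excluded from the
mean, never coerced to zero), an alignment with no gap-free column warns
and returns an empty SNP set, a window longer than the alignment collapses
to a single whole-alignment window with a warning, and an empty SSR input
summarises to an all-zero table. All randomness flows from the single
seed in the simulation config; identical config and seed give
byte-identical genomes, ledger and alignment.

## Known limitations

* The IR detector requires exact repeats; a plastome with a genuinely
  degraded IR (some gymnosperms) is reported as non-quadripartite rather
  than fuzzily partitioned.
* SSR detection is perfect-repeat only; imperfect SSRs and MISA's
  compound merging are out of scope, so totals on real genomes can differ
  slightly from MISA runs that merge interrupted repeats.
* Substitution direction is majority-polarised, not tree-polarised; with
  an outgroup and a tree, directed class counts could differ.
* Inversion orientation is reported as a bipartition convention, not an
  ancestral-state inference.
* The alignment is an input. The package never aligns, and indel/inversion
  coordinates inherit whatever gap placement the aligner chose.
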