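---
title: "Methods and design notes for mitotick"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for mitotick}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

mitotick is a toolkit for comparative analysis of hard-tick (Ixodidae)
mitochondrial genomes: circular ~14-15 kb molecules carrying 13
protein-coding genes (PCGs), 22 tRNAs, two rRNAs and one control region
(CR). This vignette records the statistical definitions the package
implements, the tunable parameters and their defaults, the design
decisions taken where published descriptions leave the choice open, and
what the synthetic-data generator does and does not emulate.

## Coordinates and gene vocabulary

All coordinates are 0-based half-open on the heavy strand (the strand a
GenBank flat file prints); conversion from 1-based inclusive GenBank
coordinates happens only in `read_genbank()`/`write_genbank()`. This
makes arithmetic on origin-wrapping features of circular genomes
unambiguous: a feature with `wraps_origin = TRUE` runs from `start` to
the sequence end and continues from 0 to `end`.

Gene names are normalized onto a canonical vocabulary (ND1-ND6, ND4L,
COX1-3, CYTB, ATP6, ATP8; trnA...trnV with the leucine and serine
isoacceptors split as trnL1/trnL2 and trnS1/trnS2 by anticodon class;
rrnS, rrnL; CR and CR2). Labels that cannot be mapped are retained with
category "other" and ignored downstream. Public tick records disagree on
the strand of trnL2; the package always takes strand assignments from
each record's own annotation rather than assuming the ancestral
placement.

## Composition and skew

AT-skew = (A - T)/(A + T) and GC-skew = (G - C)/(G + C), computed on
counts. A zero denominator yields a missing value, never 0. IUPAC
ambiguity characters count as "other" and are excluded from the four
skew counts.

Per-gene rows of `genome_gene_table()` are computed on the
coding-orientation sequence (light-strand genes reverse-complemented).
The published analyses do not state their convention; the coding
orientation was chosen because it reproduces, as a pure
strand-orientation effect, the systematically higher GC-skew of
light-chain genes relative to heavy-chain genes. `gene_strand = "heavy"`
switches to printed-strand statistics. Percentages are rounded to 2
decimals and skews to 3 in the table (the reporting style of the
literature); `base_composition()` retains full precision.

## Microsatellite mining

A microsatellite locus is a maximal perfect tandem tract of a primitive
1-6 bp motif whose whole-unit repeat count meets the per-length minimum:
10 (mono), 5 (di), 4 (tri), 3 (tetra), 3 (penta), 3 (hexa). A partial
trailing unit is part of the tract span but does not increment the
repeat count, and it does participate in maximality. Only perfect
repeats are reported; compound or interrupted arrays are not merged.
Sequences are scanned linearly -- no wrap-around repeat across the
origin -- matching the behavior of the standard SSR tools on deposited
records. N never joins a repeat.

Motif classes group all cyclic rotations of a motif together with the
rotations of its reverse complement, taking the lexicographically
smallest string as the class representative (so T-rich heavy-strand
tracts of poly-T report as class "A", and TTA/ATT/TAT as "AAT"). This
complement-grouping is required to reproduce the dominance of classes A
and AAT on T-rich heavy strands; `revcomp_classes = FALSE` preserves
strand-specific (MISA-style) classes. Relative abundance is loci per
kilobase: RA = n / genome size x 1000, reported to 3 decimals.

## Degenerate motif scanning

`scan_motif()` matches an IUPAC pattern (default the 17 bp Tick-Box
consensus TTGyrTChwwwTwwGdA) against every window on both strands,
including windows across the origin of circular records, reporting all
windows within the mismatch tolerance. The default tolerance is 1
mismatch: the known bat-tick occurrence of the motif deviates from the
printed consensus at one degenerate position yet is treated as an
occurrence in the literature, so a strict 0-mismatch rule would be too
narrow. Overlapping hits are all reported.

Context labels follow a fixed precedence: a hit fully inside a feature
is "within <gene>" (smallest containing feature); otherwise a hit whose
5' start lies within `downstream_window` (default 100 bp -- the
literature gives no numeric definition of "downstream") of a gene's 3'
end is "downstream of <gene>"; otherwise "intergenic". When several
genes qualify as upstream neighbors, genes transcribed on the hit's own
strand take precedence, because a motif downstream of a gene reads in
that gene's transcription direction.

## K2P distances and species delimitation

For an aligned pair, with P and Q the transition (A/G, C/T) and
transversion proportions over usable sites,
d = -(1/2) ln((1 - 2P - Q) sqrt(1 - 2Q)). Sites where either sequence
carries a gap or ambiguity are excluded pair by pair (pairwise
deletion); this maximizes usable sites on near-complete marker
sequences and is the default the package applies consistently across the
distance and diversity modules. A non-positive log argument flags the
distance as undefined (NA) rather than raising an error.

Species-complex delimitation thresholds default to the recommended tick
species boundaries, 0.0525 for rrnL and 0.0613 for COX1. Individuals
i, j are linked when the rule holds and groups are the connected
components (single linkage), numbered in first-seen order. The default
rule requires the distance to fall below threshold for *every* marker.
This is the only rule consistent with both published species-complex
tables: in the I. acutitarsus table the rrnL distances to the singleton
individual (0.0491-0.0502) sit below the rrnL threshold while the COX1
distances (0.0754-0.0776) sit above it, so an any-marker rule would
collapse the two groups into one. Undefined distances count as above
threshold.

## Diversity statistics

A column is variable iff at least two distinct unambiguous bases occur
among its non-gap characters; the percentage denominator is the number
of columns with at least two usable characters, which is robust to
ragged alignment ends. Nucleotide diversity is the mean over unordered
pairs of per-site differences under pairwise deletion. Sliding windows
are indexed by alignment columns (the DnaSP convention), default 200 bp
window and 20 bp step, advancing from column 0 with the trailing partial
window dropped, giving floor((L - window)/step) + 1 windows.
Supermatrix concatenation matches taxa by id and gap-fills missing
genes; partitions are emitted in RAxML and NEXUS styles.

## Gene-order rearrangement scoring

Gene orders are signed circular permutations canonicalized by anchoring
trnI at index 0 with positive sign (reflecting and sign-flipping first
if needed), so rotation of the annotation or deposition of the
complement strand cannot change any downstream result.

The published description of rearrangement frequency (RF) and
rearrangement score (RS) does not spell out per-gene scoring rules, so
the package fixes a documented contract: each target gene is compared to
the benchmark on (a) its own strand sign and (b) the identity of its
circular predecessor, ignoring the predecessor's sign so that an
in-place inversion flags only the inverted gene. Scores: kept 0,
translocated 1, inverted 1, inverted+translocated 2, duplicated (CR2) 1;
RS is the sum, zero exactly for an identical order. RF(g) is the
percentage of arrangements in which g scores positive, and the maximal
circular run of RF = 0 genes is reported as the conserved segment --
always computed from the data, never hard-coded, because published
conserved-segment listings are not fully consistent with the canonical
ancestral order. Only the ancestral arthropod arrangement (T1, CR
between rrnS and trnI) ships built in; further arrangement types are
supplied as a catalog file, since their full orders are published only
as figures. Typing is exact canonical-form matching, no fuzzy match.

## The synthetic world

`simulate_mitogenome()` draws an i.i.d. heavy-strand background at a
target A+T fraction of 0.78 with AT-skew -0.017 and GC-skew -0.172 --
the family-level means reported for Ixodidae mitogenomes -- and lays the
37 genes + CR of the chosen arrangement from position 0 with random
intergenic spacers; default gene lengths total ~14.5 kb and the default
genome lands near 14.7 kb, the family average. PCG start/stop codons are
rewritten so codon QC passes. Planted SSR tracts get flanking bases
chosen to break the repeat, making the tract maximal exactly at its
planted coordinates, and recovery by the scanner is verified before the
genome is returned; spacers hosting intergenic plants are widened so an
"intergenic" context is geometrically guaranteed. `evolve_pair()`
applies exact K2P transition probabilities at the requested divergence
(default kappa = 2), so the expected K2P estimate equals the target;
`simulate_marker_alignment()` composes these branches star-wise to give
chosen within- and between-group divergences. All generator entry
points are deterministic to the byte under a fixed seed.

What the generator does *not* emulate -- and hence what a green test
does not establish: indels (alignments are generated gap-free unless
punched in by a test), base-composition autocorrelation and
codon structure beyond start/stop codons, selection, secondary-structure
constraints on tRNAs/rRNAs, and real annotation noise (boundary errors,
missing genes). Statistics sensitive to those features are validated
only against the published numbers typed in as fixtures, not against
simulation.

## Numerical conventions and degenerate inputs

Percentages print at 2 decimals, skews at 3, distances at 4, relative
abundance at 3, matching the reporting style of the field. Undefined
quantities (zero skew denominators, saturated K2P pairs, empty SSR
summaries) propagate as NA. Empty sequences, single-sequence alignments,
ragged alignments and windows longer than the alignment raise immediate
domain errors. Codon QC flags but never fails records with atypical
start/stop codons.

## Known limitations

- GenBank parsing covers the LOCUS/FEATURES/ORIGIN subset used by
  mitogenome records (single-range and origin-spanning join locations);
  it is not a general flat-file parser.
- The RF/RS scoring contract is this package's own formalization of a
  qualitative published description; absolute RS values are comparable
  within this package only.
- Recomputing published distance/diversity values from deposited
  accessions requires network retrieval of those records and is out of
  scope; the published matrices are instead consumed as typed-in TSV
  fixtures.
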