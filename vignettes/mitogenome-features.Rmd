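---
title: "Methods: quantitative feature analysis of circular mitochondrial genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative feature analysis of circular mitochondrial genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitofeatures)
```

This vignette is the package's own account of the models and procedures it
implements, the parameters that matter, the numerical conventions, and what
the synthetic-data tests do and do not demonstrate about real genomes.

## The coordinate model

Every analysis runs over a `circular_genome`: a residue string over
{A,C,G,T,N} with circular topology, in which any 1-based position `p` has
the canonical image `((p-1) mod L) + 1`. External coordinates are 1-based
inclusive, the GenBank/EMBL convention in which published annotation tables
are written; internal arithmetic converts to 0-based half-open spans with
explicit wrap handling. A feature crossing the sequence origin is a single
interval flagged `wraps_origin`, never a pair of sub-intervals — the first
gene of a circular record conventionally starts at position 1, and origin
shifts must be lossless. In GFF3 and BED output a wrapped feature is
written with `end = end + L` (the usual convention for circular
molecules), and folded back on input. `N` residues are tolerated in
sequence but excluded from every composition denominator, since draft
assemblies contain ambiguity codes.

Gene models hold exons in transcription order (descending genomic
coordinates on the minus strand); introns are derived from the gaps
between consecutive exons unless supplied with type and
homing-endonuclease labels. The published *P. radiata* tables fully
determine each gene's span, coding length, stop codon, and ordered intron
lengths — but not the exact exon boundaries within a span, which were
adjusted manually against multiple alignments in the original annotation.
`phlebia_gene_models()` therefore lays exons out synthetically (coding
sequence split evenly between the published introns). Every statistic
derived from spans, coding lengths and intron lengths is exactly that of
the published annotation; only the internal exon boundaries are a
convention, and nothing in the package computes from them.

## Architecture statistics and rounding

Coding density is `100 * coding_bp / span_bp`; protein length is
`coding_bp/3 - 1` when a stop codon is annotated (the stop is part of the
coding sequence but not of the protein — this convention reproduces the
published 1590/3 − 1 = 529 aa for cox1). All printed-precision comparisons
round half up (`round_half_up()`): densities to one decimal, intron means
to integers. Base R's `round()` rounds half to even and would disagree
with printed tables on exact .5 boundaries.

The genome composition partition assigns every position to exactly one of
conserved-coding > intronic > intergenic, in that precedence, so
overlapping annotations (a start codon sharing a base with the upstream
stop) are counted once and the three categories always sum to the genome
length. Additional ORF layers are reported on top without disturbing the
partition, because intronic ORFs (homing endonucleases) already lie inside
the intronic category.

## Codon usage, distances, and CAI

Codon frequencies are global relative frequencies over the included codon
set — by default the sense codons of the configured genetic code (stop
codons excluded), because protein-coding usage analysis concerns sense
codons and the treatment of stops in published codon-on-codon matrices is
not standardized. "Codon-on-codon" RMSD is taken over the raw usage
vector, not within-family RSCU; a family-normalized view is available
through `synonymous_fractions()`. The default genetic code is NCBI table 4
(mold/protozoan/coelenterate mitochondrial), the conventional starting
assumption for fungal mtDNA; every function takes a `code_table` argument.

Neighbor joining is the Saitou–Nei algorithm: join the pair minimizing
`Q(i,j) = (n-2) d(i,j) - r_i - r_j`, branch lengths from the three-point
formulas, final unrooted multifurcation closed in closed form. Two
numerical conventions make it deterministic and safe: among equal-Q pairs
(within 1e-12) the lexicographically smallest sorted taxon-name pair is
joined, and negative branch lengths are clamped to zero with the deficit
transferred to the sister branch, raw values retained in the
`raw_edge_length` attribute. On additive matrices the tree metric is
recovered to better than 1e-9 (verified against cophenetic recomputation
and against `ape::nj` as an independent reference).

CAI follows Sharp & Li: relative adaptiveness `w(c)` is the codon's
reference count divided by the maximum count in its synonymous family, and
the index is the geometric mean of `w` over the ORF's codons. Stop codons
and single-codon families are excluded (they carry no choice). A codon
never observed in the reference receives the pseudo-adaptiveness
`0.5 / (family max count)` rather than zero — one unused codon must not
collapse the geometric mean to 0 — and families entirely absent from the
reference are excluded with a warning. CAI is invariant to codon order and
to rescaling of reference counts.

## Skew and replication landmarks

Windowed skew is `(n_first - n_second)/(n_first + n_second)` per window
(0 on an empty denominator), windows wrapping across the origin; defaults
are 1 kb windows stepped by 100 bp, matching the ~1 kb resolution at which
origin calls are conventionally read off mitochondrial skew plots. Only
mono-nucleotide skew is implemented; higher-order (k-mer) strand bias is a
documented extension point, since no standard computation exists for it.

Landmark calling works on the *detrended* cumulative curve: per-position
contributions (+1 for G, −1 for C) minus their genome-wide mean, so the
curve closes to zero around the circle. Detrending is what makes the
extremum positions exactly equivariant under rotation of the sequence
origin; the raw cumulative curve is not rotation-equivariant when global
composition is unbalanced. The origin candidate is the global minimum (the
transition into the G-dominant leading segment), the terminus the global
maximum, both reported as ± half a window. Under reverse complement the
skew negates and each landmark reappears at its mirrored coordinate
`L - p`, with roles preserved: viewed from the other strand, the leading
segment still begins at the origin.

Calls are withheld unless the cumulative range exceeds the critical value
from a seeded null: the contribution series is cut into window-sized
blocks, blocks are permuted and each is sign-flipped with probability 1/2.
This preserves the genome's regional composition texture (genes vs AT-rich
spacers produce correlated stretches) while destroying coherent strand
asymmetry; a plain residue shuffle is measurably anti-conservative on
structured genomes (~13% false-call rate instead of the nominal 5% in our
calibration runs). The critical value is the exact permutation-test order
statistic (the k-th largest of `n_null` replicate ranges, k =
⌊(1−q)(n_null+1)⌋), with `n_null = 499` by default — marginal decisions
should be dominated by the data, not by critical-value estimation noise.
The package default significance is the 95th percentile; batch studies
over many genomes should tighten it (the acceptance study uses 0.99 per
genome so the family-wise false-call count over 20 genomes stays well
below one).

## Repeat discovery and clustering

`self_compare()` is a blastn-style self-search: exact k-mer seeds (word
size 11 by default; 8 is the floor) on the forward strand for direct
repeats and against the reverse complement for inverted ones, extended
ungapped with an X-drop of 20 score units at +1/−2 scoring, on a doubled
sequence so hits may cross the origin. Coordinates are folded back to the
circle, symmetric duplicates and the trivial self-hit removed. Hit ends
are refined by an adaptive rule: an outermost 16 bp window is trimmed only
when its identity is a 3σ binomial outlier against the hit's own core
identity (with a variance floor) — a fixed trim threshold close to the
repeat's true identity would clip genuine mismatch-dense ends and bias
reported identities upward, while no refinement at all lets chance
excursions into the flanks dilute them. Filtering is purely by identity
and length; the attached Karlin–Altschul-style E-value (λ = 1.28,
K = 0.46, the ungapped +1/−2 DNA parameters) is for reporting only.

For diverged repeat families the word size matters: at 85% pairwise
identity, 150–200 bp copies fail to share an exact 11-mer in 2–8% of
pairs, so recovery studies run at word size 9, where the miss probability
is negligible; 11 remains the general-purpose default.

Clustering is CD-HIT-style greedy incremental: member intervals sorted by
length descending (ties by start, then end), each joining the first
cluster whose representative it matches at or above the cut-off (global
alignment identity, matches / alignment columns including gaps), else
founding a new cluster. The cascade re-clusters each level at the next,
stricter cut-off (0.75 → 0.80 → 0.90), so cluster counts are
non-increasing as the cut-off loosens.

`find_inverted_duplication()` chains collinear inverted hits — an indel in
the duplication shifts the (forward, reverse-complement) diagonal by one,
splitting the ungapped search into adjacent-diagonal segments — then
aligns the chained regions globally (match +1, mismatch −1, gap open 5,
extend 1) to produce the explicit per-site difference list, with
substitutions and single-base insertions/deletions classified separately.
Reported lengths are inclusive lengths from coordinates. On the published
mirror-region coordinates, the inclusive length of ID2 (36,285..42,360) is
6,076 bp; the accompanying text prints 6,075 bp, and the package never
reconciles to either — it reports what the coordinates imply.

## Wobble decoding and HE correlations

Wobble expansion follows the mitochondrial rules: anticodon positions 2
and 3 pair Watson–Crick with codon positions 2 and 1; at the wobble
position a U reads all four third-position bases, a G reads C or U, and A
and C pair only Watson–Crick. The literal wobble-U rule crosses two-fold
family boundaries (a Leu-UAA anticodon formally reads all UUN codons) —
this "superwobble" over-coverage is intentional: the decoding check asks
whether any *used* codon lacks a reader, so over-coverage never produces a
false alarm of undecodability. With the CAU→Ile reassignment flag, an
isoleucine-annotated CAU anticodon is treated as an edited (lysidine-type)
anticodon reading AUA. Codons with zero usage in conserved coding
sequences but nonzero usage elsewhere are listed as unassigned candidates.

Homing-endonuclease domain similarity is global-alignment percent identity
(match +1, mismatch −1, gap open 5, extend 1; denominator = alignment
columns including gaps — the denominator must be fixed for determinism,
and published identity methods rarely state theirs). The locus of a domain
is the genomic midpoint of its coding interval, and locus distance is the
circular metric `min(|m_i - m_j|, L - |m_i - m_j|)`, bounded by ⌊L/2⌋.
Similarity may be log-transformed as `log(x + 1)` so that 0% identities
(observed in real LAGLIDADG-2 pairs) remain finite. Because the n(n−1)/2
matrix pairs are not independent, the classical Pearson/Spearman p-value
is reported alongside an optional seeded Mantel permutation p-value
(rows/columns permuted jointly); the classical value mirrors what
published correlation analyses report, the Mantel value is the honest one.

## The synthetic genome generator

`synthetic_genome_spec()` defaults describe a large Agaricomycotina-type
mtDNA: 156,348 bp at 31.1% GC, the published conserved gene complement
with its coding lengths and intron counts, intron lengths 0.2–3.4 kbp, a
6,076 bp inverted duplication differing at 3 sites (one substitution, one
insertion, one deletion), five dispersed/inverted repeat families of
150–200 nt members at 85% identity planted in intergenic spacers, AT
enrichment of non-coding sequence by a factor 1.3, and a G-over-C leading
segment of amplitude 0.25 switching at the planted origin and terminus.
Coding sequences are drawn from an AT-rich codon table (W-ending codons
preferred, as in real fungal mtDNA usage) and are stop-free under the
configured code except the terminal TAA; layout is computed before any
residue is drawn, so a seed fully determines the output byte for byte.

Three generator design choices deserve explanation because they define
what "planted truth" means:

* **Skew amplitude and flip placement.** The composition switch is only
  expressed in non-coding sequence (coding sequence composition is fixed
  by the codon table), so the default origin and terminus sit at spacer
  midpoints — a flip point inside a gene would be unlocatable by
  construction, and real mtDNA replication landmarks lie intergenic. The
  amplitude 0.25 follows from an error analysis of the cumulative-skew
  changepoint estimator: its localization error scales like σ²/μ² with
  exponential tails, and weaker asymmetries cannot be localized to the one
  smoothing window a skew plot readable at ~1 kb resolution implies.
* **Repeat family structure.** Members diverge from the family consensus
  at interior positions only, keeping 10 bp termini exact — the
  conserved-termini structure of mobile-element-derived repeats — and each
  member carries a distinct flanking dinucleotide code over {A,C} whose
  reverse complement lies in {T,G}, so every pair mismatches immediately
  outside the planted boundary in both orientations. Without these the
  "true extent" of a planted copy is operationally ill-defined: a trailing
  mismatch cluster belongs to the repeat or to the flank depending on
  taste, and no detector can then be scored on exact identity agreement.
  Members are planted ≥250 bp apart so ungapped extension cannot bridge
  neighbours into spurious tandem hits.
* **Duplication flanks.** The two residues flanking each duplication copy
  are set equal to their partner's flank (a base never pairs with its
  equal under reverse complement), so the planted boundaries are also the
  maximal extent and boundary recovery can be scored exactly.

What the generator does *not* emulate: transcription-coupled or
replication-age skew gradients, tandem microsatellites, nested or
fragmented repeat copies, intron-borne ORFs with their own codon bias,
base modification, and assembly artifacts. Passing the recovery tests
therefore shows the algorithms are correct under a clean, known model —
not that their defaults are tuned for every real genome.

## Problem sizes and test design

The test suite and the acceptance script run the simulation studies at
deliberately modest sizes chosen by the package: 15 kb genomes with two
genes for the skew and repeat recovery studies (20 replicates each), 25 kb
for mirror-region recovery at the published 6,076 bp scale, 4–8 leaf trees
for neighbor-joining recovery, and brute-force oracle comparisons on
≤2 kb sequences where exhaustive all-substring scanning is feasible. The
localization and recovery properties under test are local, so they do not
improve with genome size; the published-table replays are exact
arithmetic and size-free.

## Known limitations

* Repeat boundary estimation is ungapped; families whose copies differ by
  internal indels are found as split hits rather than one gapped
  alignment (the duplication detector chains across indels, the family
  detector does not). Reported identities carry an irreducible
  boundary-estimation uncertainty of up to ~2–3 percentage points in the
  tails, because a maximal-scoring extent legitimately excludes end
  segments with mismatch density above 1/3.
* The E-value attached to repeat pairs uses fixed ungapped DNA
  Karlin–Altschul parameters and is not composition-adjusted; it is a
  reporting aid, not a filter.
* A genome-scale inverted duplication distorts the skew curve (its second
  copy contributes skew of the opposite sign), which can displace the
  cumulative extremum by more than a window on small genomes; landmark
  benchmarks therefore run on duplication-free genomes.
* GenBank/EMBL parsing covers the feature-table subset the pipeline
  consumes (CDS, tRNA, rRNA keys; join/complement/order locations;
  gene/product/anticodon qualifiers), not the full flat-file grammar.
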