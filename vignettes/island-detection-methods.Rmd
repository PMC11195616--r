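---
title: "Detecting genomic islands as synteny breaks: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting genomic islands as synteny breaks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models behind `islandbreak`, the parameters
that matter, the synthetic data the package validates itself on, and the
design choices made where the problem admitted more than one reasonable
answer.

## The model

The package operationalizes a genomic island as a **synteny break**: a
region lying between two synteny blocks that are consecutive in both of
two closely related genomes, on the same strand. The underlying assumption
is vertical inheritance of gene order — in genomes related enough to share
long colinear stretches, a gap in colinearity flanked by otherwise
uninterrupted synteny marks DNA gained (or lost) since divergence,
typically by horizontal transfer. The method is therefore only meaningful
for genome pairs that actually share synteny; for very distant pairs the
"backbone" dissolves and breaks lose their interpretation.

### Orthologs

One-to-one orthologs are best reciprocal hits (BRH) over a filtered
all-vs-all protein comparison. Retention thresholds (E-value `< 1e-10`,
identity `> 40%`, aligned span `>= 40%` of the shorter protein) follow the
method's standard operating point; identity and E-value bounds are
strict, the coverage bound is inclusive ("at least 40%"). Coverage is
measured as the aligned span (`end - start + 1`) on the shorter protein
divided by its length: whether gap columns should count is not specified
anywhere authoritative, and the span convention is the one a 12-column
tabular alignment file can always reproduce.

Bitscores are compared after rounding to one decimal, so near-equal scores
tie. Ties are resolved by gene-order context: a candidate pair (a, b) is
*anchored* when an already-accepted pair lies within `max_gap + 1` ranks
of `a` and within `max_gap + 1` ranks of `b` (either side, so inverted
neighborhoods anchor too — the anchor window is deliberately the same
tolerance used for block gaps). Resolution iterates to a fixpoint with
anchors frozen at the start of each pass, scanning genome-A genes in
ascending rank; a gene accepts its uniquely *nearest* anchored candidate
(anchor distance = the larger of the two rank offsets), and genes whose
candidates tie at the fixpoint stay unpaired — a gene with several
surviving best hits gets no ortholog. Whether the original resolves in one
pass or iterates is not documented; the fixpoint was chosen because a pair
accepted early can legitimately anchor its neighbor, and the frozen
per-pass anchor set keeps the result independent of within-pass order
effects beyond the documented scan order.

### Synteny blocks

Ortholog pairs chain when their genes are adjacent among the mapped genes
of both genomes — an orthologous gene inside the gap breaks the chain —
and separated by at most `max_gap` non-orthologous CDS/tRNA ranks in each
genome independently (a gap of exactly `max_gap` in both genomes at once
still links; the tolerance reading is per-genome, not summed). Blocks are
maximal constant-direction chains with at least two pairs; the direction
sign is the block's orientation. Because chaining requires adjacency among
mapped genes on both sides, blocks are automatically strictly monotonic in
both genomes and every pair belongs to at most one block. tRNA genes never
form orthologs but occupy ranks, so they count toward gap distances.

### Breaks

An island is called between blocks *i* and *j* (*i* before *j* in genome
A, same replicon pair, same orientation) when every block strictly between
them in A is a **stray** — not consecutive-in-both-genomes with any other
block — and *i*, *j* are adjacent in B in the blocks' shared direction
once strays are ignored. "Consecutive in both genomes" is
orientation-aware: a same-orientation neighbor must follow in B in the
blocks' direction, while an opposite-orientation block adjacent in both
genomes (an inversion) also counts as consecutive and is never absorbed.
Without the first clause a transposed block that happens to be
ordinal-adjacent in reverse order would block absorption; without the
second, a whole inversion would be swallowed as "interior" and called an
island. There is no cap on how many strays a break may absorb; strays are
recorded per island as `interior_blocks`.

The island's gene interval on each side is the ranks strictly between the
facing boundary orthologs of the flanks (so a tRNA sitting between the
flank and the island's first CDS is inside the interval). A break is
reported when `max(n_cds_a, n_cds_b) >= min_break_cds` (default 3); the
display filter `filter_islands(min_cds)` additionally retains islands
whose own side is small when the partner side passes, because a 0–2 CDS
side is still the orthologous position of a real island in the partner.

### Island metrics

Per genome side: CDS count; CDSs with **no ortholog anywhere** in the
partner genome (not merely outside the island — a gene whose ortholog sits
elsewhere may be a relocated native gene, not island cargo); CDSs with at
least one paralog, from the filtered proteome self-comparison with trivial
self-hits dropped; a tRNA flag true when a tRNA lies inside the interval
or within `trna_vicinity_cds` (default 2) ranks of either boundary — the
source material says only "immediate vicinity", and two ranks covers the
tRNA-then-integrase arrangements seen at integration sites; and ΔGC, the
GC of the island's contiguous nucleotide span (first island gene start to
last island gene end, intergenic DNA included, since islands arrive as
contiguous DNA) minus the replicon-wide GC, in percentage points.
Keyword tags are case-insensitive substring matches of the configured
mobility/interest lists against product annotations.

`rank_islands()` min–max normalizes each numeric metric across the island
set (booleans as 0/1, ΔGC by absolute value — a strong shift in either
direction is the signal), scores by the weighted sum, and breaks ties by
island id. Normalization makes the score invariant under affine rescaling
of any one metric; a degenerate metric (all values equal) contributes 0.
Default weights are equal, and weights are fully user-configurable —
no authoritative default weighting is available.

### GOC profile

Per genome of a pair, windows of `goc_window_frac` (default 0.03) of the
replicon bp length, stepped by a quarter window; the value is the fraction
of window CDSs that have an ortholog whose partner is rank-adjacent
(|Δrank| = 1) to the next CDS's partner. "3% of the genome size" is
ambiguous between bp and CDS count; bp was chosen because the profile is
plotted along physical coordinates. The last CDS of a replicon has no next
CDS and is excluded from numerator and denominator, so a perfectly
conserved pair reads exactly 1.0 in every reported window; windows with no
countable CDS are omitted. CDSs are assigned to windows by their midpoint.

### Hotspots

Islands are anchored by the reference-genome orthologs of their boundary
genes (the last gene of the left flank, the first of the right), ordered
by reference rank. Identical anchor pairs define "the same location":
diversity is the number of distinct genomes carrying an island there
(distinct genomes, not pairwise calls — one genome may show the same
island against several partners), and the break graph links those genomes.
Islands whose reference intervals intersect with *different* anchors are
grouped as overlapping islands by transitive closure; exact matches are
excluded from overlap groups. Anchoring requires both boundary genes to
have reference orthologs; islands that cannot be projected are skipped.

## Parameters

| parameter | default | units | notes |
|---|---|---|---|
| `evalue_max` | 1e-10 | — | strict `<` |
| `identity_min_pct` | 40 | % | strict `>` |
| `coverage_min_pct` | 40 | % of shorter protein | inclusive `>=`, aligned span |
| `max_gap` | 2 | CDS/tRNA ranks | per genome, non-orthologous only |
| `min_break_cds` | 3 | CDS | in at least one genome |
| `goc_window_frac` | 0.03 | fraction of replicon bp | step = window/4 |
| `trna_vicinity_cds` | 2 | ranks | boundary vicinity |
| `builtin_budget` | 1e7 | protein-count product | builtin aligner guard |
| `max_genomes` | 20 | genomes | database size cap |

The built-in aligner is exact Smith–Waterman (BLOSUM62, gap open 11,
extend 1, a length-1 gap costing 12) with Karlin–Altschul scaling fixed at
λ = 0.267, K = 0.041 and search space = product of the two proteomes'
residue counts. Its E-values are approximate: external hit tables from a
standard search tool are authoritative when reproducing counts from full search engines.
Candidate pairs for the built-in aligner are prescreened by shared 4-mers
(threshold `max(6, 2%)` of the shorter length), which is calibrated for
closely related proteomes (roughly ≥ 50% identity); more distant homology
should come in through external hit files.

## What the simulator emulates — and what it does not

`simulate_pair()` builds two genomes from one ancestor proteome: a
colinear backbone of orthologs mutated to a target identity
(substitution-only, exact count, never to the original residue), islands
of independently drawn proteins (so they produce no retained hits at the
pipeline's thresholds), optional tRNA anchors and mobility-annotated
genes, optional inversions, and nucleotide sequences reverse-translated
with a two-codon-per-residue scheme steered to hit the backbone GC and
per-island GC shifts (exact to about one base per gene; the codon scheme
realizes roughly 0.30–0.63 GC for coding sequence, so the default
backbone of 0.55 leaves headroom for ±8-point shifts). Genes average
900 bp (±30%), spacers 150 bp, both annotated and emitted as GenBank or
GFF3+FASTA that re-enter `parse_genome()` unchanged.

Passing recovery tests on these simulations shows the machinery is
correct under the model's assumptions — it does **not** show field
performance on real genomes, which add indels, gene fusions and splits,
annotation disagreements between genomes, assembly fragmentation, repeat
families, composition-biased proteins and islands that share ancient
homology with the backbone. The validation suite uses backbones of
100–500 genes with 1–5 islands of 3–30 genes at 60–95% identity, island
positions at least 4 backbone genes apart and 3 from the ends — under
about two backbone genes between islands the flanking block between them
cannot form and adjacent islands legitimately fuse, which the exact-
boundary tests deliberately avoid generating.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive (GenBank convention); compound (join)
  locations collapse to their outer span — rank order, not exon structure,
  drives the method. Circular replicons are linearized at the annotation
  origin, so wrap-around blocks and breaks are not called (a documented
  limitation; actinobacterial chromosomes are linear).
* Gene identity is the locus tag, falling back to protein id, then a
  positional synthetic id; duplicate tags are a hard error. `source` and
  `gene` records are skipped (the latter would duplicate CDS locus tags).
* Pseudo-genes and CDSs without a given or derivable (code 11)
  translation are excluded with a message.
* GC fractions exclude ambiguous bases from numerator and denominator; an
  all-ambiguous span is an error, and an empty island side reports ΔGC as
  absent rather than 0.
* Stable identifiers (blocks, islands, config snapshots) are FNV-1a
  hashes of boundary feature ids, so ids survive re-runs and database
  rebuilds; islands never depend on row order.
* The pipeline contains no randomness: identical inputs and configuration
  give byte-identical exports, which the test suite asserts.

## Known limitations

* Strictly pairwise orthology; no orthogroups or phylogenetic orthology.
  Hotspot projection degrades when boundary genes lack reference
  orthologs.
* The relational store is an in-memory object with CSV/JSON export rather
  than an embedded SQL database; exports carry a config hash for
  provenance, and determinism substitutes for transactional identity.
* E-values from the built-in aligner are approximate (fixed λ, K); counts
  derived from them can differ from a full search engine's at the
  threshold margin.
* Multi-contig drafts are supported (links never cross contigs), but
  heavy fragmentation shortens blocks and inflates break counts, as with
  any synteny method.
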