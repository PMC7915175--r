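---
title: "Methods: repeat annotation, divergence landscapes and synteny net-graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repeat annotation, divergence landscapes and synteny net-graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repeatscape)
```

`repeatscape` reimplements, at desk scale, the repeat-element side of a
BAC-based cytogenomic chromosome study: homology annotation of pooled BAC
inserts against a TE consensus library, repeat statistics, Kimura-distance
copy-divergence landscapes (within and across species), and the
BAC–chromosome synteny net-graph. This vignette records the models, the
parameters that matter, and the design choices made where the design was
genuinely open.

## Annotation model

Annotation is homology-based only: there is no de novo repeat discovery.
Each consensus record (headers in the `name#class/family` dialect) is
compared with every target sequence on both strands by a seeded local
alignment:

1. **Seeding** — exact `seed_k`-mer matches (default 11; the sensitive
   preset uses 9). Seeds falling inside an already-extended candidate on a
   nearby diagonal are skipped.
2. **Extension** — ungapped X-drop extension (drop-off 12) grows each seed
   into a candidate interval.
3. **Refinement** — candidates are merged into windows (a margin of up to
   1 kb on either side) and re-aligned with full affine-gap
   Smith–Waterman. After each reported alignment the window is split at
   the reported interval and the two flanks are re-aligned, so several
   copies inside one window are all recovered.

Scoring is unit match/mismatch (+1/−1) with affine gaps: a gap of length
*L* costs `gap_open + L·gap_extend` (defaults −3, −1; the first gap column
pays both). A complexity-adjusted matrix is unnecessary here because
divergence is estimated from *counted substitution columns*, not from the
score; unit scoring finds copies comfortably beyond 30% divergence, which
is the edge of the landscape's informative range anyway. Alignment columns
are classified during traceback: transitions (A↔G, C↔T), transversions,
ambiguous (`N`, excluded from everything), and gap columns (tracked
separately). Hits below `min_score = 20` or shorter than
`min_length_bp = 50` are dropped.

Overlap resolution is greedy by descending score (ties: lower divergence
proportion, then lexicographic consensus name, then leftmost start). A
lower-scoring hit overlapping an accepted one keeps its non-overlapping
remainder only if each piece is at least `min_length_bp`; its column
counts are rescaled pro rata, which is an approximation — such pieces are
flagged `trimmed` and excluded from divergence landscapes entirely.

On planted-copy simulations (divergence up to 0.25, copy length ≥ 200 bp)
recall is ≥ 95% with interval Jaccard ≥ 0.9; the test suite checks the
engine's best local score against an independent dynamic-programming
oracle (`Biostrings::pairwiseAlignment`) on one hundred random instances.

## Kimura divergence and landscapes

For every untrimmed hit, with `sites` the aligned non-gap non-ambiguous
columns, `p = transitions/sites` and `q = transversions/sites`, the copy
divergence is the plain Kimura two-parameter correction

$$K = -\tfrac12 \ln\!\big((1 - 2p - q)\sqrt{1 - 2q}\big),$$

with no CpG adjustment (some landscape tools optionally apply one; plain
K2P is the choice here and is recorded in the landscape metadata). When
`1 − 2p − q ≤ 0` or `1 − 2q ≤ 0` the copy is *saturated*: it is excluded
from the bins but its length is reported, so binned bp + saturated bp
always equals the divergence-eligible annotated bp. Gap columns are
excluded from `sites` because indels carry no signal under K2P.

Landscapes put each copy's genomic length into percent-K bin
`floor(100·K)`, clamped at bin 50, per class/family; normalization is raw
bp or percent of analyzed length (both provided, since conventions vary).
The main peak is reported as a *plateau range*: per-bin totals are
smoothed with a centred, edge-truncated moving average (window 3), the
argmax bin taken (ties to the lower bin), and the maximal contiguous run
of bins at ≥ 80% of the smoothed maximum containing it is returned —
burst ages are better described by a range than a single bin.

Cross-species mode is the same composition (scan → resolve → K2P →
landscape) with a library of different provenance: typically one built by
`build_chromosome_library()`, which extracts every resolved hit's genomic
sequence (reverse-complemented on the minus strand), names it
`origName_seqid_start_end`, inherits the consensus class/family, and
dereplicates. Dereplication is greedy: records sorted by length
descending (ties by name), each joining the first retained representative
it matches at ≥ 95% identity over ≥ 90% of the shorter sequence, either
strand. Identity counts gap columns as mismatches, so indel-divergent
duplicates are kept apart. No tool-published thresholds exist for this
step; 0.95/0.90 are conventional clustering values and are exposed as
arguments. Hits are extracted without flanks.

Two estimator biases are worth knowing. First, local alignment trims
divergent alignment ends, biasing per-copy K̂ downward by roughly 5–8%
relative at K ≈ 0.2; in cross-species recovery (copy age 0.10 plus
consensus divergence 0.08) the modal bin lands at 16–17 rather than the
naively additive 18. Second, K2P distances compose additively only in
expectation, so the cross-species tolerance is ±2 bins.

## Simple repeats and low complexity

SSR detection reports maximal *perfect* tandem runs of primitive motifs of
length 1–6, extended into partial copies, at thresholds: total length
≥ 12 bp and minimum copies {mono 12, di 6, tri 4, tetra 3, penta 3,
hexa 3}. Motifs are canonicalised to the lexicographically minimal
rotation over both strands; runs explained by a shorter period are
suppressed. Imperfect (mismatch-tolerant) SSRs are out of scope — locus
counts and coverage are the quantities of interest, and perfect runs keep
an exact oracle possible. At these thresholds, chance tandem runs in
random DNA are expected at ~1–2 loci per 100 kb (dominated by minimal
12 bp tetramer runs, per-position probability ≈ 0.25⁸); that floor is a
property of the thresholds, not of the detector.

Low-complexity detection flags 64 bp windows whose base-2 Shannon entropy
over A/C/G/T frequencies falls below 1.2 bits, merging flags within 10 bp.
Uniform-random DNA is essentially never flagged (expected flagged
fraction ≪ 0.5%).

TE annotation takes precedence: SSR/low-complexity intervals overlapping
resolved TE loci are trimmed before statistics, so category coverages are
additive.

## Repeat statistics

A locus is one post-resolution hit. `analyzed_bp` is the full target
length including `N` runs (assembled BACs carry few; a flag excludes
them). NL/Mb is `loci × 10⁶ / analyzed_bp`; coverage merges intervals
before summing, as a percentage of `analyzed_bp`. The summary table
follows the conventional hierarchy — Retroelements split into SINEs (with
Penelope printed under SINEs, as repeat-summary tables conventionally do),
LINEs (L2/CR1/Rex, R1/LOA/Jockey, R2/R4/NeSL, RTE/Bov-B, L1/CIN4) and LTR
(BEL/Pao, Ty1/Copia, Gypsy/DIRS1, Retroviral); DNA transposons split into
hobo-Activator, Tc1-IS630-Pogo, PiggyBac, Tourist/Harbinger and Other —
plus rolling-circle, satellite, simple-repeat, low-complexity and
unclassified rows. Unmatched families fall to the nearest fallback row of
their class; a class with no row at all is a contract error, not a silent
drop.

## Synteny tallies and net-graphs

Placement tables carry one row per (BAC, gene, species); `SSE` rows are
home assignments, other species codes are syntenic placements. Tallies
count distinct genes per BAC, and distinct gene *symbols* per arm and
chromosome — adjacent overlapping clones annotating the same genes (as the
packaged table's 36H3/36H2 pair does) therefore contribute those genes
once to arm and chromosome totals, which is how chromosome gene totals
are conventionally reported. The packaged table reproduces its printed
totals exactly: 21 BACs, 154 genes, arms 66/19 (chromosome 2) and 12/57
(chromosome 4).

The net-graph is bipartite: one edge per (BAC, species, chromosome),
weighted by gene count, chromosome nodes species-qualified (`C9`-style) to
avoid label collisions. The layout is the classic Fruchterman–Reingold
algorithm on a square of area *n*: ideal length `k = C√(area/n)`,
repulsion `k²/d` between all pairs, attraction `d²/k` along edges,
per-iteration displacement capped at a temperature cooled *linearly* from
`start_temp = √n` to zero over `niter = 10000` iterations; initial
positions are uniform-random from a seed, and the result is deterministic
given (graph, seed, parameters). Whether edge weights should influence
the layout is genuinely open; since the graph's interpretation is that
BACs sharing more connections sit closer, attraction is scaled by
`weight/max(weight)` by default, with an unweighted switch. Only
inter-node distances are meaningful; orientation is arbitrary.

## The simulator, and what passing tests do not show

The generator plants divergence as realized substitution proportions:
`solve_pq()` inverts the K2P closed form (bisection, `|ΔK| ≤ 1e-13`) at a
transition/transversion ratio of 2.0 (a typical vertebrate neutral-site
value), and `mutate_copy()` applies per-site transitions/transversions and
geometric indels (length 1–3, rate 0.005 per column by default — small but
nonzero so gap handling is exercised). Truth K is therefore *exactly* the
closed form of the planted counts, giving an exact estimator oracle.
Copies are placed uniformly without overlap by rejection sampling, about
half on the minus strand; planted SSR truth records the maximal run after
placement, since background can extend a planted run by chance partial
copies. Species pairs mutate a shared ancestor consensus set by K = D/2
per species, so cross-annotation divergence is approximately copy age
plus D. Identical config and seed give byte-identical output.

The simulator emulates i.i.d. background at a configurable GC fraction
(default 0.44, fish-euchromatin-like), clean single-copy insertions and
perfect SSRs. It does **not** emulate TE nesting or fragmentation,
insertion-age population dynamics, CpG hypermutability, satellite
higher-order structure, or assembly artefacts. Passing recovery tests
therefore demonstrates correctness of the estimators under the stated
generative model, not performance on real BAC assemblies; numeric results
on real data will differ with the consensus library and engine settings
used.

## Problem sizes and numerical choices

The test suite and the acceptance script run simulations of 100–500 kb
with 20–200 planted copies per stage — sizes chosen so every stage's
statistical expectations (binomial substitution counts, Poisson locus
counts) are tight enough to assert against while the whole suite stays in
the minutes range on one core. Other numerics: alignment problems above
6×10⁸ cells are refused rather than silently thrashing; the K2P domain
boundary is treated as saturation, not error; `solve_pq` caps `q` just
inside the domain boundary and names the maximum attainable K in its
error; peak plateau fraction (0.8), entropy threshold (1.2 bits), and all
scan scores are exposed as arguments with the defaults above.

## Known limitations

Homology-only annotation misses families absent from the library;
pro-rata rescaling of trimmed hits is approximate (hence their exclusion
from landscapes); local-alignment end-trimming biases K̂ slightly
downward; perfect-only SSR detection undercounts degenerate
microsatellites; the chance-tandem floor of the SSR thresholds (~1–2
loci/100 kb) is irreducible without raising the thresholds; and the
fixed-seed layout, while deterministic, is only one local minimum of the
Fruchterman–Reingold energy.
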