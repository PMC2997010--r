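---
title: "Synteny block detection: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synteny block detection: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(syntenyr)
```

## The detection model

`syntenyr` works purely at gene-order resolution. The inputs are two gene
coordinate tables and an ortholog relation; nucleotide sequence never
enters detection. This is the classic anchor-based formulation: genes are
anchors, and a synteny block is a pair of contiguous gene intervals — one
per genome — whose anchors correspond.

Within a candidate interval pair, each gene is *matched* (it has an
ortholog inside the partner interval), an *in-map mismatch* (orthologs
exist but all lie elsewhere), or an *out-map mismatch* (no ortholog at
all). The distinction matters biologically: an out-map mismatch is a
species-specific gene or an annotation gap, while an in-map mismatch marks
a conserved gene that a rearrangement carried away. The two types therefore
get independent caps.

The validity predicate (condition by condition, the order diagnostics use):

1. **Size.** Matched genes per side must lie in `[min_size, max_size]`.
   `min_size` counts *matched* genes, not interval genes: a "block of two
   genes" means two genes of conserved content, however many mismatches the
   caps let in around them.
2. **Out-map caps.** Per side, the out-map mismatch count must satisfy both
   the absolute cap (`out_map_max`, flag `-o`) and the percentage cap
   (`out_map_pct`, flag `-op`) of *that interval's* total gene count.
3. **In-map caps.** Same, with `in_map_max` / `in_map_pct` (`-i` / `-ip`).
4. **Order and strandedness.** There must exist a selection of ortholog
   pairs inside the candidate that covers every matched gene on both sides
   and forms a monotone staircase compatible with the mode.

Both the count cap *and* the percentage cap must hold, on *both* sides, and
the percentage denominator is the interval's total gene count (mismatches
included). Other denominators (matched genes only, or the two sides
pooled) were considered; the per-interval total is the reading that makes
"5% mismatches" describe what a browser screenshot of the block shows.

### Order/strand coupling

Rearrangements leave two clean signatures: a conserved segment (colinear
order, consistent strand relation per pair) and an inversion (reversed
order *and* reversed strand relation). Mode `rs` admits exactly these two.
Mode `r-s` decouples the two axes — any of the four order-by-strand
combinations, with the strand relation still uniform within a block — and
`free` drops both constraints, which is the setting that merges regions
interrupted by single-gene strand flips.

The existence check in condition 4 is a reachability sweep over the grid of
in-interval ortholog pairs (rows = matched genes of one side in order,
columns = the other): a valid selection is a staircase from the top-left to
the bottom-right cell moving down, right, or diagonally through admitted
pairs. Horizontal/vertical steps make several adjacent genes share one
partner, which is exactly a tandem array — so tandem expansions and
contractions stay inside one block rather than fragmenting it. The naive
reading "one partner per gene, strictly monotone" breaks the symmetry of
the two genomes as soon as a one-to-many family appears on the second
side; the staircase formulation is symmetric, and the test suite checks
genome-swap symmetry explicitly, plus equivalence against brute-force
enumeration over partner selections on small instances.

### Maximality and nesting

Detection reports every valid candidate that is *containment-maximal*: no
other valid candidate contains both of its intervals. Single-gene
extension-maximality, the more operational phrasing, is equivalent: any
valid candidate grows by single-gene steps into an extension-maximal valid
superset, so the maximal sets coincide. Overlapping maximal blocks are all
reported (coverage uses span unions, so nothing is double counted).

A reported block is **nested** when its interval in one genome sits
strictly inside a larger block's interval while its partner interval is
disjoint from that block — a segmental duplication carried the copy
elsewhere. `parent_id` names the containing block (the largest when
several qualify).

Blocks never span chromosome boundaries; chromosome assignment of inputs is
taken at face value, and unplaced scaffolds are simply chromosomes with
their own names.

### The enumeration oracle

`enumerate_blocks_oracle()` computes the same result by enumerating every
interval pair and applying the validity predicate, with its own independent
maximality filter. It is quartic in chromosome length and exists to verify
`find_synteny_blocks()`, whose pruned search must match it exactly — the
acceptance suite compares the two on 200 random instances across the
parameter grid (mismatch caps 0–3 and 0–50%, all three modes). Instance
sizes are drawn mostly between 6 and 16 genes per genome with a tail up to
30; beyond that the oracle's enumeration, not the search, dominates run
time without adding distinct structure.

## Parameters at a glance

| Parameter | Flag | Unit | Default | Notes |
|---|---|---|---|---|
| `min_size` | `--min-size` | matched genes | 2 | the "at least two genes" of a perfect block |
| `max_size` | `--max-size` | matched genes | unlimited | |
| `in_map_max` | `-i` | genes | 0 | absolute cap per side |
| `in_map_pct` | `--ip` | % of interval genes | 0 | joint with `-i` |
| `out_map_max` | `-o` | genes | 0 | e.g. 20 when hunting annotation gaps |
| `out_map_pct` | `--op` | % of interval genes | 0 | |
| `mode` | `--mode` | — | `rs` | `rs`, `r-s`, `free` |

Defaults reproduce perfect-block detection. Percentage caps use a `1e-9`
absolute tolerance so that "1 mismatch in 20 genes at 5%" sits on the legal
side of the boundary despite floating-point division.

## Downstream statistics

* **Coverage** is the union of block bp spans over the chromosome length
  (`IRanges::reduce`), length-weighted for the genome total; a per-bp
  bitmap oracle in the tests confirms it to 1 bp. Degenerate single-gene
  "blocks" (isolated in-map genes) can be included for the accounting view
  that asks how much conserved content exists outside multi-gene blocks.
* **Size comparisons** use the Mann-Whitney U test via `wilcox.test`:
  exact when both groups have ≤ 20 observations without ties, otherwise
  the tie-corrected normal approximation with continuity correction. The
  two branches agree within 0.01 at the crossover in the tests.
* **Random breakage.** The null places `k − 1` breakpoints uniformly on
  the concatenated genome, where `k` is the *observed* number of
  non-nested blocks, and asks how often the maximal segment reaches the
  observed block span; the p-value carries a pseudo-count of one on both
  numerator and denominator so it is never exactly zero. All spans tested
  in one call share one null sample — semantically identical to per-block
  simulation and far cheaper. Multiple testing uses Benjamini–Hochberg by
  default (Bonferroni by flag): block-size significance is a screening
  question, where FDR control is the convention. Calibration is part of
  acceptance: spans generated *by* the null survive BH at α = 0.05 in at
  least 94% of 50 seeded runs, and a planted block covering 30% of the
  genome among 100 is rejected at p < 0.01.
* **Regions.** Arm/center analyses assign each block to the region holding
  its midpoint; region boundaries are user input, never hard-coded.
* **Operons.** A *conserved* operon has every member gene matched within a
  single block; this containment definition is a package choice (the
  literature quantifies operon conservation by other means), so a
  user-supplied conserved-operon list is accepted everywhere the
  definition would otherwise bind. An *operonic* block has at least half
  of its interval genes (mismatches in the denominator) in conserved
  operons — boundary inclusive, threshold configurable.
* **Tandem asymmetries** are connected components of the ortholog relation
  inside a block with unequal gene counts whose runs are
  adjacency-contiguous on both sides; interleaved families are reported
  separately only on request (`include_loose`).

## Annotation refinement

Out-map mismatches inside blocks are where synteny localizes missing or
broken gene models: the block's partner interval is the search space handed
to an external spliced aligner (the package deliberately does not align —
the contribution is the decision procedure, and prediction records are a
plain TSV any aligner can produce). Records covering less than 60% of the
query protein, or containing internal stops, are dropped (boundary
inclusive, configurable).

The classifier then applies, in order: one prediction spanning several
poorly-supported or out-map models → **merge**; two or more predictions
from distinct queries tiling a single model essentially without mutual
overlap (tolerance: 10% of the shorter prediction) → **split**; a single
prediction covering at least the threshold of an out-map model →
**replace**; no gene overlap at all → **new gene**; everything else →
discard with a recorded reason, including any hit on an in-map model that
is already well covered. Each existing model is touched by at most one
action; `apply_actions()` enforces this and the bookkeeping identity
`initial − deleted + added = final` on every run. New ids are minted under
a configurable prefix. Accepted ortholog pairs require PID ≥ 40% and
e-value ≤ 1e-10, both inclusive; PID comes from a global Needleman–Wunsch
alignment (BLOSUM62, gap opening 10, extension 0.5, all configurable) as
identical positions over alignment columns, and e-values are always taken
from the aligner, never recomputed.

## What the simulator emulates — and what it does not

`generate_ancestor()` lays out genes with gamma-distributed lengths
(shape 2, mean 3 kb) and intergaps (shape 1.5, mean 2 kb) — about one gene
per 5 kb, so kb-denominated statistics land in a nematode-like regime.
These are configuration values, not constants. `apply_script()` derives a
second genome through inversions, transpositions, deletions, insertions,
tandem and segmental duplications and reciprocal translocations, tracking
every gene's ancestral source, and emits the exact set of maximal perfect
blocks (mode `rs`, zero mismatches, minimum size 2) this history implies,
with orientations and nested flags. `random_script()` keeps operation
footprints at least `margin` genes apart so planted events cannot interact;
truth ledgers are only exact under that spacing, which is the regime the
recovery tests use. Ledgers for relaxed parameters are derived on demand by
the oracle rather than stored. `inject_defects()` plants fused models,
fissioned models and dropped ortholog pairs with the corrective action
recorded, and `make_operons()` plants 2–8-gene operons.

What passing these tests shows: the implementation realizes its stated
semantics exactly, on genomes whose rearrangement history is known. What
it does not show: performance of the semantics on real annotations, where
ortholog calls are noisy, rearrangements overlap and nest, gene models err
in ways richer than three defect classes, and paralogy is pervasive. The
simulator makes no attempt at nucleotide sequences, realistic gene-family
birth–death, or biased rearrangement size spectra.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive throughout (GFF3 convention); BED
  export converts to 0-based half-open at the boundary. Coordinate 0 is
  rejected on input.
* Gene order is the total order `(start, end, gene_id)` per chromosome, so
  any row permutation of an input file reads back identically. "Longest
  isoform" in GFF3 reduction means greatest summed CDS length, ties broken
  by genomic span then isoform id.
* Detection is fully deterministic: blocks are ordered by A-chromosome,
  A-start, then interval bounds, and ids (`SB0001`, …) follow that order.
  Orientation/strand labels use a fixed preference order (colinear before
  inverted, consistent before reversed), so a two-gene block that could be
  read either way is always labelled the same.
* Empty genomes or empty correspondences yield empty block sets, not
  errors; empty groups in statistics raise errors instead of NaNs.
* Every stochastic routine takes an explicit seed and restores the
  caller's RNG state.

## Known limitations

* Complexity targets desk-scale and test-scale inputs (the search is
  polynomial but unoptimized R; ~10^5 genes is out of scope, as is
  multi-genome (>2) detection).
* One-to-many relations are taken as given; no attempt is made to
  distinguish orthology from paralogy beyond the correspondence file.
* The refinement decision tree resolves only the defect classes it can
  see; predictions consistent with several interpretations are discarded
  as ambiguous rather than guessed, and "special cases" are left to manual
  review by design.
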