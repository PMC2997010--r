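# syntenyr

Anchor-based synteny block detection and analysis for gene-order genomes.

Two related genomes — say a pair of *Caenorhabditis* nematodes — share long
stretches in which gene content, order and strandedness are conserved.
Finding those stretches is the first step of most comparative-genomics
analyses: they reveal genome rearrangement events (inversions, insertions,
deletions, transpositions, segmental duplications), they constrain where a
missing or mis-annotated gene model must lie, and their size distribution
tests hypotheses such as the random breakage model of chromosome evolution.
`syntenyr` is for comparative genomicists who have two gene-coordinate
tables and an ortholog table (e.g. from InParanoid or OrthoFinder) and want
the blocks, the downstream statistics, and a reproducible way to test the
whole pipeline on synthetic genomes with known ground truth.

## The model

Genes are *anchors*. Given genomes \(G_1, G_2\) and an ortholog relation
\(R \subseteq G_1 \times G_2\) (one-to-many allowed), a gene is **in-map**
if it has at least one partner under \(R\) and **out-map** otherwise. A
*candidate block* is a pair of contiguous gene intervals \((A_1, A_2)\),
one per genome. Genes inside an interval partition into

* **matched** genes — at least one partner inside the partner interval;
* **in-map mismatches** — partners exist, but all lie outside \(A_2\)
  (conserved genes stranded elsewhere, e.g. by a transposition);
* **out-map mismatches** — no partner anywhere (species-specific genes, or
  annotation gaps).

A candidate is a **synteny block** when, on *each* side,

1. the matched-gene count lies in `[min_size, max_size]` (default ≥ 2);
2. out-map mismatches satisfy `-o` (count cap) *and* `-op` (% of the
   interval's genes);
3. in-map mismatches satisfy `-i` and `-ip` likewise;
4. a covering, monotone selection of ortholog pairs exists whose order and
   strand pattern the chosen *mode* admits:
   * `rs` — colinear order with consistent strands, or inverted order with
     reversed strands (the two signatures rearrangements actually leave);
   * `r-s` — all four order × strand combinations, strand relation uniform
     within the block;
   * `free` — no order or strand constraint.

The monotone-selection step handles tandem arrays: several adjacent genes
sharing one partner count as one step of the staircase, so lineage-specific
family expansions stay inside a block. Detection reports **all maximal**
valid candidates (none contained, both intervals, in another). A block
whose interval in one genome lies inside a larger block while its partner
interval lies elsewhere is flagged **nested** — the signature of a
segmental duplication. With zero mismatch caps and mode `rs` the blocks are
*perfect*: gene content, order and strandedness fully conserved.

Every result is an ordinary tibble, so the whole toolkit composes with
dplyr pipelines; `enumerate_blocks_oracle()` re-derives the same answer by
exhaustive enumeration and is used throughout the test suite to verify the
search.

## Worked example

A nine-gene region with one-to-one orthologs in identical order; the
ortholog of gene 6 is strand-inverted. Strict detection refuses to bridge
the strand break:

```r
library(syntenyr)
library(dplyr)

ext <- function(f) system.file("extdata", f, package = "syntenyr")
genome_a <- read_genome_table(ext("toy_genome_a.tsv"), "elegans_like")
genome_b <- read_genome_table(ext("toy_genome_b.tsv"), "briggsae_like")
orth     <- read_correspondence(ext("toy_orthologs.tsv"), genome_a, genome_b)

blocks <- find_synteny_blocks(genome_a, genome_b, orth,
                              detection_params(mode = "rs"))
blocks %>% select(block_id, chrom_a, a_start, a_end,
                  n_matched_a, orientation, strand_pattern)
#> # 2 synteny block(s) [elegans_like vs briggsae_like], 0 nested
#> # A tibble: 2 × 7
#>   block_id chrom_a a_start a_end n_matched_a orientation strand_pattern
#> 1 SB0001   chrIII     1000 23999           5 colinear    consistent
#> 2 SB0002   chrIII    31000 43999           3 colinear    consistent
```

Two perfect blocks, of 5 and 3 genes, separated by the single gene whose
ortholog is inverted — it is in-map, so no mismatch allowance can absorb
it; only relaxing the order/strand coupling merges the region:

```r
free <- find_synteny_blocks(genome_a, genome_b, orth,
                            detection_params(mode = "free"))
glance(free)
#> # A tibble: 1 × 6
#>   n_blocks n_nested n_matched_genes_a n_matched_genes_b mean_span_kb median_span_kb
#> 1        1        0                 9                 9           43           43
```

Coverage accounting uses bp-span unions, so overlapping blocks are not
double counted:

```r
genome_coverage(blocks, genome_a, side = "a")
#> # A tibble: 2 × 4
#>   chrom  length_bp covered_bp coverage_pct
#> 1 chrIII     43999      36000         81.8
#> 2 TOTAL      43999      36000         81.8
```

The two strict blocks span 36 kb of the 44 kb region (81.8%); the matched
gene counts (5 and 3) are the numbers a curator would read off a genome
browser view of this region.

Downstream: `block_size_stats()`, `distribution_matrix()` (chromosome-by-
chromosome counts with nested blocks in parentheses), `compare_block_sizes()`
(Mann-Whitney, e.g. X vs autosomes), `random_breakage_test()`,
`conserved_operons()` / `operonic_blocks()`, `tandem_asymmetries()`, and the
annotation-refinement engine `outmap_candidates()` → `filter_predictions()`
→ `classify_predictions()` → `apply_actions()` → `assign_orthologs()`.
The simulator (`generate_ancestor()`, `random_script()`, `apply_script()`,
`inject_defects()`, `make_operons()`) produces genome pairs with a planted
truth ledger for all of it.

A command-line interface wraps the same functions:

```sh
syntenyr detect --genome-a a.tsv --genome-b b.tsv --corr orth.tsv \
         -i 0 --ip 0 -o 0 --op 0 --mode rs --out-dir out/
syntenyr simulate --chromosomes 2 --genes 20 --ops 3 --seed 1 --out-dir sim/
```

Every run writes a `provenance.json` with parameters, seeds and input
checksums.

## File formats

* **Genome TSV** — 5 columns: gene id, chromosome/supercontig, start, end
  (1-based inclusive), strand (`+`/`-`). Header optional, `#` comments.
* **GFF3** — `read_gff3_genome()` reduces each gene locus to its longest
  isoform (greatest summed CDS length).
* **Correspondence TSV** — two columns of gene ids; duplicates collapsed;
  one-to-many allowed. (From InParanoid output, export each ortholog pair
  of every cluster as one row.)
* **Operon TSV** — operon id, tab, comma-separated member gene ids.
* **Blocks** — TSV (full ledger per row, round-trips through
  `read_blocks()`) or BED (two records per block, 0-based half-open).

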