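test_that("ancestor generation is deterministic and honors the spec", {
  spec <- ancestor_spec(n_chrom = 2, genes_per_chrom = c(8, 6), seed = 11)
  g1 <- generate_ancestor(spec)
  g2 <- generate_ancestor(spec)
  expect_equal(tibble::as_tibble(g1), tibble::as_tibble(g2))
  expect_equal(nrow(g1), 14L)
  expect_equal(dplyr::n_distinct(g1$chrom), 2L)
  # byte-identical serialization under a fixed seed
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_genome_table(g1, p1); write_genome_table(g2, p2)
  expect_identical(readLines(p1), readLines(p2))
  # non-overlapping sorted coordinates per chromosome
  for (cc in unique(g1$chrom)) {
    d <- g1[g1$chrom == cc, ]
    expect_true(all(diff(d$start) > 0))
    expect_true(all(d$start[-1] > d$end[-nrow(d)]))
  }
})

test_that("gene and gap lengths follow the spec distributions", {
  # pooled two-sample comparison against an independently drawn reference,
  # over many seeds (KS on the continuous pre-discretization scale)
  gaps <- unlist(lapply(1:50, function(s) {
    g <- generate_ancestor(ancestor_spec(n_chrom = 1, genes_per_chrom = 12,
                                         seed = 1000 + s))
    g$start[-1] - g$end[-nrow(g)] - 1
  }))
  ref <- with_seed2(77, pmax(50, round(rgamma(length(gaps), shape = 1.5,
                                              scale = 2000 / 1.5))))
  ks <- suppressWarnings(stats::ks.test(gaps + runif(length(gaps)),
                                        ref + runif(length(ref))))
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(gaps) - 2000) / 2000, 0.15)
})

test_that("an empty script yields one truth block per chromosome", {
  anc <- generate_ancestor(ancestor_spec(n_chrom = 2, genes_per_chrom = 6, seed = 3))
  sim <- apply_script(anc, list())
  expect_equal(nrow(sim$truth$blocks), 2L)
  expect_equal(sim$truth$blocks$n_a, c(6L, 6L))
  expect_equal(nrow(sim$corr), 12L)
  found <- find_synteny_blocks(anc, sim$genome, sim$corr, detection_params(mode = "rs"))
  expect_equal(nrow(found), 2L)
  expect_equal(found$n_matched_a, c(6L, 6L))
})

test_that("a mid-chromosome inversion produces two flanks plus an inverted block", {
  anc <- generate_ancestor(ancestor_spec(n_chrom = 1, genes_per_chrom = 10, seed = 5))
  sim <- apply_script(anc, list(op_inversion("chr01", 4, 3)))
  tb <- sim$truth$blocks
  expect_equal(nrow(tb), 3L)
  expect_equal(tb$orientation, c("colinear", "inverted", "colinear"))
  expect_equal(tb[tb$orientation == "inverted", ]$a_first, 4L)
  expect_equal(tb[tb$orientation == "inverted", ]$a_last, 6L)
  found <- find_synteny_blocks(anc, sim$genome, sim$corr, detection_params(mode = "rs"))
  expect_equal(nrow(found), 3L)
  expect_equal(sort(found$orientation), sort(tb$orientation))
})

test_that("a segmental duplication plants exactly one nested truth block", {
  anc <- generate_ancestor(ancestor_spec(n_chrom = 2, genes_per_chrom = 10, seed = 7))
  sim <- apply_script(anc, list(op_segmental_duplication("chr01", 4, 3, "chr02", 5)))
  tb <- sim$truth$blocks
  expect_equal(sum(tb$nested), 1L)
  nested <- tb[tb$nested, ]
  expect_equal(nested$chrom_a, "chr01")
  expect_equal(c(nested$a_first, nested$a_last), c(4L, 6L))
  expect_equal(nested$chrom_b, "chr02")
  found <- find_synteny_blocks(anc, sim$genome, sim$corr, detection_params(mode = "rs"))
  expect_equal(sum(found$nested), 1L)
})

test_that("detection recovers the truth ledger exactly on spaced random scripts", {
  for (seed in 1:8) {
    anc <- generate_ancestor(ancestor_spec(n_chrom = 2, genes_per_chrom = 14,
                                           seed = seed * 13))
    script <- random_script(anc, n_ops = 3, seed = seed * 13 + 1)
    sim <- apply_script(anc, script, seed = seed * 13 + 2)
    found <- find_synteny_blocks(anc, sim$genome, sim$corr,
                                 detection_params(mode = "rs"))
    got <- plain_blocks(found)[, c("chrom_a", "a_first", "a_last", "chrom_b",
                                   "b_first", "b_last", "orientation", "nested")]
    want <- tibble::as_tibble(sim$truth$blocks)[, names(got)]
    expect_equal(got, want, info = sprintf("seed %d", seed))
  }
})

test_that("insertions and deletions register as out-map genes in the ledger", {
  anc <- generate_ancestor(ancestor_spec(n_chrom = 1, genes_per_chrom = 12, seed = 9))
  sim <- apply_script(anc, list(op_deletion("chr01", 3, 1), op_insertion("chr01", 7, 2)))
  expect_equal(sim$truth$out_map_a, anc$gene_id[3])
  expect_equal(length(sim$truth$out_map_b), 2L)
  st <- classify_markers(anc, sim$genome, sim$corr)
  expect_setequal(st$gene_id[st$status == "out_map" & st$genome == "A"],
                  sim$truth$out_map_a)
  expect_setequal(st$gene_id[st$status == "out_map" & st$genome == "B"],
                  sim$truth$out_map_b)
})

test_that("a single-gene tandem duplication stays inside one block", {
  anc <- generate_ancestor(ancestor_spec(n_chrom = 1, genes_per_chrom = 10, seed = 15))
  sim <- apply_script(anc, list(op_tandem_duplication("chr01", 5, 1, copies = 2)))
  tb <- sim$truth$blocks
  expect_equal(nrow(tb), 1L)
  expect_equal(tb$n_a, 10L)
  expect_equal(tb$n_b, 12L)
  expect_equal(sim$truth$tandem$n_copies, 3L)
  found <- find_synteny_blocks(anc, sim$genome, sim$corr, detection_params(mode = "rs"))
  expect_equal(nrow(found), 1L)
  expect_equal(found$n_matched_b, 12L)
})

test_that("operation errors name the offending op", {
  anc <- generate_ancestor(ancestor_spec(n_chrom = 1, genes_per_chrom = 5, seed = 2))
  expect_error(apply_script(anc, list(op_inversion("chr01", 4, 5))), "operation 1")
  expect_error(apply_script(anc, list(op_inversion("chr01", 1, 2),
                                      op_deletion("chr01", 9, 1))), "operation 2")
})

test_that("defect injection is identity at rate zero and tracks its ledger", {
  ids <- toy_identity(12)
  none <- inject_defects(ids$gb, ids$corr, list(), seed = 1)
  expect_equal(tibble::as_tibble(none$genome), tibble::as_tibble(ids$gb))
  expect_equal(nrow(none$defects), 0L)

  one <- inject_defects(ids$gb, ids$corr, list(split = 0.15), seed = 4)
  if (nrow(one$defects)) {
    # every fusion removes two models and adds one, and orphans two A genes
    st <- classify_markers(ids$ga, one$genome, one$corr)
    orphans_a <- st$gene_id[st$genome == "A" & st$status == "out_map"]
    expect_setequal(orphans_a, unlist(one$defects$query_genes))
    expect_equal(nrow(one$genome), nrow(ids$gb) - nrow(one$defects))
  }
})

test_that("defect counts scale with the injection rate", {
  rate <- 0.25
  counts <- vapply(1:30, function(s) {
    ids <- toy_identity(20)
    nrow(inject_defects(ids$gb, ids$corr, list(drop_ortholog = rate), seed = s)$defects)
  }, numeric(1))
  # eligible sites are thinned by the one-gene buffer; accept a broad band
  expect_gt(mean(counts), 20 * rate * 0.4)
  expect_lt(mean(counts), 20 * rate * 1.6)
})

test_that("planted operons are adjacent, sized in range, non-overlapping", {
  g <- generate_ancestor(ancestor_spec(n_chrom = 2, genes_per_chrom = 20, seed = 21))
  ops <- make_operons(g, 4, size_range = c(2, 5), seed = 3)
  expect_equal(dplyr::n_distinct(ops$operon_id), 4L)
  sizes <- table(ops$operon_id)
  expect_true(all(sizes >= 2 & sizes <= 5))
  expect_equal(anyDuplicated(ops$gene_id), 0L)
  expect_silent(syntenyr:::check_operons(ops, g))
  expect_equal(nrow(make_operons(g, 0)), 0L)
})
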