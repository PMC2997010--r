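test_that("two identical genomes yield one block containing every gene", {
  for (n in c(2, 5, 9)) {
    ids <- toy_identity(n)
    b <- find_synteny_blocks(ids$ga, ids$gb, ids$corr)
    expect_equal(nrow(b), 1L)
    expect_equal(b$n_matched_a, n)
    expect_equal(b$n_matched_b, n)
    expect_equal(b$orientation, "colinear")
    expect_equal(b$in_mm_a + b$out_mm_a + b$in_mm_b + b$out_mm_b, 0L)
  }
})

test_that("one strand-inverted ortholog splits a nine-gene region into 5 + 3", {
  toy <- toy_strandflip()
  strict <- find_synteny_blocks(toy$ga, toy$gb, toy$corr, detection_params(mode = "rs"))
  expect_equal(nrow(strict), 2L)
  expect_equal(sort(strict$n_matched_a), c(3L, 5L))
  # the two blocks are separated by exactly the in-map gene at position 6
  expect_equal(sort(c(strict$a_first, strict$a_last)), c(1L, 5L, 7L, 9L))
  # uniform-strand relaxation alone does not merge them
  rel_order <- find_synteny_blocks(toy$ga, toy$gb, toy$corr, detection_params(mode = "r-s"))
  expect_equal(sort(rel_order$n_matched_a), c(3L, 5L))
  # dropping the order/strand constraints merges everything into one block
  free <- find_synteny_blocks(toy$ga, toy$gb, toy$corr, detection_params(mode = "free"))
  expect_equal(nrow(free), 1L)
  expect_equal(free$n_matched_a, 9L)
})

test_that("a planted inversion is reported as an inverted-orientation block", {
  n <- 10
  ga <- toy_genome("A", rep("+", n))
  strands_b <- rep("+", n); strands_b[4:6] <- "-"
  gb <- toy_genome("B", strands_b)
  # genes 4:6 of B carry the orthologs of A's 6:4 (order and strand reversed)
  corr <- tibble::tibble(gene_a = ga$gene_id[c(1:3, 6:4, 7:10)],
                         gene_b = gb$gene_id)
  b <- find_synteny_blocks(ga, gb, corr, detection_params(mode = "rs"))
  expect_equal(nrow(b), 3L)
  expect_equal(b$orientation[b$a_first == 4], "inverted")
  expect_equal(b$strand_pattern[b$a_first == 4], "reversed")
  expect_equal(sort(b$n_matched_a), c(3L, 3L, 4L))
})

test_that("a segmental duplication appears as a nested block with its parent", {
  n <- 10
  ga <- toy_genome("A", rep("+", n), chrom = "chr01")
  gb_main <- toy_genome("B", rep("+", n), chrom = "chr01")
  dup <- toy_genome("Bdup", rep("+", 3), chrom = "chr02")
  gb <- as_genome(dplyr::bind_rows(tibble::as_tibble(gb_main),
                                   tibble::as_tibble(dup)), "B")
  corr <- dplyr::bind_rows(
    tibble::tibble(gene_a = ga$gene_id, gene_b = gb_main$gene_id),
    tibble::tibble(gene_a = ga$gene_id[3:5], gene_b = dup$gene_id))
  b <- find_synteny_blocks(ga, gb, corr, detection_params(mode = "rs"))
  expect_equal(nrow(b), 2L)
  big <- b[b$n_matched_a == 10, ]; small <- b[b$n_matched_a == 3, ]
  expect_false(big$nested)
  expect_true(small$nested)
  expect_equal(small$parent_id, big$block_id)
  expect_equal(small$chrom_b, "chr02")
  # nested + non-nested = total
  expect_equal(sum(b$nested) + sum(!b$nested), nrow(b))
})

test_that("detection is symmetric in the two genomes", {
  for (seed in 1:6) {
    inst <- random_instance(seed + 50, max_genes = 10)
    params <- random_params(seed + 50)
    fwd <- find_synteny_blocks(inst$ga, inst$gb, inst$corr, params)
    rev <- find_synteny_blocks(inst$gb, inst$ga,
                               tibble::tibble(gene_a = inst$corr$gene_b,
                                              gene_b = inst$corr$gene_a), params)
    key_fwd <- sort(sprintf("%s:%d-%d|%s:%d-%d", fwd$chrom_a, fwd$a_first, fwd$a_last,
                            fwd$chrom_b, fwd$b_first, fwd$b_last))
    key_rev <- sort(sprintf("%s:%d-%d|%s:%d-%d", rev$chrom_b, rev$b_first, rev$b_last,
                            rev$chrom_a, rev$a_first, rev$a_last))
    expect_equal(key_rev, key_fwd)
    expect_equal(sort(rev$orientation), sort(fwd$orientation))
  }
})

test_that("blocks admitted by stricter modes remain valid under looser modes", {
  for (seed in 1:4) {
    inst <- random_instance(seed + 70, max_genes = 10)
    b_rs <- find_synteny_blocks(inst$ga, inst$gb, inst$corr, detection_params(mode = "rs"))
    for (mode in c("r-s", "free")) {
      params <- detection_params(mode = mode)
      for (k in seq_len(nrow(b_rs))) {
        v <- validate_block(inst$ga, inst$gb, inst$corr,
                            b_rs[k, c("chrom_a", "a_first", "a_last",
                                      "chrom_b", "b_first", "b_last")], params)
        expect_true(v$valid)
      }
    }
  }
})

test_that("perfect-parameter blocks carry empty mismatch ledgers", {
  for (seed in 1:5) {
    inst <- random_instance(seed + 90, max_genes = 12)
    b <- find_synteny_blocks(inst$ga, inst$gb, inst$corr, detection_params(mode = "rs"))
    if (!nrow(b)) next
    expect_true(all(b$in_mm_a + b$out_mm_a + b$in_mm_b + b$out_mm_b == 0))
    expect_true(all(b$strand_pattern != "mixed"))
    expect_true(all(vapply(b$mm_genes, function(m) sum(lengths(m)), numeric(1)) == 0))
  }
})

test_that("covered genes grow monotonically with any mismatch cap", {
  covered_genes <- function(b, inst) {
    idx <- syntenyr:::genome_index(inst$ga)
    unlist(lapply(seq_len(nrow(b)), function(k)
      idx$by_chrom[[b$chrom_a[k]]]$gene_id[b$a_first[k]:b$a_last[k]]))
  }
  for (seed in 1:4) {
    inst <- random_instance(seed + 110, max_genes = 12)
    prev <- character(0)
    for (cap in 0:3) {
      b <- find_synteny_blocks(inst$ga, inst$gb, inst$corr,
                               detection_params(in_map_max = cap, in_map_pct = 50,
                                                out_map_max = cap, out_map_pct = 50,
                                                mode = "rs"))
      cur <- unique(covered_genes(b, inst))
      expect_true(all(prev %in% cur),
                  info = sprintf("seed %d cap %d lost covered genes", seed, cap))
      prev <- cur
    }
  }
})

test_that("singleton blocks cover isolated in-map genes only", {
  toy <- toy_strandflip()
  b <- find_synteny_blocks(toy$ga, toy$gb, toy$corr, detection_params(mode = "rs"))
  s <- singleton_blocks(toy$ga, toy$gb, toy$corr, b)
  # gene 6 on both genomes is in-map but belongs to no block
  expect_equal(sort(s$gene_id), sort(c("GA_g06", "GB_g06")))
  # coverage with singletons never decreases
  cov0 <- genome_coverage(b, toy$ga, "a")
  cov1 <- genome_coverage(b, toy$ga, "a", singletons = s)
  expect_true(all(cov1$coverage_pct >= cov0$coverage_pct - 1e-9))
  # a fully covered genome yields no singletons
  ids <- toy_identity(5)
  b2 <- find_synteny_blocks(ids$ga, ids$gb, ids$corr)
  expect_equal(nrow(singleton_blocks(ids$ga, ids$gb, ids$corr, b2)), 0L)
})
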