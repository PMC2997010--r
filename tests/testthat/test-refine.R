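test_that("out-map candidates enumerate the mismatch ledger with its target regions", {
  toy <- toy_strandflip()
  corr <- toy$corr[-4, ]  # GA_g04 / GB_g04 both become out-map
  params <- detection_params(out_map_max = 2, out_map_pct = 25, mode = "rs")
  blocks <- find_synteny_blocks(toy$ga, toy$gb, corr, params)
  cand <- outmap_candidates(blocks, toy$ga, toy$gb)
  # candidate count equals the total out-map ledger entries across blocks
  expect_equal(nrow(cand), sum(blocks$out_mm_a + blocks$out_mm_b))
  expect_true(all(c("GA_g04", "GB_g04") %in% cand$query_gene))
  a_cand <- cand[cand$query_gene == "GA_g04", ]
  expect_equal(a_cand$target_genome, "B")
  blk <- blocks[blocks$block_id == a_cand$block_id, ]
  expect_equal(a_cand$target_start, blk$b_start)
  expect_equal(a_cand$target_end, blk$b_end)
  # blocks without out-map mismatches contribute nothing
  perfect <- find_synteny_blocks(toy$ga, toy$gb, toy$corr, detection_params(mode = "rs"))
  expect_equal(nrow(outmap_candidates(perfect, toy$ga, toy$gb)), 0L)
})

test_that("prediction filtering applies the coverage boundary inclusively", {
  rec <- tibble::tibble(prediction_id = sprintf("p%d", 1:4),
                        query_coverage = c(0.59, 0.60, 0.95, 0.80),
                        has_internal_stop = c(FALSE, FALSE, TRUE, FALSE))
  kept <- filter_predictions(rec)
  expect_setequal(kept$prediction_id, c("p2", "p4"))  # 0.59 out, 0.60 in, stop out
  # idempotent and order-independent
  expect_equal(filter_predictions(kept), kept)
  shuffled <- rec[c(3, 1, 4, 2), ]
  expect_setequal(filter_predictions(shuffled)$prediction_id, kept$prediction_id)
  expect_error(filter_predictions(tibble::tibble(query_coverage = 1.2,
                                                 has_internal_stop = FALSE)),
               "0, 1")
})

test_that("the decision tree routes intergenic, fused and split models correctly", {
  target <- as_genome(tibble::tibble(
    gene_id = c("m1", "fused", "h1", "h2"),
    chrom = "c1",
    start = c(1000, 5000, 20000, 23000),
    end = c(2000, 9000, 21800, 24000),
    strand = "+"), "T")
  records <- tibble::tibble(
    prediction_id = c("new", "sp1", "sp2", "mg"),
    query_gene = c("qn", "q1", "q2", "q3"),
    target_chrom = "c1",
    target_start = c(12000, 5000, 7500, 20000),
    target_end = c(13000, 7000, 9000, 24000),
    target_strand = "+",
    query_coverage = 1, has_internal_stop = FALSE)
  actions <- classify_predictions(records, target, in_map_genes = "m1")
  expect_equal(actions$kind[vapply(actions$prediction_ids,
                                   function(p) "new" %in% p, logical(1))], "new_gene")
  split <- actions[actions$kind == "split", ]
  expect_equal(nrow(split), 1L)
  expect_equal(split$target_genes[[1]], "fused")
  expect_equal(nrow(split$new_models[[1]]), 2L)
  mg <- actions[actions$kind == "merge", ]
  expect_equal(nrow(mg), 1L)
  expect_setequal(mg$target_genes[[1]], c("h1", "h2"))
})

test_that("replace requires an out-map model covered at least as well", {
  target <- as_genome(tibble::tibble(gene_id = c("om", "im"), chrom = "c1",
                                     start = c(1000, 9000), end = c(3000, 11000),
                                     strand = "+"), "T")
  rec <- function(id, s, e) tibble::tibble(prediction_id = id, query_gene = paste0("q", id),
                                           target_chrom = "c1", target_start = s,
                                           target_end = e, target_strand = "+",
                                           query_coverage = 1, has_internal_stop = FALSE)
  # full-span hit on an out-map model: replace
  a1 <- classify_predictions(rec("r1", 1000, 3000), target, in_map_genes = "im")
  expect_equal(a1$kind, "replace")
  # poor hit on an out-map model: discard
  a2 <- classify_predictions(rec("r2", 1000, 1500), target, in_map_genes = "im")
  expect_equal(a2$kind, "discard")
  # hit on a well-supported in-map model: discard
  a3 <- classify_predictions(rec("r3", 9000, 11000), target, in_map_genes = "im")
  expect_equal(a3$kind, "discard")
})

test_that("applying actions preserves the bookkeeping identity", {
  g <- toy_genome("T", rep("+", 10))
  split_act <- tibble::tibble(
    action_id = "a1", kind = "split", reason = "",
    prediction_ids = list("p1"), target_genes = list("T_g03"),
    new_models = list(tibble::tibble(chrom = "chr01", start = c(11000, 12600),
                                     end = c(12400, 13999), strand = "+")))
  res <- apply_actions(g, split_act)
  expect_equal(nrow(res$genome), 11L)
  expect_equal(res$report$final, res$report$initial - res$report$deleted +
                 res$report$added)
  merge_act <- tibble::tibble(
    action_id = "a1", kind = "merge", reason = "",
    prediction_ids = list("p1"), target_genes = list(c("T_g05", "T_g06")),
    new_models = list(tibble::tibble(chrom = "chr01", start = 21000, end = 28999,
                                     strand = "+")))
  res2 <- apply_actions(g, merge_act)
  expect_equal(nrow(res2$genome), 9L)
  # conflicting actions error out with the conflict listed
  expect_error(apply_actions(g, dplyr::bind_rows(split_act, dplyr::mutate(
    split_act, action_id = "a2", kind = "replace"))), "conflict")
  # random action mixes keep the identity
  for (seed in 1:4) {
    acts <- with_seed2(seed, {
      genes <- sample(g$gene_id, 4)
      dplyr::bind_rows(
        tibble::tibble(action_id = "n1", kind = "new_gene", reason = "",
                       prediction_ids = list("p"), target_genes = list(character(0)),
                       new_models = list(tibble::tibble(chrom = "chr01", start = 90000,
                                                        end = 91000, strand = "+"))),
        tibble::tibble(action_id = "r1", kind = "replace", reason = "",
                       prediction_ids = list("p"), target_genes = list(genes[1]),
                       new_models = list(tibble::tibble(chrom = "chr01", start = 95000,
                                                        end = 96000, strand = "+"))))
    })
    rep <- apply_actions(g, acts)$report
    expect_equal(rep$final, rep$initial - rep$deleted + rep$added)
  }
})

test_that("percent identity matches direct arithmetic and an ungapped oracle", {
  expect_equal(percent_identity("MKVLA", "MKVLA"), 100)
  expect_equal(percent_identity("AAAA", "AATA"), 75)
  # with prohibitive gap costs the optimal global alignment of equal-length
  # sequences is ungapped, so PID reduces to positional identity
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I")
  for (seed in 1:6) {
    s <- with_seed2(seed, paste(sample(aa, 8, TRUE), collapse = ""))
    t <- with_seed2(seed + 50, paste(sample(aa, 8, TRUE), collapse = ""))
    expected <- 100 * mean(strsplit(s, "")[[1]] == strsplit(t, "")[[1]])
    expect_equal(percent_identity(s, t, gap_opening = 1000), expected)
  }
  expect_error(percent_identity("MKV", "MK9"), "amino acids")
})

test_that("ortholog acceptance applies both boundaries inclusively", {
  cand <- tibble::tibble(gene_a = sprintf("a%d", 1:4), gene_b = sprintf("b%d", 1:4),
                         pid = c(40.0, 39.9, 80, 80),
                         e_value = c(1e-10, 1e-50, 2e-10, 1e-12))
  acc <- assign_orthologs(cand)
  expect_setequal(acc$gene_a, c("a1", "a4"))  # pid 40 + e 1e-10 in; 39.9 out; 2e-10 out
  merged <- merge_correspondence(tibble::tibble(gene_a = "a9", gene_b = "b9"), acc)
  expect_equal(nrow(merged), 3L)
})

test_that("injected defects are corrected by the classifier at high fidelity", {
  ids <- toy_identity(30)
  bad <- inject_defects(ids$gb, ids$corr,
                        list(split = 0.2, merge = 0.15, drop_ortholog = 0.15),
                        seed = 8)
  expect_gt(nrow(bad$defects), 3)
  records <- truth_predictions(bad$defects)
  kept <- filter_predictions(records)
  expect_equal(nrow(kept), nrow(records))  # noiseless records all pass
  inmap_b <- unique(bad$corr$gene_b)
  actions <- classify_predictions(kept, bad$genome, in_map_genes = inmap_b)
  expect_gte(action_recovery(bad$defects, actions), 0.9)
  # applying the emitted actions keeps the bookkeeping identity
  res <- apply_actions(bad$genome, actions)
  expect_equal(res$report$final, res$report$initial - res$report$deleted +
                 res$report$added)
  # degrading coverage below the filter threshold removes those recoveries
  weak <- dplyr::mutate(records, query_coverage = 0.5)
  expect_equal(nrow(filter_predictions(weak)), 0L)
})

test_that("refinement never reduces the matched-gene count of detection", {
  ids <- toy_identity(16)
  bad <- inject_defects(ids$gb, ids$corr, list(split = 0.2, drop_ortholog = 0.2),
                        seed = 12)
  params <- detection_params(out_map_max = 4, out_map_pct = 50, mode = "rs")
  before <- find_synteny_blocks(ids$ga, bad$genome, bad$corr, params)
  matched_a_genes <- function(b) unique(unlist(lapply(b$pairs, function(p) p$gene_a)))
  n_before <- length(matched_a_genes(before))
  actions <- classify_predictions(truth_predictions(bad$defects), bad$genome,
                                  in_map_genes = unique(bad$corr$gene_b))
  res <- apply_actions(bad$genome, actions)
  # re-assign orthology for the repaired models from the defect ledger
  new_pairs <- purrr::map_dfr(seq_len(nrow(bad$defects)), function(k) {
    tm <- bad$defects$true_models[[k]]
    hit <- res$genome[res$genome$start %in% tm$start & res$genome$chrom %in% tm$chrom, ]
    tibble::tibble(gene_a = bad$defects$query_genes[[k]],
                   gene_b = hit$gene_id[order(hit$start)],
                   pid = 95, e_value = 1e-50)
  })
  corr2 <- merge_correspondence(bad$corr, assign_orthologs(new_pairs))
  after <- find_synteny_blocks(ids$ga, res$genome, corr2, params)
  expect_gte(length(matched_a_genes(after)), n_before)
})
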