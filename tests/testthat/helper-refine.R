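# Fabricate noiseless prediction records from a defect ledger: one record
# per true model, query = the orphaned partner gene, full query coverage,
# no internal stops.
truth_predictions <- function(defects) {
  purrr::map_dfr(seq_len(nrow(defects)), function(k) {
    tm <- defects$true_models[[k]]
    tibble::tibble(prediction_id = sprintf("P_%d_%d", k, seq_len(nrow(tm))),
                   query_gene = defects$query_genes[[k]],
                   target_chrom = tm$chrom, target_start = tm$start,
                   target_end = tm$end, target_strand = tm$strand,
                   query_coverage = 1, has_internal_stop = FALSE,
                   pid = 95, e_value = 1e-50)
  })
}

# Fraction of defects whose expected corrective action was emitted on the
# defective model(s).
action_recovery <- function(defects, actions) {
  hit <- vapply(seq_len(nrow(defects)), function(k) {
    targets <- defects$target_genes[[k]]
    any(actions$kind == defects$expected_action[k] &
          vapply(actions$target_genes, function(tg) setequal(tg, targets), logical(1)))
  }, logical(1))
  mean(hit)
}
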