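#' Out-map mismatch genes and their syntenic search spaces
#'
#' For every out-map mismatch gene inside a block, emits the block's
#' partner interval on the other genome (optionally padded) as the target
#' region in which a spliced aligner should look for the missing or
#' defective gene model. These records are the inputs handed to an external
#' predictor; its output comes back as prediction records.
#'
#' @param blocks Block tibble (detected with out-map mismatches allowed).
#' @param genome_a,genome_b Genome tibbles.
#' @param pad_bp Padding added to each side of the target interval.
#' @return A tibble with `query_gene`, `query_genome` (`"A"`/`"B"`),
#'   `block_id`, `target_genome`, `target_chrom`, `target_start`,
#'   `target_end`.
#' @export
outmap_candidates <- function(blocks, genome_a, genome_b, pad_bp = 0) {
  purrr::map_dfr(seq_len(nrow(blocks)), function(k) {
    mm <- blocks$mm_genes[[k]]
    dplyr::bind_rows(
      if (length(mm$out_mm_a))
        tibble::tibble(query_gene = mm$out_mm_a, query_genome = "A",
                       block_id = blocks$block_id[k], target_genome = "B",
                       target_chrom = blocks$chrom_b[k],
                       target_start = pmax(1, blocks$b_start[k] - pad_bp),
                       target_end = blocks$b_end[k] + pad_bp),
      if (length(mm$out_mm_b))
        tibble::tibble(query_gene = mm$out_mm_b, query_genome = "B",
                       block_id = blocks$block_id[k], target_genome = "A",
                       target_chrom = blocks$chrom_a[k],
                       target_start = pmax(1, blocks$a_start[k] - pad_bp),
                       target_end = blocks$a_end[k] + pad_bp))
  })
}

#' Filter spliced-alignment predictions
#'
#' Keeps predictions that cover at least `min_coverage` of the query
#' protein length (boundary inclusive) and contain no internal stop codon.
#' Filtering is idempotent and order-independent.
#'
#' @param records Prediction tibble with at least `query_coverage`
#'   (fraction in `[0, 1]`) and `has_internal_stop` (logical).
#' @param min_coverage Coverage threshold, default 0.6.
#' @return The accepted subset of `records`.
#' @export
filter_predictions <- function(records, min_coverage = 0.6) {
  records <- tibble::as_tibble(records)
  if (any(records$query_coverage < 0 | records$query_coverage > 1, na.rm = TRUE))
    stop_data("query_coverage must lie in [0, 1]")
  records[records$query_coverage >= min_coverage - 1e-12 &
            !records$has_internal_stop, , drop = FALSE]
}

# Models of `genome` overlapping a bp interval on a chromosome.
overlapping_models <- function(genome, chrom, start, end) {
  hit <- genome$chrom == chrom & genome$start <= end & genome$end >= start
  genome[hit, , drop = FALSE]
}

#' Classify filtered predictions into refinement actions
#'
#' The decision tree, applied to the full accepted record set against the
#' target genome's annotation:
#' \itemize{
#' \item a prediction overlapping no existing model becomes a `new_gene`;
#' \item two or more predictions from distinct queries that tile one model
#'   essentially without overlapping each other trigger a `split` into one
#'   model per prediction (distinct query proteins landing side by side in
#'   one model is the signature of a fused gene);
#' \item one prediction spanning two or more adjacent models that are
#'   out-map (or in-map but covered below `cov_threshold` by the
#'   prediction set) triggers a `merge` into a single model;
#' \item one prediction covering at least `cov_threshold` of a single
#'   out-map model `replace`s it (the re-prediction supports the model at
#'   least as well as its original evidence);
#' \item everything else is `discard`ed with a reason; in particular a
#'   prediction hitting an in-map model that is already well covered is
#'   discarded.
#' }
#' Each existing model is affected by at most one action; conflicting
#' groups are discarded as ambiguous.
#'
#' @param records Accepted prediction tibble with columns `prediction_id`,
#'   `query_gene`, `target_chrom`, `target_start`, `target_end` (and
#'   optionally `target_strand`).
#' @param target_genome Annotation of the genome the predictions land on.
#' @param in_map_genes Character vector of in-map gene ids in
#'   `target_genome` (e.g. from [classify_markers()]); others are out-map.
#' @param cov_threshold Coverage threshold for "well supported", default
#'   0.6 (same as the prediction filter).
#' @return A tibble of actions: `action_id`, `kind` (`new_gene`, `split`,
#'   `merge`, `replace`, `discard`), `reason`, list columns `target_genes`,
#'   `prediction_ids` and `new_models` (tibbles with `chrom`, `start`,
#'   `end`, `strand`).
#' @export
classify_predictions <- function(records, target_genome, in_map_genes = character(),
                                 cov_threshold = 0.6) {
  records <- tibble::as_tibble(records)
  if (!"target_strand" %in% names(records)) records$target_strand <- "+"
  unknown <- setdiff(unique(records$target_chrom), unique(target_genome$chrom))
  if (length(unknown)) stop_data("prediction targets unknown chromosome '%s'", unknown[1])
  if (!"prediction_id" %in% names(records))
    records$prediction_id <- sprintf("P%04d", seq_len(nrow(records)))

  ov <- lapply(seq_len(nrow(records)), function(i)
    overlapping_models(target_genome, records$target_chrom[i],
                       records$target_start[i], records$target_end[i])$gene_id)
  actions <- list()
  used_pred <- rep(FALSE, nrow(records))
  used_model <- character(0)
  add <- function(kind, reason, preds, models, new_models) {
    actions[[length(actions) + 1L]] <<- tibble::tibble(
      kind = kind, reason = reason,
      prediction_ids = list(records$prediction_id[preds]),
      target_genes = list(models), new_models = list(new_models))
    used_pred[preds] <<- TRUE
    used_model <<- c(used_model, models)
  }
  model_row <- function(g) target_genome[target_genome$gene_id == g, , drop = FALSE]
  cover_of <- function(i, g) {
    m <- model_row(g)
    ov_bp <- max(0, min(records$target_end[i], m$end) - max(records$target_start[i], m$start) + 1)
    ov_bp / (m$end - m$start + 1)
  }
  pred_models <- function(chrom, start, end, strand) {
    tibble::tibble(chrom = chrom, start = start, end = end, strand = strand)
  }

  # merge: one prediction spanning >= 2 models
  for (i in seq_len(nrow(records))) {
    ms <- ov[[i]]
    if (length(ms) < 2 || used_pred[i] || any(ms %in% used_model)) next
    support <- vapply(ms, function(g) {
      if (!g %in% in_map_genes) return(TRUE)  # out-map: eligible
      cover_of(i, g) < cov_threshold - 1e-12  # poorly covered in-map: eligible
    }, logical(1))
    if (all(support)) {
      add("merge", "one prediction spans adjacent models", i, ms,
          pred_models(records$target_chrom[i], records$target_start[i],
                      records$target_end[i], records$target_strand[i]))
    } else {
      add("discard", "multi-model hit includes a well-supported in-map model", i,
          character(0), NULL)
    }
  }
  # split: several single-model predictions tiling one model
  by_model <- split(seq_len(nrow(records)),
                    vapply(ov, function(m) if (length(m) == 1L) m else NA_character_,
                           character(1)))
  by_model <- by_model[!is.na(names(by_model))]
  for (g in names(by_model)) {
    if (g %in% used_model) next
    preds <- by_model[[g]][!used_pred[by_model[[g]]]]
    preds <- preds[!duplicated(records$query_gene[preds])]
    if (length(preds) < 2) next
    o <- order(records$target_start[preds])
    preds <- preds[o]
    len <- records$target_end[preds] - records$target_start[preds] + 1
    tol <- 0.1 * pmin(len[-1], len[-length(len)])
    gaps_ok <- all(records$target_start[preds][-1] >
                     records$target_end[preds][-length(preds)] - tol)
    if (gaps_ok) {
      add("split", "distinct queries tile one model", preds, g,
          pred_models(records$target_chrom[preds], records$target_start[preds],
                      records$target_end[preds], records$target_strand[preds]))
    } else {
      add("discard", "overlapping or dominating predictions on one model", preds,
          character(0), NULL)
    }
  }
  # replace / new_gene / discard for the remaining single predictions
  for (i in seq_len(nrow(records))) {
    if (used_pred[i]) next
    ms <- ov[[i]]
    if (!length(ms)) {
      add("new_gene", "prediction lies in intergenic space", i, character(0),
          pred_models(records$target_chrom[i], records$target_start[i],
                      records$target_end[i], records$target_strand[i]))
    } else if (length(ms) == 1L && !ms %in% used_model) {
      g <- ms
      if (g %in% in_map_genes) {
        add("discard", "in-map model already adequately supported", i, character(0), NULL)
      } else if (cover_of(i, g) >= cov_threshold - 1e-12) {
        add("replace", "prediction supports the out-map model at least as well", i, g,
            pred_models(records$target_chrom[i], records$target_start[i],
                        records$target_end[i], records$target_strand[i]))
      } else {
        add("discard", "prediction covers the out-map model poorly", i,
            character(0), NULL)
      }
    } else {
      add("discard", "target model already claimed by another action", i,
          character(0), NULL)
    }
  }
  out <- dplyr::bind_rows(actions)
  if (!nrow(out))
    out <- tibble::tibble(kind = character(), reason = character(),
                          prediction_ids = list(), target_genes = list(),
                          new_models = list())
  out$action_id <- sprintf("ACT%04d", seq_len(nrow(out)))
  dplyr::relocate(out, "action_id")
}

#' @rdname classify_predictions
#' @param record A one-row prediction record.
#' @return `classify_prediction()`: the single action row for one record
#'   (`split`/`merge` require the full record set; use
#'   [classify_predictions()]).
#' @export
classify_prediction <- function(record, target_genome, in_map_genes = character(),
                                cov_threshold = 0.6) {
  classify_predictions(tibble::as_tibble(record), target_genome,
                       in_map_genes, cov_threshold)
}

#' Apply refinement actions to an annotation
#'
#' Rewrites the gene models named by the action set: `split` removes one
#' model and adds its parts, `merge` removes several models and adds one,
#' `replace` swaps one model, `new_gene` adds one. New ids are minted under
#' `id_prefix`. Actions touching the same model twice raise an error
#' listing the conflict. The change report satisfies the bookkeeping
#' identity `initial - deleted + added = final`.
#'
#' @param genome Annotation to revise.
#' @param actions Action tibble from [classify_predictions()].
#' @param id_prefix Prefix for minted gene ids (default `"NEWG"`).
#' @return A list with `genome` (revised annotation) and `report` (a
#'   one-row tibble with per-kind tallies plus `initial`, `deleted`,
#'   `added`, `final`).
#' @export
apply_actions <- function(genome, actions, id_prefix = "NEWG") {
  genome <- as_genome(genome, genome_id(genome))
  act <- actions[actions$kind != "discard", , drop = FALSE]
  touched <- unlist(act$target_genes)
  dup <- unique(touched[duplicated(touched)])
  if (length(dup))
    stop_data("conflicting actions touch model(s): %s", paste(dup, collapse = ", "))
  missing <- setdiff(touched, genome$gene_id)
  if (length(missing))
    stop_data("action references unknown model '%s'", missing[1])
  counter <- 0L
  mint <- function(n) {
    ids <- sprintf("%s%04d", id_prefix, counter + seq_len(n))
    counter <<- counter + n
    ids
  }
  added <- list()
  deleted <- character(0)
  for (k in seq_len(nrow(act))) {
    nm <- act$new_models[[k]]
    deleted <- c(deleted, act$target_genes[[k]])
    if (!is.null(nm) && nrow(nm)) {
      nm <- tibble::as_tibble(nm)
      nm$gene_id <- mint(nrow(nm))
      added[[length(added) + 1L]] <- nm[, c("gene_id", "chrom", "start", "end", "strand")]
    }
  }
  revised <- genome[!genome$gene_id %in% deleted, , drop = FALSE]
  revised <- dplyr::bind_rows(tibble::as_tibble(revised), dplyr::bind_rows(added))
  revised <- as_genome(revised, genome_id(genome))
  tally <- table(factor(act$kind, levels = c("new_gene", "split", "merge", "replace")))
  n_added <- sum(vapply(act$new_models, function(x) if (is.null(x)) 0L else nrow(x),
                        integer(1)))
  report <- tibble::tibble(
    new_gene = as.integer(tally[["new_gene"]]), split = as.integer(tally[["split"]]),
    merge = as.integer(tally[["merge"]]), replace = as.integer(tally[["replace"]]),
    initial = nrow(genome), deleted = length(deleted), added = n_added,
    final = nrow(revised))
  stopifnot(report$initial - report$deleted + report$added == report$final)
  list(genome = revised, report = report)
}

#' Percent identity of two protein sequences
#'
#' Global (Needleman-Wunsch) alignment with affine gap penalties and the
#' BLOSUM62 matrix; PID is the number of identical aligned positions over
#' the number of alignment columns, times 100.
#'
#' @param seq_a,seq_b Protein sequences (strings, standard amino-acid
#'   alphabet).
#' @param gap_opening,gap_extension Affine gap penalties (defaults 10 and
#'   0.5).
#' @param matrix Substitution matrix name (default `"BLOSUM62"`).
#' @return PID as a percentage.
#' @export
percent_identity <- function(seq_a, seq_b, gap_opening = 10, gap_extension = 0.5,
                             matrix = "BLOSUM62") {
  ok <- function(s) nchar(s) > 0 && grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", s)
  if (!ok(seq_a) || !ok(seq_b))
    stop_data("sequences must be nonempty and contain standard amino acids only")
  pa <- Biostrings::pairwiseAlignment(Biostrings::AAString(seq_a),
                                      Biostrings::AAString(seq_b),
                                      type = "global",
                                      substitutionMatrix = matrix,
                                      gapOpening = gap_opening,
                                      gapExtension = gap_extension)
  Biostrings::pid(pa, type = "PID1")
}

#' Accept new ortholog assignments
#'
#' Keeps candidate pairs with PID at least `min_pid` percent and e-value at
#' most `max_evalue` (both boundaries inclusive). E-values come from the
#' aligner and are never recomputed here.
#'
#' @param candidates Tibble with columns `gene_a`, `gene_b`, `pid`,
#'   `e_value`.
#' @param min_pid PID threshold in percent (default 40).
#' @param max_evalue E-value ceiling (default 1e-10).
#' @return The accepted subset, ready for [merge_correspondence()].
#' @export
assign_orthologs <- function(candidates, min_pid = 40, max_evalue = 1e-10) {
  candidates <- tibble::as_tibble(candidates)
  candidates[candidates$pid >= min_pid - 1e-9 &
               candidates$e_value <= max_evalue * (1 + 1e-9), , drop = FALSE]
}
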