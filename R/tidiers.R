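#' Tidy a Mann-Whitney block-size comparison
#'
#' @param x A `synt_mwu` object from [compare_block_sizes()].
#' @param ... Ignored.
#' @return A one-row tibble with `statistic`, `p_value`, `method`.
#' @method tidy synt_mwu
#' @export
tidy.synt_mwu <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p_value = x$p_value, method = x$method)
}

#' @rdname tidy.synt_mwu
#' @return `glance()`: a one-row tibble adding the group sizes.
#' @method glance synt_mwu
#' @export
glance.synt_mwu <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p_value = x$p_value,
                 n1 = x$n1, n2 = x$n2, method = x$method)
}

#' Summarise a block set in one row
#'
#' @param x A `synt_blocks` tibble.
#' @param ... Ignored.
#' @return A one-row tibble with block counts, nested counts, matched gene
#'   totals and span statistics (kb, A side).
#' @method glance synt_blocks
#' @export
glance.synt_blocks <- function(x, ...) {
  tibble::tibble(n_blocks = nrow(x), n_nested = sum(x$nested),
                 n_matched_genes_a = sum(x$n_matched_a),
                 n_matched_genes_b = sum(x$n_matched_b),
                 mean_span_kb = if (nrow(x)) mean(x$span_a) / 1e3 else NA_real_,
                 median_span_kb = if (nrow(x)) median(x$span_a) / 1e3 else NA_real_)
}

#' Flat per-gene view of a block set
#'
#' @param x A `synt_blocks` tibble.
#' @param ... Ignored.
#' @return A tibble with one row per matched pair: `block_id`, `gene_a`,
#'   `gene_b`, `orientation`, `nested`.
#' @method tidy synt_blocks
#' @export
tidy.synt_blocks <- function(x, ...) {
  purrr::map_dfr(seq_len(nrow(x)), function(k)
    dplyr::mutate(x$pairs[[k]], block_id = x$block_id[k],
                  orientation = x$orientation[k], nested = x$nested[k],
                  .before = 1))
}
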