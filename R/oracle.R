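#' Brute-force block enumeration oracle
#'
#' Reference implementation used to verify [find_synteny_blocks()]: it
#' enumerates *every* interval pair on every chromosome pair, applies the
#' validity predicate to each, and independently filters the valid set down
#' to containment-maximal candidates. Semantics are identical to
#' [find_synteny_blocks()] by definition; only the search differs. Intended
#' for small inputs (roughly up to 40 genes per genome) -- the enumeration
#' is quartic in chromosome length and makes no attempt to prune.
#'
#' @inheritParams find_synteny_blocks
#' @return A `synt_blocks` tibble, ordered and labelled exactly as
#'   [find_synteny_blocks()] orders and labels its output.
#' @export
enumerate_blocks_oracle <- function(genome_a, genome_b, corr,
                                    params = detection_params(), nested = TRUE) {
  corr <- as_correspondence(corr)
  if (nrow(genome_a) == 0L || nrow(genome_b) == 0L || nrow(corr) == 0L)
    return(empty_blocks(genome_a, genome_b))
  ctx <- detection_context(genome_a, genome_b, corr)
  valid <- list()
  for (ca in names(ctx$A$by_chrom)) {
    for (cb in names(ctx$B$by_chrom)) {
      if (is.null(ctx$pp[[ctx_key(ca, cb)]])) next
      nA <- ctx$A$by_chrom[[ca]]$n
      nB <- ctx$B$by_chrom[[cb]]$n
      for (a1 in seq_len(nA)) for (a2 in a1:nA) {
        for (b1 in seq_len(nB)) for (b2 in b1:nB) {
          res <- validate_core(ctx, ca, cb, a1, a2, b1, b2, params)
          if (res$valid)
            valid[[length(valid) + 1L]] <-
              list(ca = ca, cb = cb, i1 = a1, i2 = a2, j1 = b1, j2 = b2, res = res)
        }
      }
    }
  }
  # independent maximality filter: plain double loop over the valid set
  keep <- rep(TRUE, length(valid))
  for (u in seq_along(valid)) {
    x <- valid[[u]]
    for (v in seq_along(valid)) {
      if (u == v) next
      y <- valid[[v]]
      if (y$ca == x$ca && y$cb == x$cb &&
          y$i1 <= x$i1 && y$i2 >= x$i2 && y$j1 <= x$j1 && y$j2 >= x$j2 &&
          (y$i1 < x$i1 || y$i2 > x$i2 || y$j1 < x$j1 || y$j2 > x$j2)) {
        keep[u] <- FALSE
        break
      }
    }
  }
  blocks <- assemble_blocks(ctx, valid[keep], genome_a, genome_b)
  if (nested) flag_nested(blocks) else blocks
}
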