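#' Find all maximal synteny blocks between two genomes
#'
#' Anchor-based search: ortholog pairs are anchors; candidate interval pairs
#' around them are screened with necessary-count conditions and then passed
#' through the full validity predicate (see [validate_block()]). The
#' returned set consists of every valid candidate that is maximal, i.e. not
#' contained (both intervals) in another valid candidate. Overlapping
#' maximal blocks are all reported; blocks whose interval in one genome lies
#' inside a larger block while the partner interval lies elsewhere are
#' flagged as nested (segmental duplications). Output order is
#' deterministic: by A-chromosome, A-start ordinal, then interval bounds.
#'
#' @param genome_a,genome_b Genome tibbles (see [as_genome()]).
#' @param corr Correspondence tibble (see [as_correspondence()]).
#' @param params A [detection_params()] object.
#' @param nested Flag nested blocks via [flag_nested()] (default `TRUE`).
#' @return A tibble of class `synt_blocks`, one row per block, with interval
#'   ordinals and bp spans for both genomes, matched/mismatch ledgers
#'   (counts plus gene-id list columns), `orientation`, `strand_pattern`,
#'   `nested` and `parent_id`.
#' @export
find_synteny_blocks <- function(genome_a, genome_b, corr,
                                params = detection_params(), nested = TRUE) {
  corr <- as_correspondence(corr)
  if (nrow(genome_a) == 0L || nrow(genome_b) == 0L || nrow(corr) == 0L)
    return(empty_blocks(genome_a, genome_b))
  ctx <- detection_context(genome_a, genome_b, corr)
  eps <- 1e-9
  cands <- list()
  for (key in names(ctx$pp)) {
    pk <- ctx$pp[[key]]
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    ca <- parts[1]; cb <- parts[2]
    nA <- ctx$A$by_chrom[[ca]]$n
    nB <- ctx$B$by_chrom[[cb]]$n
    if (length(unique(pk$pa)) < params$min_size ||
        length(unique(pk$pb)) < params$min_size) next

    # A-side screening: counts that do not depend on the partner interval.
    haspart_a <- logical(nA); haspart_a[unique(pk$pa)] <- TRUE
    inm_a <- ctx$inmapA[[ca]]
    cs_part <- cumsum(c(0L, as.integer(haspart_a)))
    cs_outa <- ctx$cs_outA[[ca]]
    cs_gin <- cumsum(c(0L, as.integer(inm_a & !haspart_a)))  # unavoidable in-map mismatches
    i1 <- rep(seq_len(nA), times = nA)
    i2 <- rep(seq_len(nA), each = nA)
    ok <- i1 <= i2
    i1 <- i1[ok]; i2 <- i2[ok]
    len <- i2 - i1 + 1L
    n_out <- cs_outa[i2 + 1L] - cs_outa[i1]
    n_gin <- cs_gin[i2 + 1L] - cs_gin[i1]
    n_part <- cs_part[i2 + 1L] - cs_part[i1]
    keep <- n_part >= params$min_size &
      n_out <= params$out_map_max & n_out <= params$out_map_pct / 100 * len + eps &
      n_gin <= params$in_map_max & n_gin <= params$in_map_pct / 100 * len + eps
    i1 <- i1[keep]; i2 <- i2[keep]
    if (!length(i1)) next

    inm_b <- ctx$inmapB[[cb]]
    cs_outb <- ctx$cs_outB[[cb]]
    jj1 <- rep(seq_len(nB), times = nB)
    jj2 <- rep(seq_len(nB), each = nB)
    okj <- jj1 <= jj2
    jj1 <- jj1[okj]; jj2 <- jj2[okj]
    lenj <- jj2 - jj1 + 1L
    n_outb <- cs_outb[jj2 + 1L] - cs_outb[jj1]
    keep_outb <- n_outb <= params$out_map_max &
      n_outb <= params$out_map_pct / 100 * lenj + eps

    for (k in seq_along(i1)) {
      a1 <- i1[k]; a2 <- i2[k]
      sel_a <- pk$pa >= a1 & pk$pa <= a2
      partnered <- logical(nB); partnered[unique(pk$pb[sel_a])] <- TRUE
      cs_pb <- cumsum(c(0L, as.integer(partnered)))
      cs_np <- cumsum(c(0L, as.integer(inm_b & !partnered)))
      n_pb <- cs_pb[jj2 + 1L] - cs_pb[jj1]
      n_np <- cs_np[jj2 + 1L] - cs_np[jj1]
      keepj <- keep_outb & n_pb >= params$min_size &
        n_np <= params$in_map_max & n_np <= params$in_map_pct / 100 * lenj + eps
      for (q in which(keepj)) {
        res <- validate_core(ctx, ca, cb, a1, a2, jj1[q], jj2[q], params)
        if (res$valid)
          cands[[length(cands) + 1L]] <-
            list(ca = ca, cb = cb, i1 = a1, i2 = a2, j1 = jj1[q], j2 = jj2[q], res = res)
      }
    }
  }
  blocks <- assemble_blocks(ctx, maximal_candidates(cands), genome_a, genome_b)
  if (nested) blocks <- flag_nested(blocks) else blocks
}

# Keep containment-maximal candidates: drop any candidate whose both
# intervals are contained in another valid candidate's intervals.
maximal_candidates <- function(cands) {
  if (!length(cands)) return(cands)
  key <- vapply(cands, function(x) paste(x$ca, x$cb, sep = "\r"), character(1))
  keep <- logical(length(cands))
  for (grp in split(seq_along(cands), key)) {
    i1 <- vapply(cands[grp], `[[`, integer(1) + 0L, "i1")
    i2 <- vapply(cands[grp], `[[`, integer(1) + 0L, "i2")
    j1 <- vapply(cands[grp], `[[`, integer(1) + 0L, "j1")
    j2 <- vapply(cands[grp], `[[`, integer(1) + 0L, "j2")
    for (u in seq_along(grp)) {
      contained <- i1 <= i1[u] & i2 >= i2[u] & j1 <= j1[u] & j2 >= j2[u] &
        (i1 < i1[u] | i2 > i2[u] | j1 < j1[u] | j2 > j2[u])
      keep[grp[u]] <- !any(contained)
    }
  }
  cands[keep]
}

# Turn validated candidates into the user-facing block tibble.
assemble_blocks <- function(ctx, cands, genome_a, genome_b) {
  if (!length(cands)) return(empty_blocks(genome_a, genome_b))
  rows <- purrr::map_dfr(cands, function(x) {
    A <- ctx$A$by_chrom[[x$ca]]; B <- ctx$B$by_chrom[[x$cb]]
    res <- x$res
    mm <- core_mismatch_genes(ctx, x$ca, x$cb, x$i1, x$i2, x$j1, x$j2,
                              res$matched_a, res$matched_b)
    pairs <- core_matched_pairs(ctx, x$ca, x$cb, res)
    tibble::tibble(
      chrom_a = x$ca, a_first = x$i1, a_last = x$i2,
      a_start = A$start[x$i1], a_end = A$end[x$i2],
      span_a = A$end[x$i2] - A$start[x$i1] + 1,
      chrom_b = x$cb, b_first = x$j1, b_last = x$j2,
      b_start = B$start[x$j1], b_end = B$end[x$j2],
      span_b = B$end[x$j2] - B$start[x$j1] + 1,
      n_genes_a = x$i2 - x$i1 + 1L, n_genes_b = x$j2 - x$j1 + 1L,
      n_matched_a = res$n_matched_a, n_matched_b = res$n_matched_b,
      in_mm_a = res$in_mm_a, out_mm_a = res$out_mm_a,
      in_mm_b = res$in_mm_b, out_mm_b = res$out_mm_b,
      orientation = res$orientation, strand_pattern = res$strand_pattern,
      nested = FALSE, parent_id = NA_character_,
      pairs = list(pairs), mm_genes = list(mm))
  })
  rows <- dplyr::arrange(rows, .data$chrom_a, .data$a_first, .data$a_last,
                         .data$chrom_b, .data$b_first, .data$b_last)
  rows$block_id <- sprintf("SB%04d", seq_len(nrow(rows)))
  rows <- dplyr::relocate(rows, "block_id")
  new_blocks(rows, genome_a, genome_b)
}

new_blocks <- function(rows, genome_a, genome_b) {
  attr(rows, "genome_a") <- genome_id(genome_a)
  attr(rows, "genome_b") <- genome_id(genome_b)
  class(rows) <- c("synt_blocks", class(tibble::tibble()))
  rows
}

empty_blocks <- function(genome_a = NULL, genome_b = NULL) {
  rows <- tibble::tibble(
    block_id = character(), chrom_a = character(), a_first = integer(),
    a_last = integer(), a_start = numeric(), a_end = numeric(), span_a = numeric(),
    chrom_b = character(), b_first = integer(), b_last = integer(),
    b_start = numeric(), b_end = numeric(), span_b = numeric(),
    n_genes_a = integer(), n_genes_b = integer(),
    n_matched_a = integer(), n_matched_b = integer(),
    in_mm_a = integer(), out_mm_a = integer(), in_mm_b = integer(), out_mm_b = integer(),
    orientation = character(), strand_pattern = character(),
    nested = logical(), parent_id = character(),
    pairs = list(), mm_genes = list())
  attr(rows, "genome_a") <- if (is.null(genome_a)) "A" else genome_id(genome_a)
  attr(rows, "genome_b") <- if (is.null(genome_b)) "B" else genome_id(genome_b)
  class(rows) <- c("synt_blocks", class(tibble::tibble()))
  rows
}

#' @export
print.synt_blocks <- function(x, ...) {
  n_nested <- if ("nested" %in% names(x)) sum(x$nested) else 0L
  cat(sprintf("# %d synteny block(s) [%s vs %s], %d nested\n",
              nrow(x), attr(x, "genome_a") %||% "A", attr(x, "genome_b") %||% "B",
              n_nested))
  NextMethod()
}

#' Flag nested blocks
#'
#' A block is nested when its interval in one genome is contained within a
#' larger block's interval in that genome while its interval in the other
#' genome is disjoint from that larger block's interval -- the signature of
#' a segmental duplication. `parent_id` is set to the containing block
#' (the largest one when several qualify).
#'
#' @param blocks A block tibble from [find_synteny_blocks()].
#' @return The same tibble with `nested`/`parent_id` recomputed.
#' @export
flag_nested <- function(blocks) {
  n <- nrow(blocks)
  if (n == 0L) return(blocks)
  nested <- logical(n)
  parent <- rep(NA_character_, n)
  disjoint <- function(c1, s1, e1, c2, s2, e2) c1 != c2 | e1 < s2 | s1 > e2
  for (u in seq_len(n)) {
    # containment on the A side, disjoint on the B side
    inside_a <- blocks$chrom_a == blocks$chrom_a[u] &
      blocks$a_first <= blocks$a_first[u] & blocks$a_last >= blocks$a_last[u] &
      (blocks$a_last - blocks$a_first) > (blocks$a_last[u] - blocks$a_first[u]) &
      disjoint(blocks$chrom_b, blocks$b_first, blocks$b_last,
               blocks$chrom_b[u], blocks$b_first[u], blocks$b_last[u])
    inside_b <- blocks$chrom_b == blocks$chrom_b[u] &
      blocks$b_first <= blocks$b_first[u] & blocks$b_last >= blocks$b_last[u] &
      (blocks$b_last - blocks$b_first) > (blocks$b_last[u] - blocks$b_first[u]) &
      disjoint(blocks$chrom_a, blocks$a_first, blocks$a_last,
               blocks$chrom_a[u], blocks$a_first[u], blocks$a_last[u])
    hit <- which(inside_a | inside_b)
    hit <- setdiff(hit, u)
    if (length(hit)) {
      nested[u] <- TRUE
      size <- (blocks$a_last - blocks$a_first + blocks$b_last - blocks$b_first)[hit]
      parent[u] <- blocks$block_id[hit[order(-size, blocks$block_id[hit])[1]]]
    }
  }
  blocks$nested <- nested
  blocks$parent_id <- parent
  blocks
}

#' Degenerate single-gene blocks for coverage accounting
#'
#' One record per in-map gene not covered by any reported block interval in
#' its genome. These are not blocks in the ordinary sense (they fail the
#' minimum size); they exist so that coverage can optionally count isolated
#' conserved genes.
#'
#' @param genome_a,genome_b Genome tibbles.
#' @param corr Correspondence tibble.
#' @param blocks Reported blocks.
#' @return A tibble with `genome` (`"A"`/`"B"`), `gene_id`, `chrom`,
#'   `start`, `end`.
#' @export
singleton_blocks <- function(genome_a, genome_b, corr, blocks) {
  corr <- as_correspondence(corr)
  one_side <- function(g, inmap_ids, chrom_col, first_col, last_col, label) {
    idx <- genome_index(g)
    ords <- unname(idx$ord_of[g$gene_id])
    covered <- rep(FALSE, nrow(g))
    if (nrow(blocks)) {
      for (k in seq_len(nrow(blocks))) {
        hit <- g$chrom == blocks[[chrom_col]][k] &
          ords >= blocks[[first_col]][k] & ords <= blocks[[last_col]][k]
        covered <- covered | hit
      }
    }
    keep <- g$gene_id %in% inmap_ids & !covered
    tibble::tibble(genome = label, gene_id = g$gene_id[keep],
                   chrom = g$chrom[keep], start = g$start[keep],
                   end = g$end[keep])
  }
  dplyr::bind_rows(
    one_side(genome_a, unique(corr$gene_a), "chrom_a", "a_first", "a_last", "A"),
    one_side(genome_b, unique(corr$gene_b), "chrom_b", "b_first", "b_last", "B"))
}
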