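# Block validity: the core predicate of the method.
#
# A candidate is a pair of contiguous gene intervals, one per genome. Genes
# inside an interval partition into matched genes (>= 1 ortholog inside the
# partner interval), in-map mismatches (orthologs exist but all fall outside
# the partner interval) and out-map mismatches (no ortholog anywhere). The
# candidate is valid when matched counts respect the size limits, both
# mismatch ledgers respect their absolute and percentage caps on both sides,
# and a covering monotone selection of ortholog pairs exists that satisfies
# the order/strand coupling admitted by the mode.

# Precompute everything detection needs from (genome_a, genome_b, corr).
detection_context <- function(genome_a, genome_b, corr) {
  ia <- genome_index(genome_a)
  ib <- genome_index(genome_b)
  corr <- as_correspondence(corr)
  bad_a <- setdiff(corr$gene_a, names(ia$ord_of))
  bad_b <- setdiff(corr$gene_b, names(ib$ord_of))
  if (length(bad_a) || length(bad_b))
    stop_data(paste0("correspondence references gene ids absent from the genomes ",
                     "(e.g. '%s'); read with validate_correspondence(strict = FALSE) first"),
              c(bad_a, bad_b)[1])

  inmap_flags <- function(idx, inmap_ids) {
    lapply(idx$by_chrom, function(b) b$gene_id %in% inmap_ids)
  }
  inmapA <- inmap_flags(ia, unique(corr$gene_a))
  inmapB <- inmap_flags(ib, unique(corr$gene_b))
  cs <- function(flags) lapply(flags, function(f) cumsum(c(0L, as.integer(f))))

  strand_a <- setNames(unlist(lapply(ia$by_chrom, `[[`, "strand"), use.names = FALSE),
                       unlist(lapply(ia$by_chrom, `[[`, "gene_id"), use.names = FALSE))
  strand_b <- setNames(unlist(lapply(ib$by_chrom, `[[`, "strand"), use.names = FALSE),
                       unlist(lapply(ib$by_chrom, `[[`, "gene_id"), use.names = FALSE))

  pa_chrom <- unname(ia$chrom_of[corr$gene_a])
  pb_chrom <- unname(ib$chrom_of[corr$gene_b])
  key <- paste(pa_chrom, pb_chrom, sep = "\r")
  pairs <- list(
    pa = unname(ia$ord_of[corr$gene_a]), pb = unname(ib$ord_of[corr$gene_b]),
    rel = unname(strand_a[corr$gene_a] == strand_b[corr$gene_b]),
    gene_a = corr$gene_a, gene_b = corr$gene_b)
  by_key <- lapply(split(seq_along(key), key), function(i) {
    list(pa = pairs$pa[i], pb = pairs$pb[i], rel = pairs$rel[i],
         gene_a = pairs$gene_a[i], gene_b = pairs$gene_b[i])
  })

  list(A = ia, B = ib, corr = corr,
       inmapA = inmapA, inmapB = inmapB,
       cs_inA = cs(inmapA), cs_inB = cs(inmapB),
       cs_outA = cs(lapply(inmapA, `!`)), cs_outB = cs(lapply(inmapB, `!`)),
       pp = by_key)
}

ctx_key <- function(ca, cb) paste(ca, cb, sep = "\r")

# Reachability sweep over the pair grid: is there a monotone covering
# selection (a staircase from cell (1,1) to (m,n) through allowed cells,
# moving down, right or diagonally)?
grid_reachable <- function(M) {
  m <- nrow(M); n <- ncol(M)
  reach <- matrix(FALSE, m, n)
  prev <- rep(FALSE, n)
  for (i in seq_len(m)) {
    row <- logical(n)
    left <- FALSE
    for (j in seq_len(n)) {
      if (M[i, j]) {
        row[j] <- if (i == 1L && j == 1L) TRUE
                  else (prev[j] || (j > 1L && prev[j - 1L]) || left)
      }
      left <- row[j]
    }
    if (!any(row)) return(NULL)
    reach[i, ] <- row
    prev <- row
  }
  if (!reach[m, n]) NULL else reach
}

# Deterministic traceback of one covering staircase (prefer diagonal, then
# horizontal, then vertical steps, walking backwards from (m, n)).
grid_traceback <- function(reach, M) {
  i <- nrow(reach); j <- ncol(reach)
  cells <- list()
  repeat {
    cells[[length(cells) + 1L]] <- c(i, j)
    if (i == 1L && j == 1L) break
    if (i > 1L && j > 1L && reach[i - 1L, j - 1L]) { i <- i - 1L; j <- j - 1L }
    else if (j > 1L && reach[i, j - 1L]) j <- j - 1L
    else i <- i - 1L
  }
  do.call(rbind, rev(cells))
}

# Core validity check on ordinal intervals. Returns a list with `valid`,
# a `reason` naming the first violated condition, ledger counts, and (for
# valid candidates) the admitted combo plus data needed to build details.
validate_core <- function(ctx, ca, cb, i1, i2, j1, j2, params) {
  fail <- function(reason, ...) c(list(valid = FALSE, reason = reason), list(...))
  pk <- ctx$pp[[ctx_key(ca, cb)]]
  lenA <- i2 - i1 + 1L
  lenB <- j2 - j1 + 1L
  out_a <- ctx$cs_outA[[ca]][i2 + 1L] - ctx$cs_outA[[ca]][i1]
  out_b <- ctx$cs_outB[[cb]][j2 + 1L] - ctx$cs_outB[[cb]][j1]
  in_all_a <- ctx$cs_inA[[ca]][i2 + 1L] - ctx$cs_inA[[ca]][i1]
  in_all_b <- ctx$cs_inB[[cb]][j2 + 1L] - ctx$cs_inB[[cb]][j1]

  if (is.null(pk)) {
    sel <- integer(0)
    matched_a <- matched_b <- integer(0)
  } else {
    sel <- which(pk$pa >= i1 & pk$pa <= i2 & pk$pb >= j1 & pk$pb <= j2)
    matched_a <- sort(unique(pk$pa[sel]))
    matched_b <- sort(unique(pk$pb[sel]))
  }
  n_ma <- length(matched_a); n_mb <- length(matched_b)
  in_mm_a <- in_all_a - n_ma
  in_mm_b <- in_all_b - n_mb
  counts <- list(n_matched_a = n_ma, n_matched_b = n_mb,
                 in_mm_a = in_mm_a, in_mm_b = in_mm_b,
                 out_mm_a = out_a, out_mm_b = out_b)

  eps <- 1e-9
  if (n_ma < params$min_size) return(do.call(fail, c(list("too_few_matched_genes_A"), counts)))
  if (n_mb < params$min_size) return(do.call(fail, c(list("too_few_matched_genes_B"), counts)))
  if (n_ma > params$max_size) return(do.call(fail, c(list("too_many_matched_genes_A"), counts)))
  if (n_mb > params$max_size) return(do.call(fail, c(list("too_many_matched_genes_B"), counts)))
  if (out_a > params$out_map_max) return(do.call(fail, c(list("out_map_count_A"), counts)))
  if (out_a > params$out_map_pct / 100 * lenA + eps)
    return(do.call(fail, c(list("out_map_pct_A"), counts)))
  if (out_b > params$out_map_max) return(do.call(fail, c(list("out_map_count_B"), counts)))
  if (out_b > params$out_map_pct / 100 * lenB + eps)
    return(do.call(fail, c(list("out_map_pct_B"), counts)))
  if (in_mm_a > params$in_map_max) return(do.call(fail, c(list("in_map_count_A"), counts)))
  if (in_mm_a > params$in_map_pct / 100 * lenA + eps)
    return(do.call(fail, c(list("in_map_pct_A"), counts)))
  if (in_mm_b > params$in_map_max) return(do.call(fail, c(list("in_map_count_B"), counts)))
  if (in_mm_b > params$in_map_pct / 100 * lenB + eps)
    return(do.call(fail, c(list("in_map_pct_B"), counts)))

  ra <- match(pk$pa[sel], matched_a)
  rb <- match(pk$pb[sel], matched_b)
  rel <- pk$rel[sel]
  for (combo in mode_combos(params$mode)) {
    dir <- combo[1]; str <- combo[2]
    mask <- switch(str, same = rel, diff = !rel, any = rep(TRUE, length(rel)))
    if (!any(mask)) next
    # coverage: every matched gene must retain at least one admitted pair
    if (length(unique(ra[mask])) < n_ma || length(unique(rb[mask])) < n_mb) next
    if (dir == "any") {
      return(c(list(valid = TRUE, reason = NA_character_,
                    orientation = "unordered",
                    strand_pattern = c(same = "consistent", diff = "reversed",
                                       any = "mixed")[[str]],
                    dir = dir, str = str, reach = NULL,
                    sel = sel, mask = mask, ra = ra, rb = rb,
                    matched_a = matched_a, matched_b = matched_b), counts))
    }
    col <- if (dir == "inc") rb else n_mb + 1L - rb
    M <- matrix(FALSE, n_ma, n_mb)
    M[cbind(ra[mask], col[mask])] <- TRUE
    reach <- grid_reachable(M)
    if (!is.null(reach)) {
      return(c(list(valid = TRUE, reason = NA_character_,
                    orientation = if (dir == "inc") "colinear" else "inverted",
                    strand_pattern = c(same = "consistent", diff = "reversed",
                                       any = "mixed")[[str]],
                    dir = dir, str = str, reach = reach, M = M,
                    sel = sel, mask = mask, ra = ra, rb = rb,
                    matched_a = matched_a, matched_b = matched_b), counts))
    }
  }
  do.call(fail, c(list("order_strand_constraint"), counts))
}

# Matched pairs (A-ordered) realized by the validated combo.
core_matched_pairs <- function(ctx, ca, cb, res) {
  pk <- ctx$pp[[ctx_key(ca, cb)]]
  if (res$dir == "any") {
    keep <- res$sel[res$mask]
    o <- order(res$ra[res$mask], res$rb[res$mask])
    keep <- keep[o]
    return(tibble::tibble(gene_a = pk$gene_a[keep], gene_b = pk$gene_b[keep]))
  }
  cells <- grid_traceback(res$reach, res$M)
  a_ord <- res$matched_a[cells[, 1]]
  b_idx <- if (res$dir == "inc") cells[, 2] else length(res$matched_b) + 1L - cells[, 2]
  b_ord <- res$matched_b[b_idx]
  ga <- ctx$A$by_chrom[[ca]]$gene_id[a_ord]
  gb <- ctx$B$by_chrom[[cb]]$gene_id[b_ord]
  tibble::tibble(gene_a = ga, gene_b = gb)
}

# Mismatch gene id sets for a validated (or merely classified) candidate.
core_mismatch_genes <- function(ctx, ca, cb, i1, i2, j1, j2, matched_a, matched_b) {
  A <- ctx$A$by_chrom[[ca]]; B <- ctx$B$by_chrom[[cb]]
  ords_a <- i1:i2; ords_b <- j1:j2
  in_a <- ctx$inmapA[[ca]][ords_a]
  in_b <- ctx$inmapB[[cb]][ords_b]
  list(in_mm_a = A$gene_id[ords_a[in_a & !(ords_a %in% matched_a)]],
       out_mm_a = A$gene_id[ords_a[!in_a]],
       in_mm_b = B$gene_id[ords_b[in_b & !(ords_b %in% matched_b)]],
       out_mm_b = B$gene_id[ords_b[!in_b]])
}

#' Validate a candidate block
#'
#' Applies the full validity predicate to one candidate interval pair:
#' size limits on matched genes, absolute and percentage caps on in-map and
#' out-map mismatches on both sides, and existence of a covering monotone
#' ortholog selection compatible with the mode's order/strand coupling.
#'
#' @param genome_a,genome_b Genome tibbles.
#' @param corr Correspondence tibble.
#' @param candidate A list or one-row data frame with `chrom_a`, `a_first`,
#'   `a_last`, `chrom_b`, `b_first`, `b_last`, where `*_first`/`*_last` are
#'   1-based gene ordinals on the named chromosome.
#' @param params A [detection_params()] object.
#' @return A list with `valid` (logical), `reason` (the first violated
#'   condition, `NA` when valid), the mismatch/matched counts, and for valid
#'   candidates `orientation`, `strand_pattern` and the realized
#'   `matched_pairs` tibble.
#' @export
validate_block <- function(genome_a, genome_b, corr, candidate, params = detection_params()) {
  ctx <- detection_context(genome_a, genome_b, corr)
  validate_block_ctx(ctx, candidate, params)
}

validate_block_ctx <- function(ctx, candidate, params) {
  cd <- as.list(candidate)
  ca <- as.character(cd$chrom_a); cb <- as.character(cd$chrom_b)
  if (!ca %in% names(ctx$A$by_chrom)) stop_data("unknown chromosome '%s' in genome A", ca)
  if (!cb %in% names(ctx$B$by_chrom)) stop_data("unknown chromosome '%s' in genome B", cb)
  i1 <- as.integer(cd$a_first); i2 <- as.integer(cd$a_last)
  j1 <- as.integer(cd$b_first); j2 <- as.integer(cd$b_last)
  if (i1 < 1 || i2 > ctx$A$by_chrom[[ca]]$n || i1 > i2 ||
      j1 < 1 || j2 > ctx$B$by_chrom[[cb]]$n || j1 > j2)
    stop_data("candidate interval falls outside its chromosome (intervals may not span chromosome boundaries)")
  res <- validate_core(ctx, ca, cb, i1, i2, j1, j2, params)
  out <- list(valid = res$valid, reason = res$reason,
              n_matched_a = res$n_matched_a, n_matched_b = res$n_matched_b,
              in_mm_a = res$in_mm_a, in_mm_b = res$in_mm_b,
              out_mm_a = res$out_mm_a, out_mm_b = res$out_mm_b)
  if (res$valid) {
    out$orientation <- res$orientation
    out$strand_pattern <- res$strand_pattern
    out$matched_pairs <- core_matched_pairs(ctx, ca, cb, res)
  }
  out
}
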