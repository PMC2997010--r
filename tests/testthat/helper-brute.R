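# From-scratch re-derivation of the block validity predicate, used to
# cross-check validate_block on tiny instances. Completely independent
# code path: naive per-gene classification plus exhaustive enumeration of
# pair subsets for the order/strand condition.

brute_setup <- function(ga, gb, corr) {
  corr <- as_correspondence(corr)
  ga <- as_genome(ga, genome_id(ga)); gb <- as_genome(gb, genome_id(gb))
  by_chrom <- function(g) split(seq_len(nrow(g)), g$chrom)
  list(ga = as.list(ga), gb = as.list(gb),
       rows_a = by_chrom(ga), rows_b = by_chrom(gb),
       pa = corr$gene_a, pb = corr$gene_b,
       same = ga$strand[match(corr$gene_a, ga$gene_id)] ==
              gb$strand[match(corr$gene_b, gb$gene_id)])
}

brute_force_valid <- function(su, cand, params) {
  ia <- su$rows_a[[cand$chrom_a]][cand$a_first:cand$a_last]
  ib <- su$rows_b[[cand$chrom_b]][cand$b_first:cand$b_last]
  genes_a <- su$ga$gene_id[ia]
  genes_b <- su$gb$gene_id[ib]

  inP <- su$pa %in% genes_a & su$pb %in% genes_b
  pos_a <- match(su$pa[inP], genes_a)
  pos_b <- match(su$pb[inP], genes_b)
  same <- su$same[inP]
  Pa <- su$pa[inP]; Pb <- su$pb[inP]

  matched_a <- unique(Pa); matched_b <- unique(Pb)
  out_a <- sum(!genes_a %in% su$pa)
  out_b <- sum(!genes_b %in% su$pb)
  in_a <- sum(genes_a %in% su$pa & !genes_a %in% matched_a)
  in_b <- sum(genes_b %in% su$pb & !genes_b %in% matched_b)
  la <- length(genes_a); lb <- length(genes_b)

  if (length(matched_a) < params$min_size || length(matched_b) < params$min_size) return(FALSE)
  if (length(matched_a) > params$max_size || length(matched_b) > params$max_size) return(FALSE)
  if (out_a > params$out_map_max || out_a > params$out_map_pct / 100 * la + 1e-9) return(FALSE)
  if (out_b > params$out_map_max || out_b > params$out_map_pct / 100 * lb + 1e-9) return(FALSE)
  if (in_a > params$in_map_max || in_a > params$in_map_pct / 100 * la + 1e-9) return(FALSE)
  if (in_b > params$in_map_max || in_b > params$in_map_pct / 100 * lb + 1e-9) return(FALSE)

  np <- length(Pa)
  if (np > 16) stop("brute force limited to 16 in-interval pairs")
  covers <- function(sel) {
    all(matched_a %in% Pa[sel]) && all(matched_b %in% Pb[sel])
  }
  monotone <- function(sel, sign) {
    if (length(sel) < 2) return(TRUE)
    for (u in sel) for (v in sel) {
      if (u == v) next
      if (sign * (pos_a[u] - pos_a[v]) * (pos_b[u] - pos_b[v]) < 0) return(FALSE)
    }
    TRUE
  }
  combos <- switch(params$mode,
    "rs" = list(c("inc", "same"), c("dec", "diff")),
    "r-s" = list(c("inc", "same"), c("inc", "diff"), c("dec", "same"), c("dec", "diff")),
    "free" = list(c("any", "any")))
  for (combo in combos) {
    strand_ok <- switch(combo[2], same = same, diff = !same, any = rep(TRUE, np))
    allowed <- which(strand_ok)
    if (!length(allowed)) next
    if (combo[1] == "any") {
      if (covers(allowed)) return(TRUE)
      next
    }
    if (!covers(allowed)) next          # no subset can cover either
    sign <- if (combo[1] == "inc") 1 else -1
    if (monotone(allowed, sign)) return(TRUE)  # the full admitted set qualifies
    # enumerate every subset of the admitted pairs
    for (mask in seq_len(2^length(allowed)) - 1L) {
      sel <- allowed[bitwAnd(mask, 2^(seq_along(allowed) - 1L)) > 0]
      if (!length(sel)) next
      if (covers(sel) && monotone(sel, sign)) return(TRUE)
    }
  }
  FALSE
}
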