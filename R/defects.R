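#' Inject annotation defects
#'
#' Corrupts an annotation and its correspondence the way real draft
#' genomes are corrupted, recording for every injected defect the
#' corrective action a refinement engine is expected to emit. Defects are
#' named after their corrective action:
#' \describe{
#'   \item{split}{two adjacent gene models are fused into one model
#'     spanning both; the fused model and the two orthologs of the
#'     original models become out-map. Expected action: split.}
#'   \item{merge}{one model is broken into two half-span models; the
#'     model's ortholog pair is removed. Expected action: merge.}
#'   \item{drop_ortholog}{the ortholog pair of one healthy model is
#'     removed, leaving both genes out-map with an intact model.
#'     Expected action: replace (a re-prediction confirms the model).}
#' }
#' Defect sites are sampled binomially at the given per-site rates among
#' eligible sites (genes with a one-to-one ortholog), with a one-gene
#' buffer between sites so defects never interact.
#'
#' @param genome Annotation to corrupt (genome B of the correspondence).
#' @param corr Correspondence tibble (`gene_a`, `gene_b`).
#' @param rates Named list with elements `split`, `merge`, `drop_ortholog`
#'   in `[0, 1]` (missing elements default to 0).
#' @param seed RNG seed.
#' @return A list with `genome` (defective annotation), `corr` (defective
#'   correspondence) and `defects`: a tibble with `kind`, `expected_action`,
#'   list columns `target_genes` (defective model ids), `query_genes`
#'   (out-map partners in genome A that should re-discover the locus) and
#'   `true_models` (tibbles of the uncorrupted model spans).
#' @export
inject_defects <- function(genome, corr, rates = list(), seed = 1) {
  genome <- as_genome(genome, genome_id(genome))
  corr <- as_correspondence(corr)
  rates <- utils::modifyList(list(split = 0, merge = 0, drop_ortholog = 0), rates)
  if (any(unlist(rates) < 0 | unlist(rates) > 1)) stop_data("rates must lie in [0, 1]")

  tab_a <- table(corr$gene_a); tab_b <- table(corr$gene_b)
  one2one <- corr$gene_b[tab_a[corr$gene_a] == 1 & tab_b[corr$gene_b] == 1]
  partner_of <- setNames(corr$gene_a, corr$gene_b)
  idx <- genome_index(genome)
  ords <- unname(idx$ord_of[genome$gene_id])

  defects <- list()
  blocked <- character(0)  # genes already used by or adjacent to a defect
  neighbours <- function(g) {
    cc <- idx$chrom_of[[g]]; o <- idx$ord_of[[g]]
    b <- idx$by_chrom[[cc]]
    b$gene_id[pmax(1, o - 1):pmin(b$n, o + 1)]
  }
  g_new <- tibble::as_tibble(genome)
  corr_new <- corr

  with_seed(seed, {
    # split defect: fuse gene with its right neighbour
    for (g in genome$gene_id) {
      cc <- idx$chrom_of[[g]]; o <- idx$ord_of[[g]]
      b <- idx$by_chrom[[cc]]
      if (o >= b$n) next
      g2 <- b$gene_id[o + 1]
      if (!(g %in% one2one) || !(g2 %in% one2one)) next
      if (any(c(neighbours(g), neighbours(g2)) %in% blocked)) next
      if (runif(1) >= rates$split) next
      rows <- g_new[g_new$gene_id %in% c(g, g2), , drop = FALSE]
      fused <- tibble::tibble(gene_id = paste0("FUSED_", g),
                              chrom = cc, start = min(rows$start),
                              end = max(rows$end), strand = rows$strand[1])
      g_new <- dplyr::bind_rows(g_new[!g_new$gene_id %in% c(g, g2), , drop = FALSE], fused)
      corr_new <- corr_new[!corr_new$gene_b %in% c(g, g2), , drop = FALSE]
      defects[[length(defects) + 1L]] <- tibble::tibble(
        kind = "split", expected_action = "split",
        target_genes = list(fused$gene_id),
        query_genes = list(unname(partner_of[c(g, g2)])),
        true_models = list(rows[, c("chrom", "start", "end", "strand")]))
      blocked <- c(blocked, neighbours(g), neighbours(g2))
    }
    # merge defect: break one gene into two half models
    for (g in genome$gene_id) {
      if (!(g %in% one2one) || g %in% blocked) next
      if (any(neighbours(g) %in% blocked)) next
      if (runif(1) >= rates$merge) next
      row <- g_new[g_new$gene_id == g, , drop = FALSE]
      if (!nrow(row) || row$end - row$start < 400) next
      mid <- floor((row$start + row$end) / 2)
      halves <- tibble::tibble(
        gene_id = paste0(g, c(".p1", ".p2")), chrom = row$chrom,
        start = c(row$start, mid + 51), end = c(mid - 50, row$end),
        strand = row$strand)
      g_new <- dplyr::bind_rows(g_new[g_new$gene_id != g, , drop = FALSE], halves)
      corr_new <- corr_new[corr_new$gene_b != g, , drop = FALSE]
      defects[[length(defects) + 1L]] <- tibble::tibble(
        kind = "merge", expected_action = "merge",
        target_genes = list(halves$gene_id),
        query_genes = list(unname(partner_of[g])),
        true_models = list(row[, c("chrom", "start", "end", "strand")]))
      blocked <- c(blocked, neighbours(g))
    }
    # dropped ortholog: model intact, pair removed
    for (g in genome$gene_id) {
      if (!(g %in% one2one) || g %in% blocked) next
      if (any(neighbours(g) %in% blocked)) next
      if (runif(1) >= rates$drop_ortholog) next
      row <- g_new[g_new$gene_id == g, , drop = FALSE]
      if (!nrow(row)) next
      corr_new <- corr_new[corr_new$gene_b != g, , drop = FALSE]
      defects[[length(defects) + 1L]] <- tibble::tibble(
        kind = "drop_ortholog", expected_action = "replace",
        target_genes = list(g), query_genes = list(unname(partner_of[g])),
        true_models = list(row[, c("chrom", "start", "end", "strand")]))
      blocked <- c(blocked, neighbours(g))
    }
  })
  defects <- if (length(defects)) dplyr::bind_rows(defects) else
    tibble::tibble(kind = character(), expected_action = character(),
                   target_genes = list(), query_genes = list(), true_models = list())
  class(corr_new) <- c("synt_corr", class(tibble::tibble()))
  list(genome = as_genome(g_new, genome_id(genome)), corr = corr_new,
       defects = defects)
}

#' Plant operons on a genome
#'
#' Chooses `n` non-overlapping runs of adjacent genes as operons, with
#' sizes drawn uniformly from `size_range` (classically 2 to 8 genes).
#'
#' @param genome Genome tibble.
#' @param n Number of operons.
#' @param size_range Length-2 integer vector of operon sizes.
#' @param seed RNG seed.
#' @return An operon tibble (`operon_id`, `gene_id`).
#' @export
make_operons <- function(genome, n, size_range = c(2, 8), seed = 1) {
  if (n == 0) return(tibble::tibble(operon_id = character(), gene_id = character()))
  idx <- genome_index(genome)
  with_seed(seed, {
    free <- lapply(idx$chroms, function(cc) rep(TRUE, idx$by_chrom[[cc]]$n))
    names(free) <- idx$chroms
    out <- list()
    tries <- 0
    while (length(out) < n && tries < 50 * n) {
      tries <- tries + 1
      cc <- sample(idx$chroms, 1)
      size <- sample(size_range[1]:size_range[2], 1)
      ncc <- length(free[[cc]])
      if (ncc < size) next
      start <- sample.int(ncc - size + 1, 1)
      span <- start:(start + size - 1)
      if (!all(free[[cc]][span])) next
      free[[cc]][span] <- FALSE
      out[[length(out) + 1L]] <- tibble::tibble(
        operon_id = sprintf("OP%03d", length(out) + 1L),
        gene_id = idx$by_chrom[[cc]]$gene_id[span])
    }
    if (length(out) < n) stop_data("not enough adjacent free genes to place %d operons", n)
    dplyr::bind_rows(out)
  })
}
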