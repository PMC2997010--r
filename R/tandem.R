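#' Tandem expansion/contraction cases within blocks
#'
#' Inside each block, groups of co-orthologous genes (connected components
#' of the ortholog relation restricted to the block's intervals) with
#' unequal gene counts on the two sides are tandem asymmetries: a run of
#' adjacent family members on one side corresponds to a shorter run on the
#' other, reflecting lineage-specific gene-family expansion or contraction.
#' By default both runs must be adjacency-contiguous; interleaved cases are
#' reported with `loose = TRUE` when `include_loose` is set.
#'
#' @param blocks Block tibble (detected with one-to-many correspondences
#'   retained).
#' @param genome_a,genome_b Genome tibbles.
#' @param corr Correspondence tibble.
#' @param include_loose Also report non-contiguous (interleaved) cases.
#' @return A tibble with `block_id`, `direction` (`"A_expanded"` /
#'   `"B_expanded"`), `n_a`, `n_b`, list columns `genes_a`, `genes_b`, and
#'   `loose`.
#' @export
tandem_asymmetries <- function(blocks, genome_a, genome_b, corr,
                               include_loose = FALSE) {
  corr <- as_correspondence(corr)
  ia <- genome_index(genome_a)
  ib <- genome_index(genome_b)
  out <- purrr::map_dfr(seq_len(nrow(blocks)), function(k) {
    ba <- ia$by_chrom[[blocks$chrom_a[k]]]
    bb <- ib$by_chrom[[blocks$chrom_b[k]]]
    genes_a <- ba$gene_id[blocks$a_first[k]:blocks$a_last[k]]
    genes_b <- bb$gene_id[blocks$b_first[k]:blocks$b_last[k]]
    p <- corr[corr$gene_a %in% genes_a & corr$gene_b %in% genes_b, , drop = FALSE]
    if (!nrow(p)) return(NULL)
    # connected components over the bipartite pair graph (union-find)
    nodes <- c(paste0("A\r", unique(p$gene_a)), paste0("B\r", unique(p$gene_b)))
    parent <- setNames(nodes, nodes)
    find <- function(x) { while (parent[[x]] != x) { parent[[x]] <<- parent[[parent[[x]]]]; x <- parent[[x]] }; x }
    for (i in seq_len(nrow(p))) {
      ra <- find(paste0("A\r", p$gene_a[i])); rb <- find(paste0("B\r", p$gene_b[i]))
      if (ra != rb) parent[[ra]] <- rb
    }
    comp <- vapply(nodes, find, character(1))
    purrr::map_dfr(split(nodes, comp), function(members) {
      ga <- sub("^A\r", "", members[startsWith(members, "A\r")])
      gb <- sub("^B\r", "", members[startsWith(members, "B\r")])
      na <- length(ga); nb <- length(gb)
      if (na == nb) return(NULL)
      big <- if (na > nb) ga else gb
      small <- if (na > nb) gb else ga
      # every gene of the larger run must have a partner in the smaller run
      pc <- p[p$gene_a %in% ga & p$gene_b %in% gb, , drop = FALSE]
      covered <- if (na > nb) all(big %in% pc$gene_a) else all(big %in% pc$gene_b)
      if (!covered) return(NULL)
      contig <- function(genes, idx) {
        o <- sort(unname(idx$ord_of[genes]))
        identical(o, seq(min(o), max(o)))
      }
      loose <- !(contig(ga, ia) && contig(gb, ib))
      if (loose && !include_loose) return(NULL)
      tibble::tibble(block_id = blocks$block_id[k],
                     direction = if (na > nb) "A_expanded" else "B_expanded",
                     n_a = na, n_b = nb,
                     genes_a = list(ga[order(unname(ia$ord_of[ga]))]),
                     genes_b = list(gb[order(unname(ib$ord_of[gb]))]),
                     loose = loose)
    })
  })
  if (is.null(out) || !nrow(out))
    return(tibble::tibble(block_id = character(), direction = character(),
                          n_a = integer(), n_b = integer(),
                          genes_a = list(), genes_b = list(), loose = logical()))
  out
}
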