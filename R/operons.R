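#' Operon annotations
#'
#' Operons are runs of adjacent genes on one chromosome transcribed as a
#' unit (2-8 genes typical). They are represented long: one row per member
#' gene with columns `operon_id`, `gene_id`, ordered by position within the
#' operon. The file format is one operon per line: operon id, a tab, then
#' comma-separated member gene ids.
#'
#' @param path Path to the operon TSV.
#' @return A tibble with columns `operon_id`, `gene_id`.
#' @export
read_operons <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  purrr::map_dfr(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 2) stop_data("malformed operon line: %s", ln)
    tibble::tibble(operon_id = f[1],
                   gene_id = strsplit(f[2], ",", fixed = TRUE)[[1]])
  })
}

#' @rdname read_operons
#' @param operons Operon tibble.
#' @param path Output path.
#' @export
write_operons <- function(operons, path) {
  d <- dplyr::summarise(dplyr::group_by(operons, .data$operon_id),
                        genes = paste(.data$gene_id, collapse = ","),
                        .groups = "drop")
  writeLines(sprintf("%s\t%s", d$operon_id, d$genes), path)
  invisible(path)
}

# Validate operons against a genome: members exist and are adjacent genes
# on one chromosome.
check_operons <- function(operons, genome) {
  idx <- genome_index(genome)
  for (grp in split(operons$gene_id, operons$operon_id)) {
    unknown <- setdiff(grp, names(idx$ord_of))
    if (length(unknown))
      stop_data("operon references unknown gene '%s'", unknown[1])
    chroms <- unique(unname(idx$chrom_of[grp]))
    ords <- sort(unname(idx$ord_of[grp]))
    if (length(chroms) != 1L || !identical(ords, seq(min(ords), max(ords))))
      stop_data("operon members must be adjacent genes on one chromosome")
  }
  invisible(TRUE)
}

#' Conserved operons
#'
#' An operon is conserved when every member gene is a matched gene within a
#' single synteny block: all members lie in the block's A interval and each
#' appears among the block's matched pairs. Operons straddling blocks, or
#' containing a mismatch gene, are not conserved. A user-supplied conserved
#' set can be used downstream instead of this definition.
#'
#' @param operons Operon tibble (genes on genome A).
#' @param blocks Block tibble from detection.
#' @param genome Optional genome A, used to validate the operon annotation.
#' @return A tibble with one row per conserved operon: `operon_id`,
#'   `block_id`.
#' @export
conserved_operons <- function(operons, blocks, genome = NULL) {
  if (!is.null(genome)) check_operons(operons, genome)
  matched_sets <- lapply(blocks$pairs, function(p) unique(p$gene_a))
  purrr::map_dfr(split(operons$gene_id, operons$operon_id), function(genes) {
    hit <- which(vapply(matched_sets, function(s) all(genes %in% s), logical(1)))
    if (length(hit)) tibble::tibble(block_id = blocks$block_id[hit[1]]) else NULL
  }, .id = "operon_id")
}

#' Operonic synteny blocks
#'
#' A block qualifies as operonic when the genes of conserved operons make
#' up at least `threshold` of the genes in its A interval (mismatch genes
#' included in the denominator). The classic definition uses perfect blocks
#' and threshold one half, boundary included.
#'
#' @param blocks Block tibble.
#' @param genome_a Genome A (to list interval genes).
#' @param operon_genes Character vector of genes belonging to conserved
#'   operons (e.g. members of [conserved_operons()] output).
#' @param threshold Fraction in `(0, 1]`, default 0.5.
#' @return The qualifying subset of `blocks` with an added
#'   `operonic_fraction` column.
#' @export
operonic_blocks <- function(blocks, genome_a, operon_genes, threshold = 0.5) {
  if (threshold <= 0 || threshold > 1) stop_data("threshold must be in (0, 1]")
  idx <- genome_index(genome_a)
  frac <- vapply(seq_len(nrow(blocks)), function(k) {
    b <- idx$by_chrom[[blocks$chrom_a[k]]]
    genes <- b$gene_id[blocks$a_first[k]:blocks$a_last[k]]
    mean(genes %in% operon_genes)
  }, numeric(1))
  out <- blocks[frac >= threshold - 1e-12, , drop = FALSE]
  out$operonic_fraction <- frac[frac >= threshold - 1e-12]
  out
}

#' Genomic coverage of operons
#'
#' Union of operon spans (first member start to last member end) over the
#' genome length; overlapping operons are not double counted.
#'
#' @param operons Operon tibble.
#' @param genome Genome carrying the operons.
#' @param lengths Optional chromosome length table (`chrom`, `length`).
#' @return A tibble like [genome_coverage()]'s.
#' @export
operon_coverage <- function(operons, genome, lengths = NULL) {
  idx <- genome_index(genome)
  spans <- purrr::map_dfr(split(operons$gene_id, operons$operon_id), function(genes) {
    rows <- genome[genome$gene_id %in% genes, , drop = FALSE]
    tibble::tibble(chrom = rows$chrom[1], start = min(rows$start), end = max(rows$end))
  })
  fake <- tibble::tibble(chrom_a = spans$chrom, a_start = spans$start, a_end = spans$end)
  genome_coverage(fake, genome, side = "a", lengths = lengths)
}
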