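#' Ortholog correspondence tables
#'
#' The correspondence between two genomes is a deduplicated set of ortholog
#' pairs `(gene_a, gene_b)`; one-to-many and many-to-many relations are
#' permitted. Genes present in at least one pair are *in-map*, all others
#' are *out-map*.
#'
#' @param x A data frame whose first two columns are gene ids in genome A
#'   and genome B (extra columns are ignored).
#' @return A tibble of class `synt_corr` with columns `gene_a`, `gene_b`.
#' @export
as_correspondence <- function(x) {
  x <- tibble::as_tibble(x)
  if (ncol(x) < 2) stop_data("correspondence table needs two columns")
  x <- tibble::tibble(gene_a = as.character(x[[1]]), gene_b = as.character(x[[2]]))
  x <- dplyr::distinct(dplyr::arrange(x, .data$gene_a, .data$gene_b))
  class(x) <- c("synt_corr", class(tibble::tibble()))
  x
}

#' Read an ortholog pair file
#'
#' Two tab-separated columns of gene ids; duplicate rows are collapsed.
#' When both genomes are supplied the pairs are validated: pairs naming a
#' gene absent from either genome are dropped with a warning (lenient
#' default) or raise an error (`strict = TRUE`). The dropped pairs are
#' attached as attribute `"orphans"` for inspection.
#'
#' @param path Path to the TSV file.
#' @param genome_a,genome_b Optional genome tibbles used for validation.
#' @param strict Raise an error on unknown gene ids instead of dropping.
#' @return A [as_correspondence()] tibble.
#' @export
read_correspondence <- function(path, genome_a = NULL, genome_b = NULL, strict = FALSE) {
  if (!file.exists(path)) stop_data("correspondence file not found: %s", path)
  d <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                       col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE)
  if (nrow(d) && !is.na(suppressWarnings(d[[1]][1])) && d[[1]][1] %in% c("gene_a", "gene_id_a"))
    d <- d[-1, , drop = FALSE]
  corr <- as_correspondence(d)
  validate_correspondence(corr, genome_a, genome_b, strict = strict)
}

#' @rdname read_correspondence
#' @param corr A correspondence tibble.
#' @export
validate_correspondence <- function(corr, genome_a = NULL, genome_b = NULL, strict = FALSE) {
  corr <- as_correspondence(corr)
  orphans <- tibble::tibble(gene_a = character(), gene_b = character(), reason = character())
  if (!is.null(genome_a)) {
    bad <- !corr$gene_a %in% genome_a$gene_id
    if (any(bad)) orphans <- dplyr::bind_rows(orphans,
      tibble::tibble(gene_a = corr$gene_a[bad], gene_b = corr$gene_b[bad],
                     reason = "unknown gene in genome A"))
  }
  if (!is.null(genome_b)) {
    bad <- !corr$gene_b %in% genome_b$gene_id
    if (any(bad)) orphans <- dplyr::bind_rows(orphans,
      tibble::tibble(gene_a = corr$gene_a[bad], gene_b = corr$gene_b[bad],
                     reason = "unknown gene in genome B"))
  }
  orphans <- dplyr::distinct(orphans)
  if (nrow(orphans)) {
    if (strict)
      stop_data("correspondence references %d unknown gene id pair(s), e.g. %s/%s",
                nrow(orphans), orphans$gene_a[1], orphans$gene_b[1])
    warn(sprintf("dropped %d correspondence pair(s) with unknown gene ids", nrow(orphans)))
    corr <- dplyr::anti_join(corr, orphans[, c("gene_a", "gene_b")],
                             by = c("gene_a", "gene_b"))
    class(corr) <- c("synt_corr", class(tibble::tibble()))
  }
  attr(corr, "orphans") <- orphans
  corr
}

#' Write an ortholog pair file
#' @param corr A correspondence tibble.
#' @param path Output path.
#' @export
write_correspondence <- function(corr, path) {
  corr <- as_correspondence(corr)
  writeLines(c("gene_a\tgene_b", sprintf("%s\t%s", corr$gene_a, corr$gene_b)), path)
  invisible(path)
}

#' Partition genes into in-map and out-map sets
#'
#' A gene is in-map when it has at least one ortholog in the other genome
#' under `corr`, and out-map otherwise. The partition is exhaustive and
#' disjoint per genome.
#'
#' @param genome_a,genome_b Genome tibbles.
#' @param corr Correspondence tibble.
#' @return A tibble with columns `genome` (`"A"`/`"B"`), `gene_id`,
#'   `status` (`"in_map"`/`"out_map"`).
#' @export
classify_markers <- function(genome_a, genome_b, corr) {
  corr <- as_correspondence(corr)
  dplyr::bind_rows(
    tibble::tibble(genome = "A", gene_id = genome_a$gene_id,
                   status = ifelse(genome_a$gene_id %in% corr$gene_a, "in_map", "out_map")),
    tibble::tibble(genome = "B", gene_id = genome_b$gene_id,
                   status = ifelse(genome_b$gene_id %in% corr$gene_b, "in_map", "out_map"))
  )
}

#' Merge newly accepted ortholog pairs into a correspondence
#'
#' Only novel pairs are added; the result stays deduplicated.
#'
#' @param corr Existing correspondence tibble.
#' @param new_pairs A data frame with columns `gene_a`, `gene_b`.
#' @export
merge_correspondence <- function(corr, new_pairs) {
  as_correspondence(dplyr::bind_rows(as_correspondence(corr),
                                     as_correspondence(new_pairs)))
}
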