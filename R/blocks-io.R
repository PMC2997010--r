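#' Write and read block tables
#'
#' `write_blocks()` serializes a block tibble either as a TSV (one row per
#' block; matched pairs encoded `geneA:geneB` comma-separated, mismatch
#' gene sets comma-separated) or as a BED dialect with one record per
#' genome per block (coordinates converted to BED's 0-based half-open
#' convention at the boundary). Output is byte-stable for a fixed input.
#' `read_blocks()` inverts the TSV form, preserving all fields.
#'
#' @param blocks A `synt_blocks` tibble.
#' @param path Output path.
#' @param format `"tsv"` or `"bed"`.
#' @export
write_blocks <- function(blocks, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "bed") {
    lines <- character(0)
    if (nrow(blocks)) {
      bed <- function(chrom, start, end, id, genome) {
        sprintf("%s\t%d\t%d\t%s|%s", chrom, as.integer(start) - 1L,
                as.integer(end), id, genome)
      }
      lines <- as.vector(rbind(
        bed(blocks$chrom_a, blocks$a_start, blocks$a_end, blocks$block_id, "A"),
        bed(blocks$chrom_b, blocks$b_start, blocks$b_end, blocks$block_id, "B")))
    }
    writeLines(lines, path)
    return(invisible(path))
  }
  join <- function(x) vapply(x, function(v) paste(v, collapse = ","), character(1))
  d <- tibble::as_tibble(blocks)
  d$pairs <- vapply(blocks$pairs, function(p) paste(paste0(p$gene_a, ":", p$gene_b),
                                                    collapse = ","), character(1))
  d$in_mm_genes_a <- join(lapply(blocks$mm_genes, `[[`, "in_mm_a"))
  d$out_mm_genes_a <- join(lapply(blocks$mm_genes, `[[`, "out_mm_a"))
  d$in_mm_genes_b <- join(lapply(blocks$mm_genes, `[[`, "in_mm_b"))
  d$out_mm_genes_b <- join(lapply(blocks$mm_genes, `[[`, "out_mm_b"))
  d$mm_genes <- NULL
  d$parent_id[is.na(d$parent_id)] <- ""
  readr::write_tsv(d, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_blocks
#' @return `read_blocks()`: a `synt_blocks` tibble.
#' @export
read_blocks <- function(path) {
  d <- readr::read_tsv(path, col_types = readr::cols(
    block_id = "c", chrom_a = "c", chrom_b = "c", orientation = "c",
    strand_pattern = "c", parent_id = "c", nested = "l", pairs = "c",
    in_mm_genes_a = "c", out_mm_genes_a = "c",
    in_mm_genes_b = "c", out_mm_genes_b = "c",
    .default = readr::col_double()), progress = FALSE, na = character())
  splitc <- function(x) lapply(x, function(v) if (identical(v, "")) character(0)
                               else strsplit(v, ",", fixed = TRUE)[[1]])
  d$mm_genes <- purrr::pmap(list(splitc(d$in_mm_genes_a), splitc(d$out_mm_genes_a),
                                 splitc(d$in_mm_genes_b), splitc(d$out_mm_genes_b)),
                            function(ia, oa, ib, ob)
                              list(in_mm_a = ia, out_mm_a = oa, in_mm_b = ib, out_mm_b = ob))
  d$pairs <- lapply(splitc(d$pairs), function(v) {
    if (!length(v)) return(tibble::tibble(gene_a = character(), gene_b = character()))
    parts <- strsplit(v, ":", fixed = TRUE)
    tibble::tibble(gene_a = vapply(parts, `[[`, character(1), 1),
                   gene_b = vapply(parts, `[[`, character(1), 2))
  })
  d$in_mm_genes_a <- d$out_mm_genes_a <- d$in_mm_genes_b <- d$out_mm_genes_b <- NULL
  d$parent_id[d$parent_id == ""] <- NA_character_
  attr(d, "spec") <- NULL
  attr(d, "problems") <- NULL
  for (col in c("a_first", "a_last", "b_first", "b_last",
                "n_genes_a", "n_genes_b", "n_matched_a", "n_matched_b",
                "in_mm_a", "out_mm_a", "in_mm_b", "out_mm_b"))
    d[[col]] <- as.integer(d[[col]])
  class(d) <- c("synt_blocks", class(tibble::tibble()))
  d
}
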