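#' Gene-order genome tables
#'
#' A genome is represented as a tibble with one row per gene marker and
#' columns `gene_id`, `chrom`, `start`, `end`, `strand`. Coordinates are
#' 1-based and inclusive; `strand` is `"+"` or `"-"`. Rows are kept in the
#' deterministic total order `(chrom, start, end, gene_id)` so that every
#' gene has a well-defined ordinal position on its chromosome regardless of
#' the order in which the input file listed it.
#'
#' @param x A data frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @param genome_id Identifier attached to the genome (attribute
#'   `"genome_id"`).
#' @return A tibble of class `synt_genome`, sorted into gene order.
#' @export
as_genome <- function(x, genome_id = "genome") {
  x <- tibble::as_tibble(x)
  need <- c("gene_id", "chrom", "start", "end", "strand")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop_data("genome table is missing column(s): %s", paste(miss, collapse = ", "))
  x <- dplyr::select(x, dplyr::all_of(need))
  x$gene_id <- as.character(x$gene_id)
  x$chrom <- as.character(x$chrom)
  x$start <- as.numeric(x$start)
  x$end <- as.numeric(x$end)
  x$strand <- as.character(x$strand)
  if (anyNA(x$start) || anyNA(x$end)) stop_data("non-numeric gene coordinates")
  if (any(x$start != round(x$start)) || any(x$end != round(x$end)))
    stop_data("gene coordinates must be integers")
  if (any(x$start < 1)) stop_data("coordinates are 1-based: start position 0 or below found")
  bad <- which(x$start > x$end)
  if (length(bad)) stop_data("start > end for gene '%s'", x$gene_id[bad[1]])
  if (!all(x$strand %in% c("+", "-")))
    stop_data("strand must be '+' or '-' (offending gene '%s')",
              x$gene_id[which(!x$strand %in% c("+", "-"))[1]])
  dup <- x$gene_id[duplicated(x$gene_id)]
  if (length(dup)) stop_data("duplicate gene_id '%s'", dup[1])
  x <- dplyr::arrange(x, .data$chrom, .data$start, .data$end, .data$gene_id)
  attr(x, "genome_id") <- genome_id
  class(x) <- c("synt_genome", class(tibble::tibble()))
  x
}

#' @export
print.synt_genome <- function(x, ...) {
  cat(sprintf("# Genome '%s': %d genes on %d chromosome(s)\n",
              genome_id(x), nrow(x), dplyr::n_distinct(x$chrom)))
  NextMethod()
}

#' @rdname as_genome
#' @export
genome_id <- function(x) attr(x, "genome_id") %||% "genome"

#' Read a five-column genome table
#'
#' Reads a tab-separated genome file with columns gene id, chromosome (or
#' supercontig), start, end and strand. A header line is detected and
#' skipped automatically; lines starting with `#` are comments. Malformed
#' rows (wrong number of fields, non-integer coordinates, `start > end`,
#' or a strand symbol other than `+`/`-`) raise an error naming the line.
#'
#' @param path Path to a TSV file.
#' @param genome_id Identifier for the genome; defaults to the file stem.
#' @return A [as_genome()] tibble.
#' @export
read_genome_table <- function(path, genome_id = NULL) {
  if (!file.exists(path)) stop_data("genome file not found: %s", path)
  genome_id <- genome_id %||% sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (!length(keep)) return(as_genome(tibble::tibble(
    gene_id = character(), chrom = character(), start = numeric(),
    end = numeric(), strand = character()), genome_id))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  # tolerate a header row: first line whose coordinate fields are non-numeric
  first <- fields[[1]]
  if (length(first) >= 5 && (is.na(suppressWarnings(as.numeric(first[3]))) ||
                             is.na(suppressWarnings(as.numeric(first[4]))))) {
    keep <- keep[-1]
    fields <- fields[-1]
  }
  rows <- vector("list", length(fields))
  for (k in seq_along(fields)) {
    f <- fields[[k]]
    line_no <- keep[k]
    if (length(f) < 5)
      stop_data("line %d: expected 5 tab-separated fields, got %d", line_no, length(f))
    s <- suppressWarnings(as.numeric(f[3])); e <- suppressWarnings(as.numeric(f[4]))
    if (is.na(s) || is.na(e) || s != round(s) || e != round(e))
      stop_data("line %d: non-integer coordinate", line_no)
    if (s < 1) stop_data("line %d: coordinates are 1-based, found %s", line_no, f[3])
    if (s > e) stop_data("line %d: start > end", line_no)
    if (!f[5] %in% c("+", "-")) stop_data("line %d: bad strand symbol '%s'", line_no, f[5])
    rows[[k]] <- tibble::tibble(gene_id = f[1], chrom = f[2], start = s, end = e, strand = f[5])
  }
  as_genome(dplyr::bind_rows(rows), genome_id)
}

#' Write a genome table
#'
#' Inverse of [read_genome_table()]; output is byte-stable for a given
#' genome (genes in canonical order, one header line).
#'
#' @param genome A genome tibble.
#' @param path Output path.
#' @export
write_genome_table <- function(genome, path) {
  genome <- as_genome(genome, genome_id(genome))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# genome_id=%s", genome_id(genome)), con)
  writeLines("gene_id\tchrom\tstart\tend\tstrand", con)
  writeLines(sprintf("%s\t%s\t%d\t%d\t%s", genome$gene_id, genome$chrom,
                     as.integer(genome$start), as.integer(genome$end), genome$strand), con)
  invisible(path)
}

#' Read a genome from GFF3, one marker per gene locus
#'
#' Reduces gene loci to single markers using the longest isoform: among the
#' mRNAs of a gene, the representative is the isoform with the greatest
#' summed CDS length (ties broken by greater genomic span, then by isoform
#' id). Genes without mRNA children fall back to the gene feature's own
#' span, with a warning when mRNAs exist but lack Parent linkage.
#'
#' @param path Path to a GFF3 file.
#' @param genome_id Identifier for the genome; defaults to the file stem.
#' @param feature_type Feature type treated as the gene locus (default
#'   `"gene"`).
#' @return A [as_genome()] tibble.
#' @export
read_gff3_genome <- function(path, genome_id = NULL, feature_type = "gene") {
  if (!file.exists(path)) stop_data("GFF3 file not found: %s", path)
  genome_id <- genome_id %||% sub("\\.[^.]*$", "", basename(path))
  g <- tibble::as_tibble(rtracklayer::readGFF(path))
  g$type <- as.character(g$type)
  id_of <- function(d) as.character(d$ID)
  parent_of <- function(d) {
    p <- d$Parent
    vapply(p, function(v) if (length(v)) as.character(v)[1] else NA_character_, character(1))
  }
  genes <- g[g$type == feature_type, , drop = FALSE]
  if (!nrow(genes)) stop_data("no '%s' features in %s", feature_type, path)
  mrna <- g[g$type %in% c("mRNA", "transcript"), , drop = FALSE]
  cds <- g[g$type == "CDS", , drop = FALSE]
  mrna_parent <- if (nrow(mrna)) parent_of(mrna) else character()
  if (nrow(mrna) && anyNA(mrna_parent))
    warn("mRNA feature(s) without Parent linkage; affected genes fall back to the gene span")
  cds_parent <- if (nrow(cds)) parent_of(cds) else character()
  cds_len_by_mrna <- if (nrow(cds)) {
    tapply(cds$end - cds$start + 1, cds_parent, sum)
  } else numeric()

  out <- purrr::map_dfr(seq_len(nrow(genes)), function(i) {
    gid <- id_of(genes[i, ])
    iso <- which(!is.na(mrna_parent) & mrna_parent == gid)
    if (!length(iso)) {
      return(tibble::tibble(gene_id = gid, chrom = as.character(genes$seqid[i]),
                            start = genes$start[i], end = genes$end[i],
                            strand = as.character(genes$strand[i])))
    }
    iso_id <- id_of(mrna[iso, , drop = FALSE])
    cds_len <- unname(ifelse(iso_id %in% names(cds_len_by_mrna),
                             cds_len_by_mrna[iso_id], 0))
    span <- mrna$end[iso] - mrna$start[iso] + 1
    pick <- order(-cds_len, -span, iso_id)[1]
    k <- iso[pick]
    tibble::tibble(gene_id = gid, chrom = as.character(mrna$seqid[k]),
                   start = mrna$start[k], end = mrna$end[k],
                   strand = as.character(mrna$strand[k]))
  })
  as_genome(out, genome_id)
}

# Ordinal index of a genome: per-chromosome vectors used by detection.
genome_index <- function(genome) {
  genome <- as_genome(genome, genome_id(genome))
  chroms <- unique(genome$chrom)
  by_chrom <- lapply(chroms, function(cc) {
    d <- genome[genome$chrom == cc, , drop = FALSE]
    list(gene_id = d$gene_id, start = d$start, end = d$end, strand = d$strand,
         n = nrow(d))
  })
  names(by_chrom) <- chroms
  ord <- unlist(lapply(by_chrom, function(b) seq_len(b$n)), use.names = FALSE)
  list(genome_id = genome_id(genome), chroms = chroms, by_chrom = by_chrom,
       chrom_of = setNames(genome$chrom, genome$gene_id),
       ord_of = setNames(ord, unlist(lapply(by_chrom, `[[`, "gene_id"), use.names = FALSE)))
}
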