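#' Genomic coverage of synteny blocks
#'
#' Fraction of each chromosome (and of the genome, length-weighted) covered
#' by the union of block bp spans, so overlapping blocks are not double
#' counted. Chromosome lengths default to the maximum gene end observed; a
#' lengths table overrides. Optionally the spans of degenerate single-gene
#' blocks ([singleton_blocks()]) are added to the union.
#'
#' @param blocks A block tibble.
#' @param genome The genome the coverage is computed on.
#' @param side Which side of the blocks lies in `genome`: `"a"` or `"b"`.
#' @param lengths Optional data frame with columns `chrom`, `length`.
#' @param singletons Optional singleton tibble (rows for this genome are
#'   selected automatically when a `genome` column is present).
#' @return A tibble with one row per chromosome plus a `TOTAL` row:
#'   `chrom`, `length_bp`, `covered_bp`, `coverage_pct`.
#' @export
genome_coverage <- function(blocks, genome, side = c("a", "b"), lengths = NULL,
                            singletons = NULL) {
  side <- match.arg(side)
  chrom_col <- paste0("chrom_", side)
  start_col <- paste0(side, "_start")
  end_col <- paste0(side, "_end")
  chroms <- unique(genome$chrom)
  if (nrow(blocks)) {
    unknown <- setdiff(unique(blocks[[chrom_col]]), chroms)
    if (length(unknown)) stop_data("block on unknown chromosome '%s'", unknown[1])
  }
  len_of <- tapply(genome$end, genome$chrom, max)
  if (!is.null(lengths)) {
    lengths <- tibble::as_tibble(lengths)
    len_of[as.character(lengths$chrom)] <- as.numeric(lengths$length)
  }
  spans <- tibble::tibble(chrom = blocks[[chrom_col]],
                          start = blocks[[start_col]], end = blocks[[end_col]])
  if (!is.null(singletons) && nrow(singletons)) {
    s <- singletons
    if ("genome" %in% names(s)) s <- s[s$genome == toupper(side), , drop = FALSE]
    spans <- dplyr::bind_rows(spans, tibble::tibble(chrom = s$chrom,
                                                    start = s$start, end = s$end))
  }
  per <- purrr::map_dfr(chroms, function(cc) {
    sp <- spans[spans$chrom == cc, , drop = FALSE]
    tibble::tibble(chrom = cc, length_bp = as.numeric(len_of[[cc]]),
                   covered_bp = union_width(sp$start, sp$end))
  })
  per$covered_bp <- pmin(per$covered_bp, per$length_bp)
  total <- tibble::tibble(chrom = "TOTAL", length_bp = sum(per$length_bp),
                          covered_bp = sum(per$covered_bp))
  out <- dplyr::bind_rows(per, total)
  out$coverage_pct <- 100 * out$covered_bp / out$length_bp
  out
}

#' Block size statistics
#'
#' Mean, median and range of block spans in kb (computed on the A-genome
#' spans unless `side = "b"`), plus the range of matched-gene counts,
#' overall or per chromosome.
#'
#' @param blocks A block tibble.
#' @param by `"genome"` for one summary row, `"chrom"` for per-chromosome
#'   rows.
#' @param side Side whose spans are summarized.
#' @return A tibble of summary rows.
#' @export
block_size_stats <- function(blocks, by = c("genome", "chrom"), side = c("a", "b")) {
  by <- match.arg(by)
  side <- match.arg(side)
  if (!nrow(blocks))
    return(tibble::tibble(chrom = character(), n_blocks = integer(),
                          mean_kb = numeric(), median_kb = numeric(),
                          min_kb = numeric(), max_kb = numeric(),
                          min_genes = integer(), max_genes = integer()))
  d <- tibble::tibble(chrom = blocks[[paste0("chrom_", side)]],
                      span = blocks[[paste0("span_", side)]] / 1000,
                      genes = blocks[[paste0("n_matched_", side)]])
  if (by == "genome") d$chrom <- "ALL"
  dplyr::summarise(dplyr::group_by(d, .data$chrom),
                   n_blocks = dplyr::n(),
                   mean_kb = mean(.data$span), median_kb = median(.data$span),
                   min_kb = min(.data$span), max_kb = max(.data$span),
                   min_genes = min(.data$genes), max_genes = max(.data$genes),
                   .groups = "drop")
}

#' Chromosome-by-chromosome block distribution
#'
#' Counts blocks per (A-chromosome, B-chromosome) cell, with nested blocks
#' counted separately, and reports the fraction of blocks falling on
#' homologous chromosome pairs. By default chromosomes with identical names
#' are homologous; a two-column `homology` table (`chrom_a`, `chrom_b`)
#' overrides. Chromosomes absent from the homology table are treated as
#' unplaced.
#'
#' @param blocks A block tibble.
#' @param homology Optional data frame pairing homologous chromosome names.
#' @return A tibble of class `synt_distmat` with columns `chrom_a`,
#'   `chrom_b`, `n_blocks`, `n_nested`, `homologous`; attributes
#'   `homologous_fraction` (percent, non-nested and nested alike) and
#'   `margins` (per-chromosome totals).
#' @export
distribution_matrix <- function(blocks, homology = NULL) {
  d <- dplyr::summarise(dplyr::group_by(tibble::as_tibble(blocks),
                                        .data$chrom_a, .data$chrom_b),
                        n_blocks = dplyr::n(), n_nested = sum(.data$nested),
                        .groups = "drop")
  if (is.null(homology)) {
    d$homologous <- d$chrom_a == d$chrom_b
  } else {
    homology <- tibble::as_tibble(homology)
    key <- paste(homology$chrom_a, homology$chrom_b, sep = "\r")
    d$homologous <- paste(d$chrom_a, d$chrom_b, sep = "\r") %in% key
  }
  tot <- sum(d$n_blocks)
  attr(d, "homologous_fraction") <- if (tot) 100 * sum(d$n_blocks[d$homologous]) / tot else NA_real_
  attr(d, "margins") <- list(
    a = dplyr::summarise(dplyr::group_by(d, .data$chrom_a),
                         n_blocks = sum(.data$n_blocks), .groups = "drop"),
    b = dplyr::summarise(dplyr::group_by(d, .data$chrom_b),
                         n_blocks = sum(.data$n_blocks), .groups = "drop"))
  class(d) <- c("synt_distmat", class(tibble::tibble()))
  d
}

#' @export
print.synt_distmat <- function(x, ...) {
  cat(sprintf("# Block distribution matrix; %.1f%% of blocks on homologous chromosomes\n",
              attr(x, "homologous_fraction")))
  NextMethod()
}

#' Compare block sizes between two groups (Mann-Whitney U)
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test on block spans between
#' two groups selected by filter expressions, e.g. X chromosome versus
#' autosomes or chromosome arms versus centers. The exact null distribution
#' is used when both groups have at most 20 observations and no ties occur;
#' otherwise the tie-corrected normal approximation (with continuity
#' correction) is used.
#'
#' @param blocks A block tibble, or a numeric vector of sizes for group 1
#'   (in which case `group1` must be the numeric vector for group 2).
#' @param group1,group2 Filter expressions evaluated inside `blocks`.
#' @param measure Column to compare (default `span_a`).
#' @return An object of class `synt_mwu` with elements `statistic` (U for
#'   group 1), `p_value`, `method`, `n1`, `n2`; supports [tidy()] and
#'   [glance()].
#' @export
compare_block_sizes <- function(blocks, group1, group2, measure = "span_a") {
  if (is.numeric(blocks)) {
    x <- blocks; y <- group1
  } else {
    q1 <- enquo(group1); q2 <- enquo(group2)
    x <- blocks[[measure]][eval_tidy(q1, blocks)]
    y <- blocks[[measure]][eval_tidy(q2, blocks)]
  }
  if (!length(x) || !length(y)) stop_data("both groups must be nonempty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- length(x) <= 20 && length(y) <= 20 && !ties
  wt <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided",
                                     exact = exact, correct = TRUE))
  structure(list(statistic = unname(wt$statistic), p_value = wt$p.value,
                 method = if (exact) "exact" else "normal approximation (tie-corrected)",
                 n1 = length(x), n2 = length(y)),
            class = "synt_mwu")
}

#' @export
print.synt_mwu <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (n = %d vs %d), two-sided p = %.4g [%s]\n",
              x$statistic, x$n1, x$n2, x$p_value, x$method))
  invisible(x)
}

#' Random-breakage significance of large blocks
#'
#' Monte-Carlo test of whether blocks as large as the observed ones could
#' arise under a random breakage model: `n_blocks - 1` breakpoints are
#' placed uniformly on the concatenated genome and the maximal segment
#' length is recorded; the p-value for a block of span `s` is the fraction
#' of replicates whose maximal segment is at least `s`, with a pseudo-count
#' of one on numerator and denominator. All spans share one null sample, so
#' testing many blocks costs the same as testing one.
#'
#' @param spans Numeric vector of observed block spans (bp).
#' @param genome_length Total genome length (bp).
#' @param n_blocks Observed number of (non-nested) blocks, used as the
#'   segment count of the null.
#' @param n_iter Number of Monte-Carlo replicates (warning below 100).
#' @param seed RNG seed for reproducibility.
#' @return A tibble with `span`, `p_value`.
#' @export
random_breakage_test <- function(spans, genome_length, n_blocks,
                                 n_iter = 10000, seed = 1) {
  if (n_iter < 100) warn("n_iter < 100: random-breakage p-values will be coarse")
  if (any(spans > genome_length)) stop_data("block span exceeds genome length")
  k <- n_blocks
  max_seg <- with_seed(seed, {
    if (k <= 1) rep(genome_length, n_iter)
    else vapply(seq_len(n_iter), function(i) {
      cuts <- sort(runif(k - 1, 0, genome_length))
      max(diff(c(0, cuts, genome_length)))
    }, numeric(1))
  })
  p <- vapply(spans, function(s) (1 + sum(max_seg >= s)) / (1 + n_iter), numeric(1))
  tibble::tibble(span = spans, p_value = p)
}

#' Multiple-testing adjustment
#'
#' Benjamini-Hochberg by default, Bonferroni by flag; a thin wrapper around
#' [stats::p.adjust()] so the correction used downstream is explicit.
#'
#' @param p Numeric vector of p-values.
#' @param method `"BH"` or `"bonferroni"`.
#' @export
adjust_pvalues <- function(p, method = c("BH", "bonferroni")) {
  p.adjust(p, method = match.arg(method))
}

#' Assign blocks to chromosome regions
#'
#' Labels each block with the region (for example `arm` or `center`)
#' containing its midpoint on the chosen side. Regions are supplied as a
#' table of bp intervals per chromosome; midpoints outside every region get
#' `NA`.
#'
#' @param blocks A block tibble.
#' @param regions Data frame with columns `chrom`, `start`, `end`, `label`.
#' @param side Side of the block used (`"a"` default).
#' @return `blocks` with an added `region` column.
#' @export
assign_regions <- function(blocks, regions, side = c("a", "b")) {
  side <- match.arg(side)
  regions <- tibble::as_tibble(regions)
  mid <- (blocks[[paste0(side, "_start")]] + blocks[[paste0(side, "_end")]]) / 2
  chrom <- blocks[[paste0("chrom_", side)]]
  blocks$region <- vapply(seq_along(mid), function(i) {
    hit <- regions$chrom == chrom[i] & regions$start <= mid[i] & regions$end >= mid[i]
    if (any(hit)) as.character(regions$label[which(hit)[1]]) else NA_character_
  }, character(1))
  blocks
}
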