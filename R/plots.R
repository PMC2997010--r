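#' Plot synteny blocks as an anchored dot plot
#'
#' One segment per block from its A-genome span to its B-genome span,
#' faceted by chromosome pair; inverted blocks slope downwards, nested
#' blocks are highlighted.
#'
#' @param object A `synt_blocks` tibble.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot synt_blocks
#' @export
autoplot.synt_blocks <- function(object, ...) {
  d <- tibble::as_tibble(object)
  if (!nrow(d)) return(ggplot2::ggplot() + ggplot2::theme_void())
  d$y_start <- ifelse(d$orientation == "inverted", d$b_end, d$b_start)
  d$y_end <- ifelse(d$orientation == "inverted", d$b_start, d$b_end)
  ggplot2::ggplot(d) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$a_start / 1e3, xend = .data$a_end / 1e3,
                                       y = .data$y_start / 1e3, yend = .data$y_end / 1e3,
                                       colour = .data$orientation,
                                       linetype = .data$nested),
                          linewidth = 1.2) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$chrom_b),
                        cols = ggplot2::vars(.data$chrom_a),
                        scales = "free") +
    ggplot2::labs(x = "genome A position (kb)", y = "genome B position (kb)",
                  colour = "orientation", linetype = "nested") +
    ggplot2::theme_bw()
}

#' Plot a block distribution matrix as a tile heat map
#'
#' @param object A `synt_distmat` tibble from [distribution_matrix()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot synt_distmat
#' @export
autoplot.synt_distmat <- function(object, ...) {
  d <- tibble::as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$chrom_b, y = .data$chrom_a,
                                  fill = .data$n_blocks)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%d (%d)", .data$n_blocks,
                                                    .data$n_nested)),
                       colour = "white") +
    ggplot2::labs(x = "genome B chromosome", y = "genome A chromosome",
                  fill = "blocks") +
    ggplot2::theme_minimal()
}

#' Plot coverage as a function of a varied parameter
#'
#' Convenience for mismatch-relaxation sweeps: takes a tibble with columns
#' `cap` (the varied mismatch allowance) and `coverage_pct` and draws the
#' rising coverage curve.
#'
#' @param sweep A data frame with columns `cap` and `coverage_pct`.
#' @return A ggplot object.
#' @export
plot_coverage_sweep <- function(sweep) {
  ggplot2::ggplot(tibble::as_tibble(sweep),
                  ggplot2::aes(x = .data$cap, y = .data$coverage_pct)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "mismatch allowance", y = "genomic coverage (%)") +
    ggplot2::theme_bw()
}
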