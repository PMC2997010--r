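#' Detection parameters
#'
#' Bundles the knobs of the block validity predicate. The mismatch caps
#' mirror the classic `-i`/`-ip`/`-o`/`-op` flags: per block side, the
#' number of in-map mismatches must satisfy both the absolute cap
#' (`in_map_max`) and the percentage cap (`in_map_pct`, as a percentage of
#' that interval's total gene count), and likewise for out-map mismatches.
#' The defaults describe perfect blocks: at least two matched genes, no
#' mismatches, mode `"rs"`.
#'
#' Modes couple gene order and strandedness inside a block:
#' \describe{
#'   \item{`"rs"`}{only colinear order with consistent strands, or inverted
#'     order with reversed strands (the signature of an inversion).}
#'   \item{`"r-s"`}{all four order-by-strand combinations, but strand
#'     relation uniform within the block.}
#'   \item{`"free"`}{no order or strand constraint.}
#' }
#'
#' @param min_size Minimum matched genes per side (default 2).
#' @param max_size Maximum matched genes per side (default unlimited).
#' @param in_map_max,out_map_max Absolute caps on in-map / out-map
#'   mismatches per side (default 0; `Inf` for unlimited).
#' @param in_map_pct,out_map_pct Percentage caps in `[0, 100]` (default 0;
#'   100 disables).
#' @param mode One of `"rs"`, `"r-s"`, `"free"`.
#' @return A list of class `synt_params`.
#' @export
detection_params <- function(min_size = 2, max_size = Inf,
                             in_map_max = 0, in_map_pct = 0,
                             out_map_max = 0, out_map_pct = 0,
                             mode = c("rs", "r-s", "free")) {
  mode <- match.arg(mode)
  if (min_size < 1) stop_data("min_size must be >= 1")
  if (max_size < min_size) stop_data("max_size must be >= min_size")
  if (in_map_max < 0 || out_map_max < 0) stop_data("mismatch count caps must be >= 0")
  if (in_map_pct < 0 || in_map_pct > 100 || out_map_pct < 0 || out_map_pct > 100)
    stop_data("percentage caps must lie in [0, 100]")
  structure(list(min_size = min_size, max_size = max_size,
                 in_map_max = in_map_max, in_map_pct = in_map_pct,
                 out_map_max = out_map_max, out_map_pct = out_map_pct,
                 mode = mode),
            class = "synt_params")
}

#' @export
print.synt_params <- function(x, ...) {
  cat(sprintf(paste0("Detection parameters: size %s..%s, in-map <= %s & %s%%, ",
                     "out-map <= %s & %s%%, mode %s\n"),
              x$min_size, x$max_size, x$in_map_max, x$in_map_pct,
              x$out_map_max, x$out_map_pct, x$mode))
  invisible(x)
}

# Admitted (direction, strand-relation) combinations per mode, in the
# deterministic preference order used to label orientation/strand pattern.
# direction: "inc" (colinear), "dec" (inverted), "any" (unordered).
# strand: "same" (consistent), "diff" (reversed), "any" (mixed).
mode_combos <- function(mode) {
  switch(mode,
    "rs" = list(c("inc", "same"), c("dec", "diff")),
    "r-s" = list(c("inc", "same"), c("dec", "diff"), c("inc", "diff"), c("dec", "same")),
    "free" = list(c("inc", "same"), c("dec", "diff"), c("inc", "diff"), c("dec", "same"),
                  c("inc", "any"), c("dec", "any"),
                  c("any", "same"), c("any", "diff"), c("any", "any")))
}
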