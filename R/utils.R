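# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Total length of the union of a set of 1-based inclusive intervals.
union_width <- function(start, end) {
  if (length(start) == 0L) return(0)
  r <- IRanges::reduce(IRanges::IRanges(start = start, end = end))
  sum(as.numeric(IRanges::width(r)))
}

stop_data <- function(msg, ...) abort(sprintf(msg, ...), class = "syntenyr_data_error")

`%theni%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a
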