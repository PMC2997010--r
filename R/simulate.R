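#' Ancestor genome specification
#'
#' Parameters of the synthetic ancestral genome. Defaults loosely imitate
#' a C. elegans-scale gene layout (about one gene per 5 kb, mean gene
#' around 3 kb) so that kb-denominated statistics land in a realistic
#' regime; every value is configurable.
#'
#' @param n_chrom Number of chromosomes.
#' @param genes_per_chrom Genes per chromosome (scalar or vector of length
#'   `n_chrom`).
#' @param mean_gene_bp Mean gene length (gamma distributed, shape 2).
#' @param mean_intergenic_bp Mean intergenic gap (gamma, shape 1.5).
#' @param strand_prob Probability a gene lies on the `+` strand.
#' @param seed RNG seed; generation is deterministic given the spec.
#' @param genome_id Identifier of the emitted genome.
#' @return A list of class `synt_ancestor_spec`.
#' @export
ancestor_spec <- function(n_chrom = 2, genes_per_chrom = 12,
                          mean_gene_bp = 3000, mean_intergenic_bp = 2000,
                          strand_prob = 0.5, seed = 1, genome_id = "ANC") {
  if (n_chrom < 1 || any(genes_per_chrom < 1)) stop_data("counts must be positive")
  genes_per_chrom <- rep_len(genes_per_chrom, n_chrom)
  structure(list(n_chrom = n_chrom, genes_per_chrom = genes_per_chrom,
                 mean_gene_bp = mean_gene_bp,
                 mean_intergenic_bp = mean_intergenic_bp,
                 strand_prob = strand_prob, seed = seed, genome_id = genome_id),
            class = "synt_ancestor_spec")
}

#' Generate the ancestral genome
#'
#' Draws gene and intergenic lengths from the spec's distributions and lays
#' genes out left to right per chromosome; deterministic under the spec's
#' seed, with non-overlapping sorted coordinates.
#'
#' @param spec An [ancestor_spec()].
#' @return A genome tibble.
#' @export
generate_ancestor <- function(spec) {
  stopifnot(inherits(spec, "synt_ancestor_spec"))
  with_seed(spec$seed, {
    rows <- purrr::map_dfr(seq_len(spec$n_chrom), function(ci) {
      n <- spec$genes_per_chrom[ci]
      chrom <- sprintf("chr%02d", ci)
      glen <- pmax(200, round(rgamma(n, shape = 2, scale = spec$mean_gene_bp / 2)))
      gap <- pmax(50, round(rgamma(n, shape = 1.5, scale = spec$mean_intergenic_bp / 1.5)))
      start <- cumsum(gap) + cumsum(c(0, glen[-n]))
      tibble::tibble(gene_id = sprintf("%s_%s_g%03d", spec$genome_id, chrom, seq_len(n)),
                     chrom = chrom, start = start, end = start + glen - 1,
                     strand = ifelse(runif(n) < spec$strand_prob, "+", "-"))
    })
    as_genome(rows, spec$genome_id)
  })
}

#' Rearrangement operations
#'
#' Constructors for the operations of a rearrangement script. Positions are
#' gene ordinals on the derived genome *at the time the operation is
#' applied* (operations are applied sequentially). `at` means "insert after
#' ordinal `at`" (0 = chromosome start).
#'
#' @param chrom Chromosome name.
#' @param start First gene ordinal of the affected interval.
#' @param n Number of genes affected.
#' @param to_chrom,at Destination of a moved/copied segment; for a
#'   transposition within one chromosome, `at` refers to ordinals after the
#'   segment has been excised.
#' @param copies Number of extra copies for tandem duplication.
#' @param chrom2,after1,after2 Reciprocal translocation: tails beginning
#'   after `after1` on `chrom` and after `after2` on `chrom2` are swapped.
#' @return A list describing the operation.
#' @name rearrangement_ops
NULL

#' @rdname rearrangement_ops
#' @export
op_inversion <- function(chrom, start, n) {
  list(op = "inversion", chrom = chrom, start = start, n = n)
}
#' @rdname rearrangement_ops
#' @export
op_transposition <- function(chrom, start, n, to_chrom, at) {
  list(op = "transposition", chrom = chrom, start = start, n = n,
       to_chrom = to_chrom, at = at)
}
#' @rdname rearrangement_ops
#' @export
op_deletion <- function(chrom, start, n) {
  list(op = "deletion", chrom = chrom, start = start, n = n)
}
#' @rdname rearrangement_ops
#' @export
op_insertion <- function(chrom, at, n) {
  list(op = "insertion", chrom = chrom, at = at, n = n)
}
#' @rdname rearrangement_ops
#' @export
op_tandem_duplication <- function(chrom, start, n = 1, copies = 1) {
  list(op = "tandem_duplication", chrom = chrom, start = start, n = n, copies = copies)
}
#' @rdname rearrangement_ops
#' @export
op_segmental_duplication <- function(chrom, start, n, to_chrom, at) {
  list(op = "segmental_duplication", chrom = chrom, start = start, n = n,
       to_chrom = to_chrom, at = at)
}
#' @rdname rearrangement_ops
#' @export
op_translocation <- function(chrom, after1, chrom2, after2) {
  list(op = "translocation", chrom = chrom, after1 = after1,
       chrom2 = chrom2, after2 = after2)
}

#' Apply a rearrangement script
#'
#' Derives a second genome from the ancestor by applying the script's
#' operations in order, tracking for every derived gene its ancestral
#' source. Emits the derived genome (fresh ids, regenerated intergenic
#' layout), the correspondence between surviving genes (duplications create
#' one-to-many relations; insertions and deletions create out-map genes),
#' and a truth ledger: the maximal blocks a perfect detector (mode `"rs"`,
#' zero mismatches, minimum size 2) must find, with orientation and nested
#' flags, plus the expected out-map sets and planted tandem asymmetries.
#'
#' @param ancestor Ancestor genome tibble.
#' @param script List of operations from the `op_*` constructors.
#' @param genome_id Identifier for the derived genome.
#' @param seed Seed for the derived genome's layout and novel genes.
#' @return A list with `genome` (derived), `corr`, and `truth` (list with
#'   `blocks`, `out_map_a`, `out_map_b`, `tandem`).
#' @export
apply_script <- function(ancestor, script, genome_id = "DER", seed = 99) {
  ancestor <- as_genome(ancestor, genome_id(ancestor))
  anc_idx <- genome_index(ancestor)
  # working state: per chromosome, a data frame of gene records
  state <- lapply(anc_idx$chroms, function(cc) {
    b <- anc_idx$by_chrom[[cc]]
    data.frame(src = b$gene_id, len = b$end - b$start + 1, strand = b$strand,
               rel = "same", origin = "ancestral", op_id = NA_integer_,
               stringsAsFactors = FALSE)
  })
  names(state) <- anc_idx$chroms
  flip <- function(s) ifelse(s == "+", "-", "+")
  check <- function(cond, k, msg) if (!cond) stop_data("operation %d: %s", k, msg)

  for (k in seq_along(script)) {
    o <- script[[k]]
    if (o$op %in% c("inversion", "deletion", "tandem_duplication",
                    "transposition", "segmental_duplication")) {
      st <- state[[o$chrom]]
      check(!is.null(st), k, sprintf("unknown chromosome '%s'", o$chrom))
      check(o$start >= 1 && o$start + o$n - 1 <= nrow(st), k, "interval out of range")
      idx <- o$start:(o$start + o$n - 1)
    }
    state <- switch(o$op,
      inversion = {
        st <- state[[o$chrom]]
        seg <- st[rev(idx), , drop = FALSE]
        seg$strand <- flip(seg$strand)
        seg$rel <- ifelse(seg$rel == "same", "diff", "same")
        st[idx, ] <- seg
        state[[o$chrom]] <- st
        state
      },
      deletion = {
        state[[o$chrom]] <- state[[o$chrom]][-idx, , drop = FALSE]
        state
      },
      insertion = {
        st <- state[[o$chrom]]
        check(o$at >= 0 && o$at <= nrow(st), k, "insertion point out of range")
        novel <- data.frame(src = NA_character_,
                            len = rep(1500, o$n), strand = "+", rel = "same",
                            origin = "insertion", op_id = k,
                            stringsAsFactors = FALSE)
        state[[o$chrom]] <- rbind(st[seq_len(o$at), , drop = FALSE], novel,
                                  st[seq_len(nrow(st)) > o$at, , drop = FALSE])
        state
      },
      tandem_duplication = {
        st <- state[[o$chrom]]
        seg <- st[idx, , drop = FALSE]
        seg$origin <- "tandem"; seg$op_id <- k
        copies <- do.call(rbind, rep(list(seg), o$copies))
        state[[o$chrom]] <- rbind(st[seq_len(max(idx)), , drop = FALSE], copies,
                                  st[seq_len(nrow(st)) > max(idx), , drop = FALSE])
        state
      },
      transposition = {
        st <- state[[o$chrom]]
        seg <- st[idx, , drop = FALSE]
        st <- st[-idx, , drop = FALSE]
        state[[o$chrom]] <- st
        dst <- state[[o$to_chrom]]
        check(!is.null(dst), k, sprintf("unknown chromosome '%s'", o$to_chrom))
        check(o$at >= 0 && o$at <= nrow(dst), k, "destination out of range")
        state[[o$to_chrom]] <- rbind(dst[seq_len(o$at), , drop = FALSE], seg,
                                     dst[seq_len(nrow(dst)) > o$at, , drop = FALSE])
        state
      },
      segmental_duplication = {
        seg <- state[[o$chrom]][idx, , drop = FALSE]
        seg$origin <- "segdup"; seg$op_id <- k
        dst <- state[[o$to_chrom]]
        check(!is.null(dst), k, sprintf("unknown chromosome '%s'", o$to_chrom))
        check(o$at >= 0 && o$at <= nrow(dst), k, "destination out of range")
        state[[o$to_chrom]] <- rbind(dst[seq_len(o$at), , drop = FALSE], seg,
                                     dst[seq_len(nrow(dst)) > o$at, , drop = FALSE])
        state
      },
      translocation = {
        s1 <- state[[o$chrom]]; s2 <- state[[o$chrom2]]
        check(!is.null(s1) && !is.null(s2), k, "unknown chromosome")
        check(o$after1 >= 0 && o$after1 <= nrow(s1) &&
                o$after2 >= 0 && o$after2 <= nrow(s2), k, "breakpoint out of range")
        head1 <- s1[seq_len(o$after1), , drop = FALSE]
        tail1 <- s1[seq_len(nrow(s1)) > o$after1, , drop = FALSE]
        head2 <- s2[seq_len(o$after2), , drop = FALSE]
        tail2 <- s2[seq_len(nrow(s2)) > o$after2, , drop = FALSE]
        state[[o$chrom]] <- rbind(head1, tail2)
        state[[o$chrom2]] <- rbind(head2, tail1)
        state
      },
      stop_data("operation %d: unknown op '%s'", k, o$op))
  }

  # lay out coordinates and mint derived ids
  derived <- with_seed(seed, purrr::map_dfr(names(state), function(cc) {
    st <- state[[cc]]
    n <- nrow(st)
    if (!n) return(NULL)
    gap <- pmax(50, round(rgamma(n, shape = 1.5, scale = 2000 / 1.5)))
    start <- cumsum(gap) + cumsum(c(0, st$len[-n]))
    tibble::tibble(gene_id = sprintf("%s_%s_g%03d", genome_id, cc, seq_len(n)),
                   chrom = cc, start = start, end = start + st$len - 1,
                   strand = st$strand, src = st$src, rel = st$rel,
                   origin = st$origin, op_id = st$op_id)
  }))
  genome_b <- as_genome(derived[, c("gene_id", "chrom", "start", "end", "strand")],
                        genome_id)
  # derived tibble rows are already in (chrom, position) order by construction
  corr <- as_correspondence(derived[!is.na(derived$src), c("src", "gene_id")])
  truth <- truth_ledger(ancestor, derived, corr)
  list(genome = genome_b, corr = corr, truth = truth)
}

# Scan the derived genome's ancestral sources into the maximal blocks a
# perfect detector (mode rs, zero mismatches, min size 2) must report.
truth_ledger <- function(ancestor, derived, corr) {
  anc_idx <- genome_index(ancestor)
  src_chrom <- unname(anc_idx$chrom_of[derived$src])
  src_ord <- unname(anc_idx$ord_of[derived$src])
  runs <- list()
  for (cc in unique(derived$chrom)) {
    rows <- which(derived$chrom == cc)
    i <- 1
    while (i <= length(rows)) {
      r <- rows[i]
      if (is.na(derived$src[r])) { i <- i + 1; next }
      members <- r
      dir <- 0L
      j <- i + 1
      while (j <= length(rows)) {
        r2 <- rows[j]; r1 <- rows[j - 1]
        if (is.na(derived$src[r2]) || is.na(derived$src[r1])) break
        if (!identical(src_chrom[r2], src_chrom[r1])) break
        d <- src_ord[r2] - src_ord[r1]
        ok <- (d == 1L && derived$rel[r2] == "same" && derived$rel[r1] == "same" &&
                 dir %in% c(0L, 1L)) ||
              (d == -1L && derived$rel[r2] == "diff" && derived$rel[r1] == "diff" &&
                 dir %in% c(0L, -1L)) ||
              (d == 0L && derived$rel[r2] == derived$rel[r1])
        if (!ok) break
        if (d == 1L) dir <- 1L else if (d == -1L) dir <- -1L
        members <- c(members, r2)
        j <- j + 1
      }
      srcs <- unique(src_ord[members])
      if (length(members) >= 2 && length(srcs) >= 2) {
        runs[[length(runs) + 1L]] <- list(
          chrom_a = src_chrom[members[1]],
          a_first = min(src_ord[members]), a_last = max(src_ord[members]),
          chrom_b = cc, b_first = as.integer(i), b_last = as.integer(j - 1),
          orientation = if (dir >= 0L) "colinear" else "inverted",
          strand_pattern = if (dir >= 0L) "consistent" else "reversed",
          n_b = length(members), n_a = length(srcs),
          segdup = all(derived$origin[members] == "segdup"))
      }
      i <- j
    }
  }
  blocks <- if (length(runs)) purrr::map_dfr(runs, tibble::as_tibble) else
    tibble::tibble(chrom_a = character(), a_first = integer(), a_last = integer(),
                   chrom_b = character(), b_first = integer(), b_last = integer(),
                   orientation = character(), strand_pattern = character(),
                   n_b = integer(), n_a = integer(), segdup = logical())
  # nested: contained on one side, disjoint on the other
  n <- nrow(blocks)
  nested <- logical(n)
  if (n > 1) {
    for (u in seq_len(n)) for (v in seq_len(n)) {
      if (u == v) next
      in_a <- blocks$chrom_a[u] == blocks$chrom_a[v] &&
        blocks$a_first[v] <= blocks$a_first[u] && blocks$a_last[v] >= blocks$a_last[u] &&
        (blocks$a_last[v] - blocks$a_first[v]) > (blocks$a_last[u] - blocks$a_first[u]) &&
        (blocks$chrom_b[u] != blocks$chrom_b[v] ||
           blocks$b_last[v] < blocks$b_first[u] || blocks$b_first[v] > blocks$b_last[u])
      in_b <- blocks$chrom_b[u] == blocks$chrom_b[v] &&
        blocks$b_first[v] <= blocks$b_first[u] && blocks$b_last[v] >= blocks$b_last[u] &&
        (blocks$b_last[v] - blocks$b_first[v]) > (blocks$b_last[u] - blocks$b_first[u]) &&
        (blocks$chrom_a[u] != blocks$chrom_a[v] ||
           blocks$a_last[v] < blocks$a_first[u] || blocks$a_first[v] > blocks$a_last[u])
      if (in_a || in_b) { nested[u] <- TRUE; break }
    }
  }
  blocks$nested <- nested
  blocks <- dplyr::arrange(blocks, .data$chrom_a, .data$a_first, .data$a_last,
                           .data$chrom_b, .data$b_first, .data$b_last)
  # planted tandem asymmetries: ancestral genes with several adjacent copies
  tandem <- dplyr::filter(
    dplyr::summarise(dplyr::group_by(derived[!is.na(derived$src), ], .data$src),
                     n_copies = dplyr::n(), .groups = "drop"),
    .data$n_copies > 1)
  list(blocks = blocks,
       out_map_a = setdiff(ancestor$gene_id, corr$gene_a),
       out_map_b = setdiff(derived$gene_id, corr$gene_b),
       tandem = tandem)
}

#' Random rearrangement script with guaranteed spacing
#'
#' Draws `n_ops` operations whose source and destination neighbourhoods
#' stay at least `margin` genes away from every previous operation's
#' footprint, so that planted events do not interact and the truth ledger
#' is exact. Operation coordinates refer to the genome state at application
#' time; a parallel marker model tracks how each operation shifts ordinals.
#' Returns fewer operations when the genome runs out of room.
#'
#' @param genome The genome the script will be applied to (the ancestor).
#' @param n_ops Number of operations requested.
#' @param seed RNG seed.
#' @param types Operation types to draw from.
#' @param margin Minimum gap (genes) between operation footprints.
#' @param max_len Maximal segment length (genes) per operation.
#' @return A list of operations for [apply_script()].
#' @export
random_script <- function(genome, n_ops = 3, seed = 1,
                          types = c("inversion", "transposition", "deletion",
                                    "insertion", "tandem_duplication",
                                    "segmental_duplication"),
                          margin = 3, max_len = 4) {
  idx <- genome_index(genome)
  with_seed(seed, {
    # TRUE = gene lies in (or within margin of) a previous op's footprint
    marks <- lapply(idx$chroms, function(cc) logical(idx$by_chrom[[cc]]$n))
    names(marks) <- idx$chroms
    free_window <- function(cc, lo, hi) {
      lo <- max(1, lo); hi <- min(length(marks[[cc]]), hi)
      lo > hi || !any(marks[[cc]][lo:hi])
    }
    mark <- function(cc, lo, hi) {
      lo <- max(1, lo - margin); hi <- min(length(marks[[cc]]), hi + margin)
      if (lo <= hi) marks[[cc]][lo:hi] <<- TRUE
    }
    ops <- list()
    tries <- 0
    while (length(ops) < n_ops && tries < 400) {
      tries <- tries + 1
      ty <- sample(types, 1)
      cc <- sample(names(marks), 1)
      ncc <- length(marks[[cc]])
      len <- if (ty == "tandem_duplication") 1L else sample(seq_len(max_len), 1)
      if (ncc < len + 2 * margin + 2) next
      start <- sample.int(ncc - len + 1, 1)
      if (!free_window(cc, start - margin, start + len - 1 + margin)) next
      if (ty %in% c("transposition", "segmental_duplication")) {
        dc <- sample(names(marks), 1)
        at <- sample.int(length(marks[[dc]]) + 1, 1) - 1L
        # destination junction must be clear, and clear of the source window
        if (!free_window(dc, at - margin + 1, at + margin)) next
        if (dc == cc && at >= start - margin - 1 && at <= start + len - 1 + margin) next
        if (ty == "transposition") {
          # `at` is interpreted after excision of the segment
          if (dc == cc && at > start + len - 1) at <- at - len
          ops[[length(ops) + 1L]] <- op_transposition(cc, start, len, dc, at)
          marks[[cc]] <- marks[[cc]][-(start:(start + len - 1))]
          mark(cc, start - 1, start)  # excision junction
          marks[[dc]] <- append(marks[[dc]], rep(TRUE, len), after = at)
          mark(dc, at, at + len + 1)
        } else {
          ops[[length(ops) + 1L]] <- op_segmental_duplication(cc, start, len, dc, at)
          mark(cc, start, start + len - 1)  # protect the source copy
          marks[[dc]] <- append(marks[[dc]], rep(TRUE, len), after = at)
          mark(dc, at, at + len + 1)
        }
        next
      }
      op <- switch(ty,
        inversion = op_inversion(cc, start, len),
        deletion = op_deletion(cc, start, len),
        insertion = op_insertion(cc, start - 1, len),
        tandem_duplication = op_tandem_duplication(cc, start, 1, sample(1:3, 1)))
      ops[[length(ops) + 1L]] <- op
      if (ty == "inversion") {
        mark(cc, start, start + len - 1)
      } else if (ty == "deletion") {
        marks[[cc]] <- marks[[cc]][-(start:(start + len - 1))]
        mark(cc, start - 1, start)
      } else if (ty == "insertion") {
        marks[[cc]] <- append(marks[[cc]], rep(TRUE, len), after = start - 1L)
        mark(cc, start - 1, start + len)
      } else {  # tandem duplication of one gene
        copies <- op$copies
        marks[[cc]] <- append(marks[[cc]], rep(TRUE, copies), after = start)
        mark(cc, start, start + copies + 1)
      }
    }
    ops
  })
}
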