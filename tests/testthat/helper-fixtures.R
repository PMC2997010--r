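# Shared fixtures, all built in code.

# Simple single-chromosome genome: n genes of 3 kb spaced 2 kb apart.
toy_genome <- function(prefix, strands, chrom = "chr01", genome_id = prefix) {
  n <- length(strands)
  start <- seq(1000, by = 5000, length.out = n)
  as_genome(tibble::tibble(gene_id = sprintf("%s_g%02d", prefix, seq_len(n)),
                           chrom = chrom, start = start, end = start + 2999,
                           strand = strands), genome_id)
}

# The nine-gene worked instance: one-to-one orthologs in identical order,
# all strand-consistent except gene 6, whose ortholog is inverted.
toy_strandflip <- function() {
  sa <- rep("+", 9)
  sb <- sa
  sb[6] <- "-"
  ga <- toy_genome("GA", sa, chrom = "chrIII")
  gb <- toy_genome("GB", sb, chrom = "chrIII")
  corr <- tibble::tibble(gene_a = ga$gene_id, gene_b = gb$gene_id)
  list(ga = ga, gb = gb, corr = corr)
}

# Identity instance: two copies of the same gene layout, one-to-one.
toy_identity <- function(n = 5, chrom = "chr01") {
  ga <- toy_genome("IA", rep("+", n), chrom = chrom)
  gb <- toy_genome("IB", rep("+", n), chrom = chrom)
  list(ga = ga, gb = gb,
       corr = tibble::tibble(gene_a = ga$gene_id, gene_b = gb$gene_id))
}

# Random two-genome instance: simulated rearrangements plus correspondence
# noise (dropped pairs create out-map genes, spurious pairs create one-to-
# many relations and in-map mismatch opportunities).
random_instance <- function(seed, max_genes = 16, n_chrom = NULL) {
  with_seed2(seed, {
    n_chrom <- if (is.null(n_chrom)) sample(1:2, 1) else n_chrom
    genes <- sample(3:max_genes, n_chrom, replace = TRUE)
    spec <- ancestor_spec(n_chrom = n_chrom, genes_per_chrom = genes,
                          seed = seed * 7 + 1, genome_id = "RA")
    anc <- generate_ancestor(spec)
    script <- random_script(anc, n_ops = sample(0:4, 1), seed = seed * 7 + 2,
                            margin = 1)
    sim <- apply_script(anc, script, genome_id = "RB", seed = seed * 7 + 3)
    corr <- sim$corr
    if (nrow(corr) > 2) {
      drop <- runif(nrow(corr)) < 0.1
      corr <- corr[!drop, , drop = FALSE]
    }
    n_spur <- sample(0:3, 1)
    if (n_spur > 0 && nrow(anc) && nrow(sim$genome)) {
      spur <- tibble::tibble(gene_a = sample(anc$gene_id, n_spur, replace = TRUE),
                             gene_b = sample(sim$genome$gene_id, n_spur, replace = TRUE))
      corr <- dplyr::bind_rows(corr, spur)
    }
    list(ga = anc, gb = sim$genome, corr = as_correspondence(corr))
  })
}

random_params <- function(seed) {
  with_seed2(seed, detection_params(
    min_size = 2,
    in_map_max = sample(0:3, 1), in_map_pct = sample(c(0, 5, 10, 20, 50), 1),
    out_map_max = sample(0:3, 1), out_map_pct = sample(c(0, 5, 10, 20, 50), 1),
    mode = sample(c("rs", "r-s", "free"), 1)))
}

# RNG-preserving seeding for helpers (mirrors the package-internal helper).
with_seed2 <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Strip class/attribute decoration so block sets compare structurally.
plain_blocks <- function(b) {
  d <- tibble::as_tibble(b)
  attr(d, "genome_a") <- attr(d, "genome_b") <- NULL
  d
}

expect_same_blocks <- function(x, y) {
  expect_equal(plain_blocks(x), plain_blocks(y))
}
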