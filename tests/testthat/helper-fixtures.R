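# Shared fixtures, built in code. The tiny world is memoized so several
# test files can reuse one generation.

.fixture_cache <- new.env(parent = emptyenv())

tiny_world <- function() {
  if (is.null(.fixture_cache$world)) {
    cfg <- synthetic_world_config(
      n_genes = 40, n_cell_lines = 80, n_patients = 120,
      n_sl_pairs = 20, n_nonsl_pairs = 20,
      d_seq = 32, d_ppi = 16)
    .fixture_cache$world <- generate_world(cfg, seed = 42)
  }
  .fixture_cache$world
}

tiny_blocks <- function() {
  if (is.null(.fixture_cache$blocks)) {
    .fixture_cache$blocks <- featurize_world(tiny_world())
  }
  .fixture_cache$blocks
}

# small hand-made blocks: one informative source (feature tracks the
# label), the rest noise; fast enough for repeated model fits
toy_blocks <- function(n = 60, informative = "s1", noise_sd = 0.3,
                       seed = 1) {
  set.seed(seed)
  genes <- sprintf("T%03d", seq_len(2 * n))
  pairs <- gene_pairs(genes[seq(1, 2 * n, 2)], genes[seq(2, 2 * n, 2)])
  y <- rep(c(0L, 1L), length.out = n)
  mk <- function(tag, signal) {
    m <- matrix(rnorm(n * 3, sd = 1), n, 3)
    if (signal) m[, 1] <- y + rnorm(n, sd = noise_sd)
    colnames(m) <- paste0(tag, "_f", 1:3)
    feature_block(pairs, m, tag)
  }
  blocks <- list(s1 = mk("s1", informative == "s1"),
                 s2 = mk("s2", informative == "s2"),
                 s3 = mk("s3", informative == "s3"))
  labels <- sl_labels(pairs$gene_a, pairs$gene_b, y, source = "toy")
  list(blocks = blocks, labels = labels, y = y, pairs = pairs)
}

# a small omics bundle with fully controlled alteration structure
manual_bundle <- function(dep = NULL, mut = NULL, expr_z = NULL,
                          expr_level = NULL, cna = NULL, clinical = NULL,
                          expr_normal = NULL, expr_healthy = NULL) {
  omics_bundle(dependency = dep, mutations = mut, expr_z = expr_z,
               expr_level = expr_level, cna = cna, clinical = clinical,
               expr_normal = expr_normal, expr_healthy = expr_healthy)
}

named_matrix <- function(v, samples, genes) {
  matrix(v, length(samples), length(genes),
         dimnames = list(samples, genes))
}
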