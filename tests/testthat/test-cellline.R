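test_that("alteration thresholds are strict, matching the 95% z bound", {
  z <- named_matrix(c(2.00, 1.96, -1.97, 0), sprintf("s%d", 1:2),
                    c("GA", "GB"))
  b <- manual_bundle(expr_z = z)
  alt <- call_alterations(b, "expression")
  expect_equal(unname(alt[, "GA"]), c(1, 0))   # 2.00 in, 1.96 out
  expect_equal(unname(alt[, "GB"]), c(1, 0))   # -1.97 in, 0 out
})

test_that("only deep copy-number events count as alterations", {
  cna <- named_matrix(c(2, 1, -2, 0), sprintf("s%d", 1:2), c("GA", "GB"))
  alt <- call_alterations(manual_bundle(cna = cna), "cna")
  expect_equal(unname(alt[, "GA"]), c(1, 0))
  expect_equal(unname(alt[, "GB"]), c(1, 0))
})

test_that("mutation channel counts only non-silent variants; any = OR", {
  mut <- data.frame(sample = c("s1", "s2"), gene = c("GA", "GA"),
                    variant_class = c("missense", "silent"))
  z <- named_matrix(rep(0, 4), c("s1", "s2"), c("GA", "GB"))
  z["s2", "GB"] <- 3
  b <- manual_bundle(mut = mut, expr_z = z)
  m_alt <- call_alterations(b, "mutation")
  expect_equal(unname(m_alt[, "GA"]), c(1, 0))
  any_alt <- call_alterations(b, "any")
  expect_equal(unname(any_alt[, "GA"]), c(1, 0))
  expect_equal(unname(any_alt[, "GB"]), c(0, 1))
  expect_error(call_alterations(b, "frobnicate"))
  zero <- call_alterations(manual_bundle(expr_z = 0 * z), "any")
  expect_true(all(zero == 0))
})

test_that("CRISPR pair features match the worked conditional means", {
  samples <- sprintf("s%d", 1:4)
  dep <- named_matrix(0, samples, c("GA", "GB"))
  dep[, "GA"] <- c(-1.0, -0.2, -0.8, 0.0)
  alt <- named_matrix(0, samples, c("GA", "GB"))
  alt[c(1, 3), "GB"] <- 1
  v <- crispr_pair_features(gene_pairs("GA", "GB"), dep, alt)
  expect_equal(unname(v[1]), -0.1)   # GA | GB unaltered
  expect_equal(unname(v[2]), -0.9)   # GA | GB altered
  # partner never altered: the altered-conditional is missing, not zero
  alt0 <- named_matrix(0, samples, c("GA", "GB"))
  v0 <- crispr_pair_features(gene_pairs("GA", "GB"), dep, alt0)
  expect_true(is.na(v0[2]) && is.na(v0[4]))
  expect_false(anyNA(v0[c(1, 3)]))
})

test_that("conditional means agree with a brute-force oracle on random data", {
  oracle <- function(dep, alt, a, b) {
    sel <- function(g, mask) {
      acc <- c()
      for (s in rownames(dep)) if (mask(s)) acc <- c(acc, dep[s, g])
      if (length(acc)) mean(acc) else NA_real_
    }
    c(sel(a, function(s) alt[s, b] == 0), sel(a, function(s) alt[s, b] == 1),
      sel(b, function(s) alt[s, a] == 0), sel(b, function(s) alt[s, a] == 1))
  }
  set.seed(99)
  for (i in 1:100) {
    samples <- sprintf("s%d", 1:10)
    genes <- sprintf("g%d", 1:6)
    dep <- named_matrix(rnorm(60), samples, genes)
    alt <- named_matrix(rbinom(60, 1, 0.3), samples, genes)
    pick <- sample(genes, 2)
    pr <- gene_pairs(pick[1], pick[2])
    got <- unname(crispr_pair_features(pr, dep, alt))
    expect_equal(got, oracle(dep, alt, pr$gene_a, pr$gene_b))
  }
})

test_that("cell-line blocks have 4 columns and separate channels", {
  w <- tiny_world()
  pairs <- gene_pairs(w$labels$gene_a, w$labels$gene_b)[1:20, ]
  class(pairs) <- c("gene_pairs", "data.frame")
  fb <- cellline_feature_blocks(pairs, w$cellline)
  expect_equal(dim(fb$crispr_mut), c(20L, 4L))
  expect_equal(dim(fb$crispr_expr), c(20L, 4L))
  # perturbing expression z-scores must not touch the mutation block
  w2 <- w$cellline
  w2$expr_z <- w2$expr_z + 10
  fb2 <- cellline_feature_blocks(pairs, w2)
  expect_identical(fb2$crispr_mut$matrix, fb$crispr_mut$matrix)
  expect_false(identical(fb2$crispr_expr$matrix, fb$crispr_expr$matrix))
})

test_that("a pair of unmeasured genes yields a fully missing row", {
  w <- tiny_world()
  pairs <- gene_pairs(c(w$labels$gene_a[1], "ZZZ1"),
                      c(w$labels$gene_b[1], "ZZZ2"))
  fb <- cellline_feature_blocks(pairs, w$cellline)
  expect_true(all(is.na(fb$crispr_mut$matrix[2, ])))
})

test_that("the planted dependency shift is recovered from the features", {
  set.seed(123)
  n <- 200
  delta <- 0.8
  samples <- sprintf("s%d", seq_len(n))
  alt <- named_matrix(rbinom(2 * n, 1, 0.3), samples, c("GA", "GB"))
  dep <- named_matrix(rnorm(2 * n, sd = 0.2), samples, c("GA", "GB"))
  dep[alt[, "GB"] == 1, "GA"] <- dep[alt[, "GB"] == 1, "GA"] - delta
  v <- crispr_pair_features(gene_pairs("GA", "GB"), dep, alt)
  n_alt <- sum(alt[, "GB"] == 1)
  se <- 0.2 * sqrt(1 / n_alt + 1 / (n - n_alt))
  expect_lt(abs((v[1] - v[2]) - delta), 3 * se)
})
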