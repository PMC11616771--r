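# builds a one-pair patient cohort with mutation-driven alterations and
# exponential survival with a planted hazard ratio for the co-altered group
survival_cohort <- function(n, hr, p_alt = 0.4, seed = 1) {
  set.seed(seed)
  samples <- sprintf("p%04d", seq_len(n))
  alt_a <- rbinom(n, 1, p_alt)
  alt_b <- rbinom(n, 1, p_alt)
  mk <- function(sel, gene) {
    if (!any(sel)) return(NULL)
    data.frame(sample = samples[sel], gene = gene,
               variant_class = "missense")
  }
  mut <- rbind(mk(alt_a == 1, "GA"), mk(alt_b == 1, "GB"))
  co <- alt_a == 1 & alt_b == 1
  t_event <- rexp(n, rate = (1 / 24) * ifelse(co, hr, 1))
  cens <- runif(n, 24, 72)
  clinical <- data.frame(sample = samples, time = pmin(t_event, cens),
                         event = as.integer(t_event <= cens),
                         age = round(rnorm(n, 60, 10)),
                         sex = sample(c("F", "M"), n, TRUE),
                         cancer = "BRCA")
  z <- named_matrix(0, samples, c("GA", "GB"))
  manual_bundle(mut = mut, expr_z = z, clinical = clinical)
}

test_that("co-mutation grouping requires an alteration in both genes", {
  samples <- c("s1", "s2", "s3")
  mut <- data.frame(sample = "s1", gene = "GA", variant_class = "missense")
  z <- named_matrix(0, samples, c("GA", "GB"))
  z["s1", "GB"] <- 2.5    # expression alteration suffices for the partner
  z["s2", "GA"] <- 2.5    # one gene only
  b <- manual_bundle(mut = mut, expr_z = z)
  grp <- comutation_grouping(gene_pairs("GA", "GB"), b)
  expect_identical(unname(grp), c(TRUE, FALSE, FALSE))
  # no alterations anywhere: nobody is co-altered
  b0 <- manual_bundle(expr_z = 0 * z)
  expect_false(any(comutation_grouping(gene_pairs("GA", "GB"), b0)))
})

test_that("a planted protective hazard ratio is detected", {
  b <- survival_cohort(500, hr = 0.3, seed = 21)
  p <- survival_feature(gene_pairs("GA", "GB"), b)
  expect_lt(p, 0.05)
})

test_that("an empty co-altered group yields a missing p-value", {
  b <- survival_cohort(100, hr = 1, p_alt = 0, seed = 3)
  expect_true(is.na(survival_feature(gene_pairs("GA", "GB"), b)))
})

test_that("average expression features match the worked example and oracle", {
  samples <- sprintf("s%d", 1:3)
  expr <- named_matrix(0, samples, c("GA", "GB"))
  expr[, "GA"] <- c(2, 4, 6)
  z <- named_matrix(0, samples, c("GA", "GB"))
  z["s3", "GB"] <- 2.5
  b <- manual_bundle(expr_level = expr, expr_z = z)
  v <- avg_expression_features(gene_pairs("GA", "GB"), b, log2p1 = FALSE)
  expect_equal(unname(v[2]), 6)   # GA | GB altered
  expect_equal(unname(v[1]), 3)   # GA | GB unaltered
  # no altered samples for the partner: feature missing
  b0 <- manual_bundle(expr_level = expr, expr_z = 0 * z)
  expect_true(is.na(avg_expression_features(gene_pairs("GA", "GB"),
                                            b0)[2]))

  set.seed(5)
  for (i in 1:100) {
    samples <- sprintf("s%d", 1:10)
    genes <- sprintf("g%d", 1:4)
    expr <- named_matrix(rexp(40), samples, genes)
    altm <- named_matrix(rbinom(40, 1, 0.3), samples, genes)
    pick <- sample(genes, 2)
    pr <- gene_pairs(pick[1], pick[2])
    a <- pr$gene_a; bg <- pr$gene_b
    le <- log2(expr + 1)
    oracle <- c(mean(le[altm[, bg] == 0, a]), mean(le[altm[, bg] == 1, a]),
                mean(le[altm[, a] == 0, bg]), mean(le[altm[, a] == 1, bg]))
    oracle[is.nan(oracle)] <- NA
    zb <- named_matrix(0, samples, genes)
    zb[altm == 1] <- 3
    bb <- manual_bundle(expr_level = expr, expr_z = zb)
    expect_equal(unname(avg_expression_features(pr, bb)), oracle)
  }
})

test_that("coexpression features recover exact and null correlations", {
  samples <- sprintf("s%d", 1:10)
  # 2^k - 1 levels make log2(x+1) exactly linear: r = 1 exactly
  expr <- named_matrix(0, samples, c("GA", "GB"))
  expr[, "GA"] <- 2^(1:10) - 1
  expr[, "GB"] <- 2^(3:12) - 1
  b <- manual_bundle(expr_level = expr)
  v <- coexpression_features(gene_pairs("GA", "GB"), b)
  expect_equal(unname(v["coexpr_tumour_r"]), 1)
  expect_true(is.na(v["coexpr_normal_r"]))  # no normal compartment
  # anti-correlation
  expr[, "GB"] <- 2^(10:1) - 1
  b <- manual_bundle(expr_level = expr)
  expect_equal(unname(coexpression_features(gene_pairs("GA", "GB"),
                                            b)["coexpr_tumour_r"]), -1)
  # constant vector: undefined, missing
  expr[, "GB"] <- 5
  b <- manual_bundle(expr_level = expr)
  expect_true(is.na(coexpression_features(gene_pairs("GA", "GB"),
                                          b)["coexpr_tumour_r"]))
})

test_that("independent expression shows near-zero correlation", {
  set.seed(8)
  hits <- replicate(100, {
    samples <- sprintf("s%d", 1:1000)
    expr <- named_matrix(exp(rnorm(2000)), samples, c("GA", "GB"))
    b <- manual_bundle(expr_level = expr)
    abs(coexpression_features(gene_pairs("GA", "GB"), b)["coexpr_tumour_r"])
  })
  expect_gte(mean(hits < 0.1), 0.95)
})

test_that("copy-number correlation is Spearman: rank-invariant, oracle-equal", {
  samples <- sprintf("s%d", 1:8)
  cna <- named_matrix(0, samples, c("GA", "GB"))
  cna[, "GA"] <- c(-2, -1, 0, 1, 2, 0, 1, -1)
  cna[, "GB"] <- cna[, "GA"]
  b <- manual_bundle(cna = cna)
  expect_equal(unname(cna_correlation_features(gene_pairs("GA", "GB"),
                                               b)["cna_rho"]), 1)
  # strictly monotone transform preserves rho = 1
  cna[, "GB"] <- pmin(2, pmax(-2, cna[, "GA"] + c(0, 0, 0, 1, 0, 0, 1, 0)))
  set.seed(17)
  for (i in 1:50) {
    x <- sample(-2:2, 12, TRUE); y <- sample(-2:2, 12, TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    cnab <- named_matrix(c(x, y), sprintf("t%d", 1:12), c("GA", "GB"))
    got <- cna_correlation_features(gene_pairs("GA", "GB"),
                                    manual_bundle(cna = cnab))
    expect_equal(unname(got["cna_rho"]),
                 cor(rank(x), rank(y)), tolerance = 1e-12)
  }
})

test_that("the tissue block has 13 stable columns with clean missingness", {
  w <- tiny_world()
  pairs <- gene_pairs(w$labels$gene_a, w$labels$gene_b)[1:20, ]
  class(pairs) <- c("gene_pairs", "data.frame")
  tb <- tissue_feature_block(pairs, w$tissue)
  expect_equal(dim(tb), c(20L, 13L))
  expect_equal(colnames(tb$matrix)[1], "survival_p")
  rs <- tb$matrix[, c("coexpr_tumour_r", "coexpr_normal_r",
                      "coexpr_healthy_r", "cna_rho")]
  expect_true(all(abs(rs[!is.na(rs)]) <= 1))
  ps <- tb$matrix[, c("survival_p", "coexpr_tumour_p", "cna_p")]
  expect_true(all(ps[!is.na(ps)] >= 0 & ps[!is.na(ps)] <= 1))
  # dropping the clinical table blanks only the survival column
  t2 <- w$tissue
  t2$clinical <- NULL
  tb2 <- tissue_feature_block(pairs, t2)
  expect_true(all(is.na(tb2$matrix[, "survival_p"])))
  expect_identical(tb2$matrix[, -1], tb$matrix[, -1])
  # deterministic for fixed inputs
  expect_identical(tissue_feature_block(pairs, w$tissue)$matrix, tb$matrix)
})

test_that("family survival with singleton families reduces to the pair case", {
  b <- survival_cohort(300, hr = 0.5, seed = 9)
  fam <- family_comutation_survival("GA", "GB", b)
  grp <- comutation_grouping(gene_pairs("GA", "GB"), b)
  expect_identical(unname(fam$groups == "both"), unname(grp))
  expect_equal(fam$p, survival_feature(gene_pairs("GA", "GB"), b))
  expect_true(all(c("both", "not_both", "one_family", "unaltered") %in%
                    fam$km$group))
})

test_that("family survival recovers a planted median survival difference", {
  set.seed(31)
  n <- 600
  samples <- sprintf("p%04d", seq_len(n))
  fa <- c("FA1", "FA2"); fb <- c("FB1", "FB2")
  altm <- named_matrix(rbinom(n * 4, 1, 0.5), samples, c(fa, fb))
  co <- (altm[, "FA1"] | altm[, "FA2"]) & (altm[, "FB1"] | altm[, "FB2"])
  # co-altered group lives twice as long (hazard halved)
  t_event <- rexp(n, rate = (1 / 20) * ifelse(co, 0.5, 1))
  clinical <- data.frame(sample = samples, time = pmin(t_event, 200),
                         event = as.integer(t_event <= 200),
                         age = 60, sex = "F", cancer = "BRCA")
  zb <- named_matrix(0, samples, c(fa, fb))
  zb[altm == 1] <- 3
  b <- manual_bundle(expr_z = zb, clinical = clinical)
  fam <- family_comutation_survival(fa, fb, b)
  ratio <- fam$median_survival[["both"]] / fam$median_survival[["not_both"]]
  expect_lt(abs(ratio - 2), 0.4)   # within 20% of the planted 2-fold
  # a family disjoint from measured genes: nobody is co-altered
  fam0 <- family_comutation_survival(fa, c("NOPE"), b)
  expect_true(all(fam0$groups != "both"))
  expect_true(is.na(fam0$p))
  expect_false(is.null(fam0$km))
})
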