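random_labels <- function(n_pos, n_neg, n_genes = NULL, seed = 1) {
  set.seed(seed)
  n <- n_pos + n_neg
  if (is.null(n_genes)) n_genes <- 2 * n
  genes <- sprintf("g%04d", seq_len(n_genes))
  idx <- utils::combn(n_genes, 2)
  pick <- sample(ncol(idx), n)
  sl_labels(genes[idx[1, pick]], genes[idx[2, pick]],
            rep(c(1L, 0L), c(n_pos, n_neg)), source = "sim")
}

# every labelled pair on a complete gene set, labels alternating
complete_labels <- function(n_genes) {
  genes <- sprintf("g%02d", seq_len(n_genes))
  prs <- enumerate_candidate_pairs(genes)
  sl_labels(prs$gene_a, prs$gene_b,
            rep_len(c(1L, 0L), nrow(prs)), source = "sim")
}

test_that("standard runs balance classes by undersampling the majority", {
  lab <- random_labels(125, 375, seed = 2)
  runs <- make_standard_runs(lab, n_runs = 10, seed = 5)
  expect_length(runs, 10)
  for (r in runs) {
    expect_equal(sum(r$train$label == 1), sum(r$train$label == 0))
    expect_equal(sum(r$test$label == 1), sum(r$test$label == 0))
    # train 80% of 125 positives = 100 -> 100 SL + 100 non-SL
    expect_equal(sum(r$train$label == 1), 100)
    tr_ids <- paste(r$train$gene_a, r$train$gene_b)
    te_ids <- paste(r$test$gene_a, r$test$gene_b)
    expect_length(intersect(tr_ids, te_ids), 0)
  }
})

test_that("balanced input makes undersampling the identity", {
  lab <- random_labels(50, 50, seed = 3)
  runs <- make_standard_runs(lab, n_runs = 2, seed = 1)
  expect_equal(nrow(runs[[1]]$train) + nrow(runs[[1]]$test), 100)
})

test_that("runs are reproducible under a fixed seed", {
  lab <- random_labels(60, 80, seed = 4)
  r1 <- make_standard_runs(lab, n_runs = 3, seed = 9)
  r2 <- make_standard_runs(lab, n_runs = 3, seed = 9)
  expect_identical(r1, r2)
  expect_error(make_standard_runs(
    sl_labels("A", "B", 1, source = "x")), "both classes")
})

test_that("double holdout runs share no genes between train and test", {
  lab <- random_labels(80, 80, n_genes = 60, seed = 6)
  runs <- make_double_holdout_runs(lab, n_runs = 10, seed = 2)
  for (r in runs) {
    tr_genes <- unique(c(r$train$gene_a, r$train$gene_b))
    te_genes <- unique(c(r$test$gene_a, r$test$gene_b))
    expect_length(intersect(tr_genes, te_genes), 0)
    expect_equal(sum(r$train$label == 1), sum(r$train$label == 0))
  }
  expect_identical(make_double_holdout_runs(lab, n_runs = 2, seed = 2),
                   runs[1:2])
})

test_that("holdout on a small complete pair set keeps only within-side pairs", {
  lab <- complete_labels(6)   # 15 pairs on 6 genes
  runs <- make_double_holdout_runs(lab, n_runs = 5, seed = 3,
                                   balance = "none")
  for (r in runs) {
    te_genes <- unique(c(r$test$gene_a, r$test$gene_b))
    # 2 test genes admit at most C(2,2) = 1 test pair; 8 cross pairs drop
    expect_lte(length(te_genes), 2)
    expect_lte(nrow(r$test), 1)
    expect_equal(nrow(r$train) + nrow(r$test),
                 choose(6 - length(te_genes), 2) + nrow(r$test))
  }
})

test_that("retained-pair fraction under an 80/20 gene split is p^2 + q^2", {
  lab <- complete_labels(30)   # 435 pairs
  # gene-side test fraction 0.2 corresponds to a retained test share of
  # 0.04 / 0.68
  t_frac <- 0.04 / 0.68
  runs <- make_double_holdout_runs(lab, n_runs = 100, seed = 8,
                                   target_test_frac = t_frac,
                                   balance = "none")
  frac <- vapply(runs, function(r)
    (nrow(r$train) + nrow(r$test)) / nrow(lab), numeric(1))
  expect_lt(abs(mean(frac) - 0.68), 0.03)
})

test_that("cross-source runs exclude pairs present in both sources", {
  a <- sl_labels(sprintf("a%02d", 1:20), sprintf("b%02d", 1:20),
                 rep_len(c(1L, 0L), 20), source = "SRC_A")
  shared <- data.frame(g1 = sprintf("a%02d", 1:4), g2 = sprintf("b%02d", 1:4))
  b <- sl_labels(c(shared$g1, sprintf("c%02d", 1:16)),
                 c(shared$g2, sprintf("d%02d", 1:16)),
                 rep_len(c(1L, 0L), 20), source = "SRC_B")
  runs <- make_cross_source_runs(a, b, n_runs = 3, seed = 1)
  for (r in runs) {
    expect_true(all(r$train$source == "SRC_A"))
    expect_true(all(r$test$source == "SRC_B"))
    te_ids <- paste(r$test$gene_a, r$test$gene_b)
    sh_ids <- paste(shared$g1, shared$g2)
    expect_length(intersect(te_ids, sh_ids), 0)
  }
  expect_identical(make_cross_source_runs(a, b, n_runs = 3, seed = 1), runs)
  expect_error(make_cross_source_runs(a, a), "distinct")
})

test_that("disjoint sources give the full balanced test source", {
  a <- sl_labels(sprintf("a%02d", 1:10), sprintf("b%02d", 1:10),
                 rep_len(c(1L, 0L), 10), source = "SRC_A")
  b <- sl_labels(sprintf("c%02d", 1:10), sprintf("d%02d", 1:10),
                 rep_len(c(1L, 0L), 10), source = "SRC_B")
  runs <- make_cross_source_runs(a, b, n_runs = 1, seed = 1)
  expect_equal(nrow(runs[[1]]$test), 10)
})

test_that("run_experiment produces one metric row per run, deterministically", {
  tb <- toy_blocks(n = 40, seed = 10)
  runs <- make_standard_runs(tb$labels, n_runs = 3, seed = 2)
  ex <- run_experiment(runs, tb$blocks, ensemble = "rf",
                       search_budget = 1, n_folds = 3, seed = 2)
  expect_equal(nrow(ex), 3)
  expect_true(all(ex$auprc >= 0 & ex$auprc <= 1))
  ex2 <- run_experiment(runs, tb$blocks, ensemble = "rf",
                        search_budget = 1, n_folds = 3, seed = 2)
  expect_equal(as.data.frame(ex), as.data.frame(ex2))
})

test_that("a label-leaking feature drives AUPRC to 1 in every run", {
  tb <- toy_blocks(n = 40, noise_sd = 0, seed = 11)  # s1 carries the label
  runs <- make_standard_runs(tb$labels, n_runs = 2, seed = 3)
  ex <- run_experiment(runs, tb$blocks, ensemble = "rf",
                       search_budget = 1, n_folds = 3, seed = 3)
  expect_true(all(ex$auprc == 1))
})
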