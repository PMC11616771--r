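test_that("dataset assembly appends the concatenated source", {
  tb <- toy_blocks(n = 10)
  pairs <- tb$pairs
  b2 <- feature_block(pairs, matrix(rnorm(20), 10, 2), "x2")
  b3 <- feature_block(pairs, matrix(rnorm(30), 10, 3), "x3")
  out <- assemble_datasets(list(b2, b3))
  expect_length(out, 3)
  expect_equal(ncol(out[[3]]$matrix), 5)
  expect_equal(out[[3]]$source, "concat")
  expect_equal(attr(out[[3]], "column_source"), c("x2", "x2", rep("x3", 3)))
  # the default five sources concatenate to 1024 + 64 + 4 + 4 + 13 = 1109
  dims <- c(seq = 1024, ppi = 64, crispr_mut = 4, crispr_expr = 4,
            tissue = 13)
  blocks <- lapply(names(dims), function(tag)
    feature_block(pairs[1:2, ], matrix(0, 2, dims[[tag]]), tag))
  expect_equal(ncol(assemble_datasets(blocks)[[6]]$matrix), 1109)
  # permuted pair order is an error, not a silent join
  b3p <- feature_block(pairs[10:1, ], b3$matrix, "x3")
  expect_error(assemble_datasets(list(b2, b3p)), "disagree")
})

test_that("weight normalization and score combination follow the rule", {
  expect_equal(normalize_weights(c(0.5, 0.5, 1.0)), c(0.25, 0.25, 0.5))
  expect_equal(combine_scores(c(0.2, 0.8), c(0.25, 0.75)), 0.65)
  expect_equal(sum(normalize_weights(runif(7))), 1)
  expect_equal(normalize_weights(c(0, 0)), c(0.5, 0.5))  # degenerate
  # convexity: equal submodel scores pass through unchanged
  expect_equal(combine_scores(matrix(0.37, 4, 3), rep(1 / 3, 3)),
               rep(0.37, 4))
})

test_that("fitting yields normalized weights and reproducible models", {
  tb <- toy_blocks(n = 40, seed = 21)
  fit <- elisl(tb$blocks, tb$labels, ensemble = "rf", search_budget = 2,
               n_folds = 3, seed = 7)
  expect_s3_class(fit, "elisl")
  expect_equal(sum(coef(fit)), 1)
  expect_true(all(coef(fit) >= 0))
  expect_length(fit$submodels, 4)   # 3 sources + concat
  fit2 <- elisl(tb$blocks, tb$labels, ensemble = "rf", search_budget = 2,
                n_folds = 3, seed = 7)
  expect_identical(coef(fit), coef(fit2))
  expect_identical(fit$hyperparameters, fit2$hyperparameters)
  sc <- predict(fit, tb$blocks)
  expect_true(all(sc >= 0 & sc <= 1))
  expect_identical(sc, predict(fit2, tb$blocks))
  # submodel scores and the weighted average agree with combine_scores
  sub <- predict(fit, tb$blocks, type = "submodels")
  expect_equal(unname(sc), combine_scores(sub, coef(fit)))
})

test_that("degenerate fits are refused", {
  tb <- toy_blocks(n = 20)
  lab1 <- tb$labels
  lab1$label <- 1L
  expect_error(elisl(tb$blocks, lab1, search_budget = 1), "both classes")
  expect_error(elisl(tb$blocks, tb$labels, search_budget = 0), "budget")
  expect_error(elisl(tb$blocks[1], tb$labels, search_budget = 1))
})

test_that("the informative source earns the largest single-source weight", {
  wins <- 0L
  for (s in 1:10) {
    tb <- toy_blocks(n = 50, informative = "s2", seed = 100 + s)
    fit <- elisl(tb$blocks, tb$labels, ensemble = "rf", search_budget = 1,
                 n_folds = 3, seed = s)
    w <- coef(fit)[c("s1", "s2", "s3")]
    wins <- wins + (names(which.max(w)) == "s2")
  }
  expect_gte(wins, 8)
})

test_that("both ensemble kinds fit and predict on the same blocks", {
  tb <- toy_blocks(n = 40, seed = 33)
  for (kind in c("rf", "gb")) {
    fit <- elisl(tb$blocks, tb$labels, ensemble = kind, search_budget = 1,
                 n_folds = 3, seed = 3)
    expect_equal(fit$ensemble, kind)
    sc <- predict(fit, tb$blocks)
    expect_true(all(sc >= 0 & sc <= 1))
    expect_gt(auprc(tb$y, sc), 0.8)   # in-sample, strong planted signal
  }
})

test_that("prediction rejects mismatched blocks", {
  tb <- toy_blocks(n = 20, seed = 5)
  fit <- elisl(tb$blocks, tb$labels, search_budget = 1, n_folds = 3,
               seed = 2)
  wrong <- tb$blocks
  wrong$s2 <- feature_block(tb$pairs, matrix(0, 20, 7), "s2")
  expect_error(predict(fit, wrong), "widths")
  renamed <- tb$blocks
  renamed$s2$source <- "other"
  expect_error(predict(fit, renamed), "sources")
})

test_that("pan-cancer ensembling normalizes validation performances", {
  tb <- toy_blocks(n = 30, seed = 8)
  fit <- elisl(tb$blocks, tb$labels, search_budget = 1, n_folds = 3,
               seed = 4)
  pan <- ensemble_pan_cancer(list(BRCA = fit, LUAD = fit),
                             validation_perf = c(BRCA = 0.6, LUAD = 0.4))
  expect_equal(unname(pan$weights), c(0.6, 0.4))
  # identical per-cancer models: the pan-cancer score equals theirs
  expect_equal(unname(predict(pan, tb$blocks)),
               unname(predict(fit, tb$blocks)))
  pan3 <- ensemble_pan_cancer(
    list(BRCA = fit, LUAD = fit, OV = fit),
    validation_perf = c(BRCA = 0.8, LUAD = 0.1, OV = 0.1),
    exclude = "BRCA")
  expect_equal(sum(pan3$weights), 1)
  expect_false("BRCA" %in% names(pan3$weights))
  expect_error(ensemble_pan_cancer(list(BRCA = fit), exclude = NULL),
               "at least 2")
})

test_that("ranking averages scores over runs with documented tie-breaks", {
  sc <- data.frame(gene_a = c("A", "A", "C"), gene_b = c("B", "B", "D"),
                   score = c(0.9, 0.7, 0.85))
  rk <- rank_predictions(sc)
  expect_equal(rk$gene_a, c("C", "A"))       # 0.85 beats mean 0.8
  expect_equal(rk$n_runs, c(1L, 2L))
  tie <- data.frame(gene_a = c("B", "A"), gene_b = c("C", "Z"),
                    score = c(0.5, 0.5))
  expect_equal(rank_predictions(tie)$gene_a, c("A", "B"))  # lexicographic
  one <- rank_predictions(list(run1 = c("A|B" = 0.3, "C|D" = 0.6)))
  expect_equal(one$mean_score, c(0.6, 0.3))
})

test_that("model archives round-trip predictions", {
  tb <- toy_blocks(n = 24, seed = 12)
  fit <- elisl(tb$blocks, tb$labels, search_budget = 1, n_folds = 3,
               seed = 6)
  dir <- withr::local_tempdir()
  save_model(fit, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- load_model(dir)
  expect_equal(coef(back), coef(fit))
  expect_equal(predict(back, tb$blocks), predict(fit, tb$blocks))
})
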