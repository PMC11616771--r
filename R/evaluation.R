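#' Evaluation run construction
#'
#' An evaluation run is one train/test draw: disjoint train and test pair
#' sets with class-balanced labels (random undersampling of the majority
#' class, independently within train and within test). Three protocols are
#' provided: standard pair-disjoint splits ([make_standard_runs()]),
#' double gene holdout with zero train/test gene overlap
#' ([make_double_holdout_runs()]), and cross-label-source transfer
#' ([make_cross_source_runs()]).
#'
#' @name evaluation_runs
NULL

undersample <- function(labels) {
  pos <- which(labels$label == 1)
  neg <- which(labels$label == 0)
  m <- min(length(pos), length(neg))
  keep <- sort(c(
    if (length(pos) > m) sample(pos, m) else pos,
    if (length(neg) > m) sample(neg, m) else neg))
  labels[keep, , drop = FALSE]
}

new_run <- function(run, seed, train, test) {
  class(train) <- class(test) <- c("sl_labels", "data.frame")
  structure(list(run = run, seed = seed, train = train, test = test),
            class = "evaluation_run")
}

#' @export
print.evaluation_run <- function(x, ...) {
  cat(sprintf("evaluation run %d: train %d pairs (%d SL), test %d pairs (%d SL)\n",
              x$run, nrow(x$train), sum(x$train$label == 1),
              nrow(x$test), sum(x$test$label == 1)))
  invisible(x)
}

#' Standard pair-disjoint evaluation runs
#'
#' Splits the labelled pairs once into disjoint train (80%) and test
#' (20%) sets, stratified by label; then draws `n_runs` runs, each
#' independently undersampling the majority class within train and within
#' test to balance the labels.
#'
#' @param labels an `sl_labels` table with both classes.
#' @param n_runs number of runs (default 10).
#' @param seed integer seed.
#' @param test_frac test fraction of the one global split.
#' @param balance `"both"` balances train and test; `"train"` only train;
#'   `"none"` leaves both unbalanced (diagnostics).
#' @return list of `evaluation_run`s.
#' @rdname evaluation_runs
#' @export
make_standard_runs <- function(labels, n_runs = 10L, seed = 1L,
                               test_frac = 0.2,
                               balance = c("both", "train", "none")) {
  balance <- match.arg(balance)
  stopifnot(inherits(labels, "sl_labels"))
  if (length(unique(labels$label)) < 2) stop("both classes must be present")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(seed)
  test_idx <- integer()
  for (cl in c(0, 1)) {
    idx <- which(labels$label == cl)
    test_idx <- c(test_idx, sample(idx, round(test_frac * length(idx))))
  }
  train_all <- labels[-test_idx, , drop = FALSE]
  test_all <- labels[test_idx, , drop = FALSE]
  lapply(seq_len(n_runs), function(r) {
    run_seed <- seed + 101L * r
    set.seed(run_seed)
    tr <- if (balance == "none") train_all else undersample(train_all)
    te <- if (balance == "both") undersample(test_all) else test_all
    new_run(r, run_seed, tr, te)
  })
}

genes_of <- function(labels) unique(c(labels$gene_a, labels$gene_b))

#' Double gene holdout runs
#'
#' Per run, the gene universe of the labelled pairs is randomly
#' partitioned into train genes and test genes; a pair is retained on a
#' side only when both its genes fall on that side (cross pairs are
#' dropped), so train and test share no genes at all. The gene-side test
#' fraction defaults to the value that makes the expected retained test
#' pair fraction about `target_test_frac` on a dense pair set. Partitions
#' leaving one class empty on either side are resampled up to
#' `retry_budget` times.
#'
#' @param target_test_frac desired test share of retained pairs.
#' @param retry_budget partition resampling attempts per run.
#' @rdname evaluation_runs
#' @export
make_double_holdout_runs <- function(labels, n_runs = 10L, seed = 1L,
                                     target_test_frac = 0.2,
                                     balance = c("both", "train", "none"),
                                     retry_budget = 50L) {
  balance <- match.arg(balance)
  stopifnot(inherits(labels, "sl_labels"))
  if (length(unique(labels$label)) < 2) stop("both classes must be present")
  genes <- sort_c(genes_of(labels))
  if (length(genes) < 4) stop("too few genes to partition")
  # gene-side fraction q with q^2 / (q^2 + (1-q)^2) = target test fraction
  t <- target_test_frac
  q <- sqrt(t) / (sqrt(t) + sqrt(1 - t))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  lapply(seq_len(n_runs), function(r) {
    run_seed <- seed + 101L * r
    set.seed(run_seed)
    for (attempt in seq_len(retry_budget)) {
      test_genes <- sample(genes, max(2L, round(q * length(genes))))
      in_test <- labels$gene_a %in% test_genes &
        labels$gene_b %in% test_genes
      in_train <- !(labels$gene_a %in% test_genes) &
        !(labels$gene_b %in% test_genes)
      tr <- labels[in_train, , drop = FALSE]
      te <- labels[in_test, , drop = FALSE]
      ok <- if (balance == "none") {
        nrow(tr) > 0 && nrow(te) > 0
      } else {
        length(unique(tr$label)) == 2 && length(unique(te$label)) == 2
      }
      if (ok) {
        if (balance != "none") tr <- undersample(tr)
        if (balance == "both") te <- undersample(te)
        return(new_run(r, run_seed, tr, te))
      }
    }
    stop("could not find a gene partition with both classes on both sides ",
         "in ", retry_budget, " attempts (run ", r, ")")
  })
}

#' Cross-label-source runs
#'
#' Trains on labels from one study source and tests on another: train
#' pairs are drawn from `train_labels` only, test pairs from
#' `test_labels` only, and any pair present in both sources is removed
#' from the test side to prevent leakage.
#'
#' @param train_labels,test_labels `sl_labels` from two distinct sources.
#' @rdname evaluation_runs
#' @export
make_cross_source_runs <- function(train_labels, test_labels, n_runs = 10L,
                                   seed = 1L,
                                   balance = c("both", "train", "none")) {
  balance <- match.arg(balance)
  stopifnot(inherits(train_labels, "sl_labels"),
            inherits(test_labels, "sl_labels"))
  if (identical(sort_c(unique(train_labels$source)),
                sort_c(unique(test_labels$source)))) {
    stop("train and test label sources must be distinct")
  }
  tr_ids <- paste(train_labels$gene_a, train_labels$gene_b, sep = "|")
  te_ids <- paste(test_labels$gene_a, test_labels$gene_b, sep = "|")
  test_all <- test_labels[!(te_ids %in% tr_ids), , drop = FALSE]
  if (nrow(test_all) == 0 || length(unique(test_all$label)) < 2) {
    stop("after removing shared pairs the test source lacks both classes")
  }
  if (length(unique(train_labels$label)) < 2) {
    stop("both classes must be present in the training source")
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  lapply(seq_len(n_runs), function(r) {
    run_seed <- seed + 101L * r
    set.seed(run_seed)
    tr <- if (balance == "none") train_labels else undersample(train_labels)
    te <- if (balance == "both") undersample(test_all) else test_all
    new_run(r, run_seed, tr, te)
  })
}

#' Run a full evaluation experiment
#'
#' Fits a model on each run's train pairs and scores its test pairs,
#' recording AUPRC and AUROC per run. Failures in individual runs are
#' isolated (recorded as NA with a warning) rather than aborting the
#' experiment.
#'
#' @param runs list of `evaluation_run`s.
#' @param blocks list of `feature_block`s covering every pair in the runs.
#' @param ensemble,search_budget,grid,n_folds,seed passed to [elisl()].
#' @return data frame of class `"elisl_experiment"` with columns `run`,
#'   `auprc`, `auroc`; per-run fitted models in attribute `"models"`,
#'   per-run test scores in attribute `"scores"`.
#' @export
run_experiment <- function(runs, blocks, ensemble = c("rf", "gb"),
                           search_budget = 5L, grid = NULL, n_folds = 5L,
                           seed = 1L) {
  ensemble <- match.arg(ensemble)
  rows <- vector("list", length(runs))
  models <- vector("list", length(runs))
  scores <- vector("list", length(runs))
  for (i in seq_along(runs)) {
    run <- runs[[i]]
    res <- tryCatch({
      tr_ids <- paste(run$train$gene_a, run$train$gene_b, sep = "|")
      te_ids <- paste(run$test$gene_a, run$test$gene_b, sep = "|")
      tr_blocks <- lapply(blocks, subset_block, ids = tr_ids)
      te_blocks <- lapply(blocks, subset_block, ids = te_ids)
      fit <- elisl(tr_blocks, run$train, ensemble = ensemble,
                   search_budget = search_budget, grid = grid,
                   n_folds = n_folds, seed = run$seed)
      sc <- predict(fit, te_blocks)
      list(fit = fit, sc = sc,
           auprc = auprc(run$test$label, sc),
           auroc = auroc(run$test$label, sc))
    }, error = function(e) {
      warning("run ", run$run, " failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) {
      rows[[i]] <- data.frame(run = run$run, auprc = NA_real_,
                              auroc = NA_real_)
    } else {
      rows[[i]] <- data.frame(run = run$run, auprc = res$auprc,
                              auroc = res$auroc)
      models[[i]] <- res$fit
      scores[[i]] <- res$sc
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "models") <- models
  attr(out, "scores") <- scores
  class(out) <- c("elisl_experiment", "data.frame")
  out
}

#' @export
print.elisl_experiment <- function(x, ...) {
  cat(sprintf("evaluation over %d runs\n", nrow(x)))
  cat(sprintf("  AUPRC mean %.3f (median %.3f), AUROC mean %.3f (median %.3f)\n",
              mean(x$auprc, na.rm = TRUE), stats::median(x$auprc, na.rm = TRUE),
              mean(x$auroc, na.rm = TRUE), stats::median(x$auroc, na.rm = TRUE)))
  invisible(x)
}
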