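#' Assemble per-source datasets plus their concatenation
#'
#' Given k per-source feature blocks over the same ordered pair list,
#' returns the k originals plus the early-integration block: the
#' column-wise concatenation (width sum of the per-source widths), with
#' per-column source provenance recorded. The k + 1 blocks are what the
#' ensemble trains on.
#'
#' @param blocks list of k (>= 2) `feature_block`s sharing the same pair
#'   list and order.
#' @return list of k + 1 `feature_block`s; the last has source `"concat"`
#'   and attribute `"column_source"`.
#' @export
assemble_datasets <- function(blocks) {
  stopifnot(is.list(blocks), length(blocks) >= 2)
  for (b in blocks) stopifnot(inherits(b, "feature_block"))
  ids <- pair_id(blocks[[1]]$pairs)
  for (b in blocks[-1]) {
    if (!identical(pair_id(b$pairs), ids)) {
      stop("feature blocks disagree on pair list/order (block '",
           b$source, "')")
    }
  }
  tags <- unname(vapply(blocks, `[[`, character(1), "source"))
  if (anyDuplicated(tags)) stop("duplicate source tags: ",
                                paste(tags[duplicated(tags)], collapse = ", "))
  mats <- lapply(blocks, `[[`, "matrix")
  concat <- do.call(cbind, mats)
  cb <- feature_block(blocks[[1]]$pairs, concat, "concat")
  attr(cb, "column_source") <- rep(tags, vapply(mats, ncol, integer(1)))
  c(blocks, list(cb))
}

# ---- hyperparameter grid -------------------------------------------------

#' Default shared hyperparameter grid
#'
#' One configuration is shared by all k + 1 submodels per trial. Random
#' forests search trees x max depth x minimum leaf size; gradient boosting
#' additionally searches the learning rate. `max_depth = 0` means
#' unlimited.
#'
#' @param kind `"rf"` or `"gb"`.
#' @return data frame, one row per configuration.
#' @export
default_grid <- function(kind = c("rf", "gb")) {
  kind <- match.arg(kind)
  g <- expand.grid(n_trees = c(100L, 200L, 500L),
                   max_depth = c(4L, 8L, 0L),
                   min_leaf = c(1L, 5L, 10L),
                   KEEP.OUT.ATTRS = FALSE)
  if (kind == "gb") {
    g <- merge(g, data.frame(learning_rate = c(0.05, 0.1, 0.3)))
  }
  g
}

#' Integration arithmetic: weight normalization and score combination
#'
#' The late-integration rule: submodel weights are validation performances
#' normalized to sum to one, `w_i = p_i / sum(p_j)`; the ensemble score of
#' a pair is the weighted average `sum_i w_i yhat_i` of submodel
#' class-probabilities. With all performances zero the weights fall back
#' to uniform.
#'
#' @param p non-negative numeric vector of validation performances.
#' @return `normalize_weights`: weights summing to 1.
#' @examples
#' normalize_weights(c(0.5, 0.5, 1.0))   # 0.25 0.25 0.50
#' combine_scores(c(0.2, 0.8), c(0.25, 0.75))  # 0.65
#' @export
normalize_weights <- function(p) {
  stopifnot(all(p >= 0))
  if (sum(p) > 0) p / sum(p) else rep(1 / length(p), length(p))
}

#' @param scores numeric vector (one pair) or N x k matrix (rows = pairs)
#'   of submodel scores.
#' @param weights weights summing to 1.
#' @return `combine_scores`: the weighted-average ensemble score(s).
#' @rdname normalize_weights
#' @export
combine_scores <- function(scores, weights) {
  if (is.matrix(scores)) {
    stopifnot(ncol(scores) == length(weights))
    as.numeric(scores %*% weights)
  } else {
    stopifnot(length(scores) == length(weights))
    sum(scores * weights)
  }
}

# ---- submodel backends ---------------------------------------------------

# backend namespaces must be loaded with the package so that S3 dispatch
# works on submodels restored from archives
#' @importFrom ranger ranger
#' @importFrom xgboost xgb.train xgb.DMatrix
#' @importFrom survival coxph Surv survfit
#' @importFrom jsonlite write_json read_json
#' @importFrom igraph simplify graph_from_data_frame
NULL

fit_submodel <- function(x, y, kind, params, seed) {
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  if (kind == "rf") {
    m <- ranger::ranger(
      x = x, y = factor(y, levels = c(0, 1)), probability = TRUE,
      num.trees = params$n_trees,
      max.depth = params$max_depth,        # 0 = unlimited
      min.node.size = params$min_leaf,
      seed = seed, num.threads = 1)
    structure(list(kind = "rf", model = m), class = "elisl_submodel")
  } else {
    dm <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
    depth <- if (params$max_depth == 0L) 12L else params$max_depth
    m <- xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    max_depth = depth,
                    eta = params$learning_rate,
                    min_child_weight = params$min_leaf,
                    nthread = 1, seed = seed),
      data = dm, nrounds = params$n_trees, verbose = 0)
    structure(list(kind = "gb", model = m), class = "elisl_submodel")
  }
}

predict_submodel <- function(sm, x) {
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  if (sm$kind == "rf") {
    predict(sm$model, data = x, num.threads = 1)$predictions[, "1"]
  } else {
    predict(sm$model, xgboost::xgb.DMatrix(x, nthread = 1))
  }
}

# per-column median imputation; all-NA columns fall back to 0
impute_stats <- function(x) {
  med <- apply(x, 2, stats::median, na.rm = TRUE)
  med[!is.finite(med)] <- 0
  med
}

impute_apply <- function(x, med) {
  for (j in seq_len(ncol(x))) {
    nas <- is.na(x[, j])
    if (any(nas)) x[nas, j] <- med[j]
  }
  x
}

# stratified k-fold assignment
make_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(seed)
  for (cl in unique(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

# evaluate one shared configuration by n-fold CV; returns the ensemble
# validation AUPRC (trial score) and per-submodel mean validation AUPRCs
eval_config <- function(mats, y, params, kind, folds, seed) {
  k1 <- length(mats)
  nf <- max(folds)
  sub_auprc <- matrix(NA_real_, nf, k1)
  ens_auprc <- numeric(nf)
  for (f in seq_len(nf)) {
    tr <- folds != f; va <- !tr
    preds <- matrix(0, sum(va), k1)
    for (i in seq_len(k1)) {
      xtr <- mats[[i]][tr, , drop = FALSE]
      med <- impute_stats(xtr)
      xtr <- impute_apply(xtr, med)
      xva <- impute_apply(mats[[i]][va, , drop = FALSE], med)
      sm <- fit_submodel(xtr, y[tr], kind, params, seed + 1000L * i + f)
      preds[, i] <- predict_submodel(sm, xva)
      sub_auprc[f, i] <- auprc(y[va], preds[, i])
    }
    w <- normalize_weights(sub_auprc[f, ])
    ens_auprc[f] <- auprc(y[va], combine_scores(preds, w))
  }
  list(score = mean(ens_auprc), p_sub = colMeans(sub_auprc))
}

# sequential model-based search over a finite grid: seed trials at random,
# then repeatedly propose the unevaluated configuration whose predicted
# score (inverse-distance-weighted over evaluated neighbours in normalized
# parameter space) plus an exploration bonus is highest
smbo_search <- function(grid, budget, eval_fn, seed) {
  n <- nrow(grid)
  if (budget < 1) stop("search budget must be >= 1")
  gnum <- scale(data.matrix(grid))
  gnum[is.nan(gnum)] <- 0
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(seed)
  if (n <= budget) {
    tried <- seq_len(n)
  } else {
    n_init <- min(budget, 5L)
    tried <- sample.int(n, n_init)
  }
  results <- vector("list", n)
  scores <- rep(NA_real_, n)
  for (i in tried) {
    results[[i]] <- eval_fn(grid[i, , drop = FALSE])
    scores[i] <- results[[i]]$score
  }
  while (sum(!is.na(scores)) < min(budget, n)) {
    done <- which(!is.na(scores))
    todo <- which(is.na(scores))
    dmat <- as.matrix(stats::dist(gnum))[todo, done, drop = FALSE]
    wts <- 1 / (dmat + 1e-6)
    pred <- as.numeric((wts %*% scores[done]) / rowSums(wts))
    explore <- apply(dmat, 1, min)
    cand <- todo[which.max(pred + 0.05 * explore)]
    results[[cand]] <- eval_fn(grid[cand, , drop = FALSE])
    scores[cand] <- results[[cand]]$score
  }
  best <- which.max(scores)
  list(best_index = best, best_params = grid[best, , drop = FALSE],
       best_result = results[[best]], scores = scores)
}

# ---- the fitting function ------------------------------------------------

#' Fit an early-late integrated SL prediction ensemble
#'
#' Trains k per-source tree-ensemble submodels plus one on the
#' concatenation of all sources, with one shared hyperparameter
#' configuration selected by sequential model-based search over a finite
#' grid, scored by the mean 5-fold cross-validated AUPRC of the weighted
#' ensemble. Each submodel's validation performance p_i (its own mean
#' fold AUPRC) sets its weight w_i = p_i / sum(p_j); the ensemble
#' prediction for a pair is the weighted average of submodel
#' class-probabilities. Missing feature values are imputed by
#' training-data column medians, frozen at fit time.
#'
#' @param blocks list of k >= 2 `feature_block`s over the same pair list
#'   (the concatenated block is built internally).
#' @param labels an `sl_labels` table covering the block pair list (both
#'   classes present). Any `source`/`cancer` provenance is ignored here;
#'   harmonize and subset upstream.
#' @param ensemble submodel family: `"rf"` (random forest) or `"gb"`
#'   (gradient-boosted trees).
#' @param search_budget maximum configurations evaluated (falls back to
#'   exhaustive search when the grid is smaller).
#' @param grid hyperparameter grid; defaults to [default_grid()].
#' @param n_folds cross-validation folds (stratified by label).
#' @param seed integer seed controlling folds, search and tree fitting.
#' @return an object of class `"elisl"`: list with `submodels`, `weights`,
#'   `val_auprc` (p_i), `hyperparameters`, `sources`, `widths`,
#'   `imputation` (per-source medians), `ensemble`, `seed`, `search`.
#' @seealso [predict.elisl()], [ensemble_pan_cancer()],
#'   [importance_report()]
#' @examples
#' \donttest{
#' world <- generate_world(synthetic_world_config(n_genes = 30,
#'   n_cell_lines = 60, n_patients = 80, n_sl_pairs = 15,
#'   n_nonsl_pairs = 15, d_seq = 16, d_ppi = 8), seed = 1)
#' blocks <- featurize_world(world)
#' fit <- elisl(blocks, world$labels, ensemble = "rf", search_budget = 1,
#'              seed = 1)
#' coef(fit)
#' }
#' @export
elisl <- function(blocks, labels, ensemble = c("rf", "gb"),
                  search_budget = 25L, grid = NULL, n_folds = 5L,
                  seed = 1L) {
  ensemble <- match.arg(ensemble)
  if (search_budget < 1) stop("search budget must be >= 1")
  all_blocks <- assemble_datasets(blocks)
  ids <- pair_id(all_blocks[[1]]$pairs)
  lab_ids <- paste(labels$gene_a, labels$gene_b, sep = "|")
  pos <- match(ids, lab_ids)
  if (anyNA(pos)) {
    stop("labels missing for ", sum(is.na(pos)), " pair(s), e.g. ",
         ids[is.na(pos)][1])
  }
  y <- as.integer(labels$label[pos])
  if (length(unique(y)) < 2) stop("both classes must be present in labels")
  if (is.null(grid)) grid <- default_grid(ensemble)
  mats <- lapply(all_blocks, `[[`, "matrix")
  folds <- make_folds(y, n_folds, seed)
  search <- smbo_search(grid, search_budget,
                        function(params) eval_config(mats, y, params,
                                                     ensemble, folds, seed),
                        seed)
  params <- search$best_params
  p_sub <- search$best_result$p_sub
  w <- normalize_weights(p_sub)
  meds <- lapply(mats, impute_stats)
  submodels <- vector("list", length(mats))
  for (i in seq_along(mats)) {
    xi <- impute_apply(mats[[i]], meds[[i]])
    submodels[[i]] <- fit_submodel(xi, y, ensemble, params,
                                   seed + 7L * i)
  }
  tags <- unname(vapply(all_blocks, `[[`, character(1), "source"))
  structure(list(
    submodels = submodels,
    weights = stats::setNames(as.numeric(w), tags),
    val_auprc = stats::setNames(as.numeric(p_sub), tags),
    hyperparameters = params,
    sources = tags[-length(tags)],
    widths = stats::setNames(vapply(mats, ncol, integer(1)), tags),
    imputation = stats::setNames(meds, tags),
    ensemble = ensemble,
    n_pairs = length(y),
    seed = seed,
    search = list(budget = search_budget, n_tried = sum(!is.na(search$scores)),
                  cv_auprc = max(search$scores, na.rm = TRUE))
  ), class = "elisl")
}

#' Predict SL probability scores
#'
#' The ensemble score of each pair is the convex combination
#' `sum_i w_i yhat_i` of submodel class-probabilities, so it always lies
#' in \[0, 1\] (and within the range of the submodel scores).
#'
#' @param object an `"elisl"` fit.
#' @param blocks list of k `feature_block`s matching the model's source
#'   tags, order and widths (the concatenation is built internally).
#' @param type `"response"` for the ensemble score, `"submodels"` for the
#'   N x (k+1) matrix of per-submodel scores.
#' @param ... unused.
#' @return numeric vector of scores named by pair id, or a score matrix.
#' @export
predict.elisl <- function(object, blocks, type = c("response", "submodels"),
                          ...) {
  type <- match.arg(type)
  all_blocks <- assemble_datasets(blocks)
  tags <- unname(vapply(all_blocks, `[[`, character(1), "source"))
  if (!identical(tags, names(object$weights))) {
    stop("blocks do not match the model's sources (expected ",
         paste(names(object$weights), collapse = ", "), ")")
  }
  widths <- vapply(all_blocks, function(b) ncol(b$matrix), integer(1))
  if (!identical(as.integer(widths), as.integer(object$widths))) {
    stop("feature widths do not match the fitted model")
  }
  ids <- pair_id(all_blocks[[1]]$pairs)
  preds <- matrix(0, length(ids), length(tags),
                  dimnames = list(ids, tags))
  for (i in seq_along(all_blocks)) {
    xi <- impute_apply(all_blocks[[i]]$matrix, object$imputation[[i]])
    preds[, i] <- predict_submodel(object$submodels[[i]], xi)
  }
  if (type == "submodels") return(preds)
  stats::setNames(combine_scores(preds, object$weights), ids)
}

#' @export
print.elisl <- function(x, ...) {
  cat(sprintf("Early-late integrated SL ensemble (%s), %d sources + concat, %d training pairs\n",
              toupper(x$ensemble), length(x$sources), x$n_pairs))
  cat("  weights:\n")
  for (nm in names(x$weights)) {
    cat(sprintf("    %-12s w = %.3f  (validation AUPRC %.3f)\n",
                nm, x$weights[nm], x$val_auprc[nm]))
  }
  cat(sprintf("  ensemble CV AUPRC: %.3f\n", x$search$cv_auprc))
  invisible(x)
}

#' @export
summary.elisl <- function(object, ...) {
  cat(sprintf("ELISL-%s model\n", toupper(object$ensemble)))
  print(object)
  cat("  shared hyperparameters:\n")
  hp <- object$hyperparameters
  for (nm in names(hp)) cat(sprintf("    %s = %s\n", nm, hp[[nm]]))
  cat(sprintf("  search: %d/%d configurations tried\n",
              object$search$n_tried, object$search$budget))
  invisible(object)
}

#' @export
coef.elisl <- function(object, ...) object$weights

#' @export
plot.elisl <- function(x, ...) {
  graphics::barplot(x$weights, ylab = "ensemble weight",
                    main = sprintf("ELISL-%s submodel weights",
                                   toupper(x$ensemble)), las = 2, ...)
  invisible(x)
}

# ---- pan-cancer ensembling ----------------------------------------------

#' Pan-cancer ensemble of per-cancer models
#'
#' Combines already-fitted per-cancer models by a weighted average of
#' their prediction scores, with weights proportional to each model's
#' validation performance. Optionally excludes one cancer's model
#' (leave-one-cancer-out evaluation).
#'
#' @param models named list (cancer -> `"elisl"` fit).
#' @param validation_perf named numeric (cancer -> validation score);
#'   defaults to each model's CV ensemble AUPRC.
#' @param exclude cancer code(s) to leave out.
#' @return object of class `"elisl_pan"` with the included models and
#'   their normalized weights.
#' @export
ensemble_pan_cancer <- function(models, validation_perf = NULL,
                                exclude = NULL) {
  stopifnot(is.list(models), !is.null(names(models)))
  if (is.null(validation_perf)) {
    validation_perf <- vapply(models, function(m) m$search$cv_auprc,
                              numeric(1))
  }
  keep <- setdiff(names(models), exclude)
  if (length(keep) < 2) stop("need at least 2 models after exclusion")
  w <- normalize_weights(validation_perf[keep])
  structure(list(models = models[keep],
                 weights = stats::setNames(as.numeric(w), keep)),
            class = "elisl_pan")
}

#' @export
predict.elisl_pan <- function(object, blocks, ...) {
  preds <- vapply(object$models,
                  function(m) predict(m, blocks), numeric(nrow(blocks[[1]])))
  stats::setNames(combine_scores(preds, object$weights),
                  pair_id(blocks[[1]]$pairs))
}

#' @export
print.elisl_pan <- function(x, ...) {
  cat("Pan-cancer SL ensemble of", length(x$models), "per-cancer models\n")
  for (nm in names(x$weights)) {
    cat(sprintf("  %-8s w = %.3f\n", nm, x$weights[nm]))
  }
  invisible(x)
}

#' Rank pairs by average prediction score across runs
#'
#' Pairs scored in at least one evaluation run are ranked by their mean
#' prediction probability over the runs they appear in, descending; ties
#' are broken lexicographically by pair id. The number of contributing
#' runs is reported per pair.
#'
#' @param scores data frame with columns `gene_a`, `gene_b`, `score` (one
#'   row per pair per run), or a named list of per-run score vectors named
#'   by pair id.
#' @return data frame (`gene_a`, `gene_b`, `mean_score`, `n_runs`),
#'   ranked.
#' @export
rank_predictions <- function(scores) {
  if (is.list(scores) && !is.data.frame(scores)) {
    scores <- do.call(rbind, lapply(scores, function(v) {
      parts <- strsplit(names(v), "|", fixed = TRUE)
      data.frame(gene_a = vapply(parts, `[`, "", 1),
                 gene_b = vapply(parts, `[`, "", 2),
                 score = as.numeric(v), stringsAsFactors = FALSE)
    }))
  }
  stopifnot(all(c("gene_a", "gene_b", "score") %in% names(scores)))
  id <- paste(scores$gene_a, scores$gene_b, sep = "|")
  mean_score <- tapply(scores$score, id, mean)
  n_runs <- tapply(scores$score, id, length)
  ids <- sort_c(names(mean_score))
  out <- data.frame(
    gene_a = sub("\\|.*$", "", ids),
    gene_b = sub("^.*\\|", "", ids),
    mean_score = as.numeric(mean_score[ids]),
    n_runs = as.integer(n_runs[ids]),
    stringsAsFactors = FALSE)
  out <- out[order(-out$mean_score, out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}
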