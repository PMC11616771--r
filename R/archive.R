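#' Save / load a fitted ensemble as a model archive
#'
#' A model archive is a directory with a JSON manifest (format version,
#' ensemble kind, source tags and widths, weights, validation
#' performances, hyperparameters, seed, imputation statistics) plus one
#' serialized submodel file per source. The manifest is plain text so the
#' archive is inspectable without loading it.
#'
#' @param model an `"elisl"` fit.
#' @param dir archive directory (created if needed).
#' @return `save_model` returns `dir` invisibly; `load_model` returns the
#'   restored `"elisl"` object.
#' @export
save_model <- function(model, dir) {
  stopifnot(inherits(model, "elisl"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    format = "elisl-archive-1",
    ensemble = model$ensemble,
    k = length(model$sources),
    sources = model$sources,
    widths = as.list(model$widths),
    weights = as.list(model$weights),
    val_auprc = as.list(model$val_auprc),
    hyperparameters = as.list(model$hyperparameters),
    n_pairs = model$n_pairs,
    seed = model$seed,
    imputation = lapply(model$imputation, as.numeric))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (i in seq_along(model$submodels)) {
    saveRDS(model$submodels[[i]],
            file.path(dir, sprintf("submodel_%02d.rds", i)))
  }
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"),
                            simplifyVector = TRUE)
  if (!identical(mf$format, "elisl-archive-1")) {
    stop("not an elisl model archive: ", dir)
  }
  tags <- c(mf$sources, "concat")
  submodels <- lapply(seq_along(tags), function(i)
    readRDS(file.path(dir, sprintf("submodel_%02d.rds", i))))
  structure(list(
    submodels = submodels,
    weights = stats::setNames(as.numeric(mf$weights[tags]), tags),
    val_auprc = stats::setNames(as.numeric(mf$val_auprc[tags]), tags),
    hyperparameters = as.data.frame(mf$hyperparameters),
    sources = mf$sources,
    widths = stats::setNames(as.integer(mf$widths[tags]), tags),
    imputation = stats::setNames(mf$imputation[tags], tags),
    ensemble = mf$ensemble,
    n_pairs = mf$n_pairs,
    seed = mf$seed,
    search = list(budget = NA_integer_, n_tried = NA_integer_,
                  cv_auprc = NA_real_)
  ), class = "elisl")
}
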