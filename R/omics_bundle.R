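#' Bundle multi-omics layers for one sample cohort
#'
#' Container for the omics layers the feature generators consume. Cell-line
#' cohorts typically carry `dependency` (CRISPR gene-dependency scores),
#' `expr_z`, `mutations` and `cna`; patient tissue cohorts carry `expr_z`,
#' `expr_level`, `mutations`, `cna`, `clinical` and, for the coexpression
#' compartments, `expr_normal` and `expr_healthy`. All matrices are
#' sample x gene with sample ids as row names and gene symbols as column
#' names. Any layer may be `NULL`; features requiring a missing layer come
#' out missing.
#'
#' @param dependency sample x gene numeric matrix of dependency scores
#'   (more negative = more essential).
#' @param expr_z sample x gene matrix of expression z-scores (used for
#'   alteration calling).
#' @param expr_level sample x gene non-negative matrix of expression levels
#'   (used for averaging/correlation).
#' @param mutations data frame with columns `sample`, `gene`,
#'   `variant_class`.
#' @param cna sample x gene integer matrix with discrete copy-number calls
#'   in -2..2.
#' @param clinical data frame with columns `sample`, `time` (months),
#'   `event` (0/1), `age` (years), `sex`, `cancer`.
#' @param sample_context named character vector mapping sample id to
#'   cancer-type code. Defaults to the clinical `cancer` column, else a
#'   single `"PAN"` context over all samples seen in the matrices.
#' @param expr_normal,expr_healthy sample x gene expression-level matrices
#'   for matched normal tissue and healthy donor tissue.
#' @return list of class `"omics_bundle"`.
#' @export
omics_bundle <- function(dependency = NULL, expr_z = NULL, expr_level = NULL,
                         mutations = NULL, cna = NULL, clinical = NULL,
                         sample_context = NULL,
                         expr_normal = NULL, expr_healthy = NULL) {
  chk_mat <- function(m, name, integerish = FALSE) {
    if (is.null(m)) return(NULL)
    m <- as.matrix(m)
    if (is.null(rownames(m)) || is.null(colnames(m))) {
      stop(name, " must have sample row names and gene column names")
    }
    storage.mode(m) <- "double"
    m
  }
  dependency <- chk_mat(dependency, "dependency")
  expr_z     <- chk_mat(expr_z, "expr_z")
  expr_level <- chk_mat(expr_level, "expr_level")
  cna        <- chk_mat(cna, "cna")
  if (!is.null(cna) && !all(cna[!is.na(cna)] %in% -2:2)) {
    stop("cna values must be discrete scores in {-2,-1,0,1,2}")
  }
  if (!is.null(mutations)) {
    mutations <- as.data.frame(mutations)
    need <- c("sample", "gene", "variant_class")
    if (!all(need %in% names(mutations))) {
      stop("mutations needs columns: ", paste(need, collapse = ", "))
    }
  }
  if (!is.null(clinical)) {
    clinical <- as.data.frame(clinical)
    need <- c("sample", "time", "event")
    if (!all(need %in% names(clinical))) {
      stop("clinical needs columns: ", paste(need, collapse = ", "))
    }
    if (any(clinical$time < 0, na.rm = TRUE)) stop("clinical time must be >= 0")
  }
  samples <- unique(c(
    rownames(dependency), rownames(expr_z), rownames(expr_level),
    rownames(cna), if (!is.null(clinical)) as.character(clinical$sample)
  ))
  if (is.null(sample_context)) {
    if (!is.null(clinical) && "cancer" %in% names(clinical)) {
      sample_context <- stats::setNames(as.character(clinical$cancer),
                                        as.character(clinical$sample))
    } else {
      sample_context <- stats::setNames(rep("PAN", length(samples)), samples)
    }
  }
  out <- list(dependency = dependency, expr_z = expr_z,
              expr_level = expr_level, mutations = mutations, cna = cna,
              clinical = clinical, sample_context = sample_context,
              expr_normal = chk_mat(expr_normal, "expr_normal"),
              expr_healthy = chk_mat(expr_healthy, "expr_healthy"))
  class(out) <- "omics_bundle"
  out
}

#' @export
print.omics_bundle <- function(x, ...) {
  cat("omics_bundle\n")
  for (nm in c("dependency", "expr_z", "expr_level", "cna",
               "expr_normal", "expr_healthy")) {
    if (!is.null(x[[nm]])) {
      cat(sprintf("  %-12s %d samples x %d genes\n", nm,
                  nrow(x[[nm]]), ncol(x[[nm]])))
    }
  }
  if (!is.null(x$mutations)) {
    cat(sprintf("  %-12s %d calls\n", "mutations", nrow(x$mutations)))
  }
  if (!is.null(x$clinical)) {
    cat(sprintf("  %-12s %d patients\n", "clinical", nrow(x$clinical)))
  }
  cat(sprintf("  contexts: %s\n",
              paste(unique(x$sample_context), collapse = ", ")))
  invisible(x)
}

#' Restrict a bundle to one cancer-type context
#'
#' Context-specific features are computed per tissue: this keeps only
#' samples whose `sample_context` matches `cancer`. The gene universe is
#' unchanged. An unknown code yields an empty (0-sample) bundle with a
#' warning; filtering twice with the same code is a no-op.
#'
#' @param bundle an `omics_bundle`.
#' @param cancer cancer-type code to keep.
#' @return the filtered `omics_bundle`.
#' @export
filter_context <- function(bundle, cancer) {
  stopifnot(inherits(bundle, "omics_bundle"))
  keep <- names(bundle$sample_context)[bundle$sample_context %in% cancer]
  if (length(keep) == 0) {
    warning("no samples with context ", paste(cancer, collapse = "/"),
            "; returning an empty selection")
  }
  sub_mat <- function(m) {
    if (is.null(m)) return(NULL)
    m[rownames(m) %in% keep, , drop = FALSE]
  }
  bundle$dependency  <- sub_mat(bundle$dependency)
  bundle$expr_z      <- sub_mat(bundle$expr_z)
  bundle$expr_level  <- sub_mat(bundle$expr_level)
  bundle$cna         <- sub_mat(bundle$cna)
  # normal/healthy compartments are reference tissue, not tumour samples;
  # they are matched to the tissue upstream and not re-filtered here
  if (!is.null(bundle$mutations)) {
    bundle$mutations <- bundle$mutations[bundle$mutations$sample %in% keep, ,
                                         drop = FALSE]
  }
  if (!is.null(bundle$clinical)) {
    bundle$clinical <- bundle$clinical[bundle$clinical$sample %in% keep, ,
                                       drop = FALSE]
  }
  bundle$sample_context <- bundle$sample_context[names(bundle$sample_context)
                                                 %in% keep]
  bundle
}
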