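#' Per-source feature matrices for gene pairs
#'
#' A feature block holds the N x f feature matrix one data source produces
#' for an ordered list of N gene pairs, plus the source tag. Row order
#' matches the pair list; missing values are allowed (imputed at model
#' fit time).
#'
#' @param pairs a `gene_pairs` object (N rows).
#' @param matrix numeric N x f matrix; column names are feature names.
#' @param source character scalar tag, e.g. `"seq"`, `"ppi"`,
#'   `"crispr_mut"`, `"crispr_expr"`, `"tissue"`.
#' @return list of class `"feature_block"` with elements `pairs`, `matrix`,
#'   `source`.
#' @export
feature_block <- function(pairs, matrix, source) {
  stopifnot(inherits(pairs, "gene_pairs"))
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "double"
  if (nrow(matrix) != nrow(pairs)) {
    stop("matrix rows (", nrow(matrix), ") != number of pairs (",
         nrow(pairs), ")")
  }
  if (ncol(matrix) < 1) stop("feature block needs at least one column")
  if (is.null(colnames(matrix))) {
    colnames(matrix) <- sprintf("%s_f%d", source, seq_len(ncol(matrix)))
  }
  rownames(matrix) <- pair_id(pairs)
  structure(list(pairs = pairs, matrix = matrix,
                 source = as.character(source)),
            class = "feature_block")
}

#' @export
print.feature_block <- function(x, ...) {
  cat(sprintf("feature_block '%s': %d pairs x %d features (%.1f%% missing)\n",
              x$source, nrow(x$matrix), ncol(x$matrix),
              100 * mean(is.na(x$matrix))))
  invisible(x)
}

#' @export
dim.feature_block <- function(x) dim(x$matrix)

#' Subset a feature block to a set of pairs
#'
#' @param block a `feature_block`.
#' @param ids character vector of pair ids (see [pair_id()]); the result
#'   follows the order of `ids`.
#' @return a `feature_block` restricted to `ids`.
#' @export
subset_block <- function(block, ids) {
  stopifnot(inherits(block, "feature_block"))
  pos <- match(ids, pair_id(block$pairs))
  if (anyNA(pos)) stop("pairs missing from block '", block$source, "': ",
                       paste(utils::head(ids[is.na(pos)], 3), collapse = ", "))
  feature_block(block$pairs[pos, , drop = FALSE],
                block$matrix[pos, , drop = FALSE], block$source)
}

#' Write / read a feature block as TSV
#'
#' The on-disk format is a TSV with header `gene_a`, `gene_b`, then one
#' column per feature; full precision is preserved so write-then-read is an
#' identity. Duplicate pairs or ragged rows are rejected with the
#' offending line number.
#'
#' @param block a `feature_block`.
#' @param path file path.
#' @param source source tag to attach on read (default: from the filename).
#' @return `read_feature_block` returns a `feature_block`;
#'   `write_feature_block` returns `path` invisibly.
#' @export
write_feature_block <- function(block, path) {
  stopifnot(inherits(block, "feature_block"))
  df <- data.frame(gene_a = block$pairs$gene_a, gene_b = block$pairs$gene_b,
                   stringsAsFactors = FALSE)
  mat <- block$matrix
  for (j in seq_len(ncol(mat))) {
    df[[colnames(mat)[j]]] <- sprintf("%.17g", mat[, j])
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_feature_block
#' @export
read_feature_block <- function(path, source = NULL) {
  lines <- readLines(path)
  if (length(lines) == 0) stop("empty file: ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(header) < 2 || header[1] != "gene_a" || header[2] != "gene_b") {
    stop("feature block header must start with gene_a, gene_b")
  }
  ncols <- length(header)
  body <- lapply(seq_along(lines)[-1], function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != ncols) {
      stop("ragged row at line ", i, ": expected ", ncols, " fields, got ",
           length(f))
    }
    f
  })
  if (is.null(source)) {
    source <- sub("\\.[^.]*$", "", basename(path))
  }
  if (length(body) == 0) {
    # header-only file: a legal empty block
    pairs <- structure(data.frame(gene_a = character(), gene_b = character(),
                                  stringsAsFactors = FALSE),
                       class = c("gene_pairs", "data.frame"))
    mat <- matrix(numeric(), nrow = 0, ncol = ncols - 2,
                  dimnames = list(NULL, header[-(1:2)]))
    return(structure(list(pairs = pairs, matrix = mat, source = source),
                     class = "feature_block"))
  }
  tab <- do.call(rbind, body)
  pairs <- gene_pairs(tab[, 1], tab[, 2])
  ids <- pair_id(pairs)
  if (anyDuplicated(ids)) {
    stop("duplicate pair at line ",
         which(duplicated(ids))[1] + 1L, ": ", ids[duplicated(ids)][1])
  }
  vals <- tab[, -(1:2), drop = FALSE]
  mat <- matrix(suppressWarnings(as.numeric(vals)), nrow = nrow(vals),
                dimnames = list(NULL, header[-(1:2)]))
  mat[vals == "NA"] <- NA_real_
  feature_block(pairs, mat, source)
}
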