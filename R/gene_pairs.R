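#' Canonical gene pairs
#'
#' A gene pair is the unit of synthetic-lethality prediction: an unordered
#' pair of distinct gene symbols stored in canonical (lexicographic) order,
#' so that `gene_pairs("BRCA1", "PARP1")` and `gene_pairs("PARP1", "BRCA1")`
#' are the same object. All order-dependent features ("first gene" vs
#' "second gene") are defined relative to this canonical order.
#'
#' @param gene_a,gene_b character vectors of gene symbols (recycled to a
#'   common length). Symbols are opaque identifiers; no alias resolution is
#'   attempted.
#' @return A data frame of class `"gene_pairs"` with columns `gene_a` and
#'   `gene_b`, where `gene_a < gene_b` lexicographically in every row.
#' @examples
#' gene_pairs(c("TP53", "BRCA2"), c("ATM", "BRCA1"))
#' @export
gene_pairs <- function(gene_a, gene_b) {
  gene_a <- as.character(gene_a)
  gene_b <- as.character(gene_b)
  n <- max(length(gene_a), length(gene_b))
  gene_a <- rep_len(gene_a, n)
  gene_b <- rep_len(gene_b, n)
  bad <- is.na(gene_a) | is.na(gene_b) | gene_a == "" | gene_b == ""
  if (any(bad)) {
    stop("malformed gene symbols at rows: ", paste(which(bad), collapse = ", "))
  }
  same <- gene_a == gene_b
  if (any(same)) {
    stop("a gene cannot be paired with itself (rows: ",
         paste(which(same), collapse = ", "), ")")
  }
  # lexicographic canonicalization must not depend on the session locale
  swap <- cmp_gt(gene_a, gene_b)
  tmp <- gene_a[swap]
  gene_a[swap] <- gene_b[swap]
  gene_b[swap] <- tmp
  out <- data.frame(gene_a = gene_a, gene_b = gene_b,
                    stringsAsFactors = FALSE)
  class(out) <- c("gene_pairs", "data.frame")
  out
}

# locale-independent string comparison (C collation)
cmp_gt <- function(a, b) {
  old <- Sys.getlocale("LC_COLLATE")
  on.exit(suppressWarnings(Sys.setlocale("LC_COLLATE", old)), add = TRUE)
  suppressWarnings(Sys.setlocale("LC_COLLATE", "C"))
  a > b
}

#' @export
print.gene_pairs <- function(x, ...) {
  cat(sprintf("%d gene pair%s\n", nrow(x), if (nrow(x) == 1) "" else "s"))
  print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Stable pair identifiers
#'
#' @param pairs a `gene_pairs` object.
#' @return character vector `"<gene_a>|<gene_b>"`, one id per pair.
#' @export
pair_id <- function(pairs) {
  stopifnot(inherits(pairs, "gene_pairs"))
  paste(pairs$gene_a, pairs$gene_b, sep = "|")
}

#' Enumerate candidate gene pairs
#'
#' All unordered pairs of distinct genes from a gene set, in canonical
#' order, minus an optional exclusion set (e.g. pairs already labelled).
#' With 572 genes and no exclusions this yields choose(572, 2) = 163306
#' candidate pairs.
#'
#' @param genes character vector of unique gene symbols (at least 2).
#' @param exclude optional `gene_pairs` of pairs to drop from the output.
#' @return a `gene_pairs` object with `choose(n, 2)` rows minus exclusions.
#' @export
enumerate_candidate_pairs <- function(genes, exclude = NULL) {
  genes <- unique(as.character(genes))
  if (length(genes) < 2) stop("need at least 2 genes to enumerate pairs")
  genes <- sort_c(genes)
  idx <- utils::combn(length(genes), 2)
  out <- gene_pairs(genes[idx[1L, ]], genes[idx[2L, ]])
  if (!is.null(exclude) && nrow(exclude) > 0) {
    stopifnot(inherits(exclude, "gene_pairs"))
    out <- out[!(pair_id(out) %in% pair_id(exclude)), , drop = FALSE]
    rownames(out) <- NULL
    class(out) <- c("gene_pairs", "data.frame")
  }
  out
}

# sort with C collation, independent of session locale
sort_c <- function(x) {
  old <- Sys.getlocale("LC_COLLATE")
  on.exit(suppressWarnings(Sys.setlocale("LC_COLLATE", old)), add = TRUE)
  suppressWarnings(Sys.setlocale("LC_COLLATE", "C"))
  sort(x, method = "radix")
}
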