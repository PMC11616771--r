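#' Synthetic-lethality label tables
#'
#' A label table records experimentally derived SL calls: one row per
#' (pair, source, cancer type) with a binary label (1 = synthetic lethal,
#' 0 = not). `source` identifies the label study the call came from and
#' `cancer` the cancer-type code it applies to.
#'
#' @param gene_a,gene_b gene symbols (canonicalized internally).
#' @param label binary vector (0/1 or logical).
#' @param source character, label-study identifier.
#' @param cancer character, cancer-type code.
#' @return data frame of class `"sl_labels"` with columns `gene_a`,
#'   `gene_b`, `label`, `source`, `cancer`.
#' @export
sl_labels <- function(gene_a, gene_b, label, source = "unknown",
                      cancer = "PAN") {
  pairs <- gene_pairs(gene_a, gene_b)
  label <- as.integer(label)
  if (any(!label %in% c(0L, 1L))) stop("labels must be binary 0/1")
  out <- data.frame(pairs, label = label,
                    source = as.character(source),
                    cancer = as.character(cancer),
                    stringsAsFactors = FALSE)
  key <- paste(pair_id(pairs), out$source, out$cancer)
  if (anyDuplicated(key)) {
    stop("duplicate (pair, source, cancer) records: ",
         paste(utils::head(key[duplicated(key)], 3), collapse = "; "))
  }
  class(out) <- c("sl_labels", "data.frame")
  out
}

#' Harmonize SL labels across studies
#'
#' Takes the union of unique (pair, cancer) labels across label sources and
#' removes every (pair, cancer) whose label disagrees between studies:
#' a pair called SL by one study and non-SL by another within the same
#' cancer type is dropped entirely. Provenance of retained labels is kept
#' (semicolon-joined source list). Harmonization is per cancer type: a pair
#' may legitimately be SL in one cancer and non-SL in another.
#'
#' @param sources a list of `sl_labels` tables.
#' @return one `sl_labels` table with unique (pair, cancer) records and no
#'   within-cancer label conflicts; attribute `"n_conflicts"` counts the
#'   (pair, cancer) keys removed.
#' @export
harmonize_labels <- function(sources) {
  if (!is.list(sources) || length(sources) == 0) {
    stop("need a non-empty list of label tables")
  }
  if (inherits(sources, "sl_labels")) sources <- list(sources)
  for (s in sources) stopifnot(inherits(s, "sl_labels"))
  all_lab <- do.call(rbind, lapply(sources, as.data.frame))
  key <- paste(all_lab$gene_a, all_lab$gene_b, all_lab$cancer, sep = "\r")
  n_lab <- tapply(all_lab$label, key, function(x) length(unique(x)))
  conflicted <- names(n_lab)[n_lab > 1]
  keep <- !(key %in% conflicted)
  all_lab <- all_lab[keep, , drop = FALSE]
  key <- key[keep]
  # collapse duplicates of the (now consistent) records, keeping provenance
  ord <- order(key)
  all_lab <- all_lab[ord, , drop = FALSE]
  key <- key[ord]
  first <- !duplicated(key)
  src <- tapply(all_lab$source, key, function(s)
    paste(sort_c(unique(s)), collapse = ";"))
  out <- all_lab[first, , drop = FALSE]
  out$source <- as.character(src[key[first]])
  rownames(out) <- NULL
  class(out) <- c("sl_labels", "data.frame")
  attr(out, "n_conflicts") <- length(conflicted)
  out
}

#' @export
print.sl_labels <- function(x, ...) {
  cat(sprintf("SL label table: %d records (%d SL, %d non-SL), %d source(s), %d cancer type(s)\n",
              nrow(x), sum(x$label == 1), sum(x$label == 0),
              length(unique(x$source)), length(unique(x$cancer))))
  print.data.frame(utils::head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}
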