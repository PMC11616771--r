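#' Non-silent variant classes used for mutation alteration calls
#' @export
NONSILENT_CLASSES <- c("missense", "nonsense", "frameshift", "splice_site",
                       "nonstop", "inframe_indel")

#' Call binary alterations from an omics bundle
#'
#' An alteration is any of: a non-silent mutation call; an extreme
#' expression z-score (|z| strictly greater than 1.96, the two-sided 95%
#' bound); or a deep copy-number event (discrete GISTIC-style score exactly
#' 2, amplification, or -2, deep loss). The `"any"` channel is the
#' elementwise OR of whichever channels the bundle provides.
#'
#' @param bundle an `omics_bundle`.
#' @param channel one of `"mutation"`, `"expression"`, `"cna"`, `"any"`.
#' @param z_cut z-score cutoff (strict inequality), default 1.96.
#' @param cna_calls copy-number scores counted as altered, default `c(-2, 2)`.
#' @param nonsilent variant classes counted as non-silent.
#' @return binary sample x gene matrix (0/1) over the channel's sample and
#'   gene universe, with attribute `"channel"`.
#' @export
call_alterations <- function(bundle,
                             channel = c("any", "mutation", "expression",
                                         "cna"),
                             z_cut = 1.96, cna_calls = c(-2, 2),
                             nonsilent = NONSILENT_CLASSES) {
  stopifnot(inherits(bundle, "omics_bundle"))
  channel <- match.arg(channel)
  mk_mut <- function() {
    ref <- bundle$expr_z %||% bundle$cna %||% bundle$dependency %||%
      bundle$expr_level
    if (is.null(ref)) {
      samples <- unique(as.character(bundle$mutations$sample))
      genes <- unique(as.character(bundle$mutations$gene))
    } else {
      samples <- rownames(ref); genes <- colnames(ref)
    }
    m <- matrix(0, length(samples), length(genes),
                dimnames = list(samples, genes))
    mu <- bundle$mutations
    if (!is.null(mu) && nrow(mu) > 0) {
      mu <- mu[mu$variant_class %in% nonsilent &
                 mu$sample %in% samples & mu$gene %in% genes, , drop = FALSE]
      if (nrow(mu) > 0) {
        m[cbind(match(mu$sample, samples), match(mu$gene, genes))] <- 1
      }
    }
    m
  }
  out <- switch(channel,
    mutation = {
      if (is.null(bundle$mutations)) stop("bundle has no mutation layer")
      mk_mut()
    },
    expression = {
      if (is.null(bundle$expr_z)) stop("bundle has no expr_z layer")
      (abs(bundle$expr_z) > z_cut) * 1
    },
    cna = {
      if (is.null(bundle$cna)) stop("bundle has no cna layer")
      matrix((bundle$cna %in% cna_calls) * 1, nrow(bundle$cna),
             dimnames = dimnames(bundle$cna))
    },
    any = {
      mats <- list()
      if (!is.null(bundle$mutations)) mats$mutation <- mk_mut()
      if (!is.null(bundle$expr_z)) {
        mats$expression <- (abs(bundle$expr_z) > z_cut) * 1
      }
      if (!is.null(bundle$cna)) {
        mats$cna <- matrix((bundle$cna %in% cna_calls) * 1, nrow(bundle$cna),
                           dimnames = dimnames(bundle$cna))
      }
      if (length(mats) == 0) stop("no alteration channel available")
      samples <- sort_c(unique(unlist(lapply(mats, rownames))))
      genes <- sort_c(unique(unlist(lapply(mats, colnames))))
      acc <- matrix(0, length(samples), length(genes),
                    dimnames = list(samples, genes))
      for (m in mats) {
        acc[rownames(m), colnames(m)] <-
          pmax(acc[rownames(m), colnames(m)], m)
      }
      acc
    })
  out[is.na(out)] <- 0
  attr(out, "channel") <- channel
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# conditional means of score(gene) given partner alteration status:
# (mean score(a) | b unaltered, mean score(a) | b altered,
#  mean score(b) | a unaltered, mean score(b) | a altered)
conditional_pair_means <- function(pairs, score, alt) {
  common <- intersect(rownames(score), rownames(alt))
  score <- score[common, , drop = FALSE]
  alt <- alt[common, , drop = FALSE]
  n <- nrow(pairs)
  out <- matrix(NA_real_, n, 4)
  masked_mean <- function(x, mask) {
    x <- x[mask]
    x <- x[!is.na(x)]
    if (length(x) == 0) NA_real_ else mean(x)
  }
  for (i in seq_len(n)) {
    a <- pairs$gene_a[i]; b <- pairs$gene_b[i]
    if (!(a %in% colnames(score)) || !(b %in% colnames(score)) ||
        !(a %in% colnames(alt)) || !(b %in% colnames(alt))) next
    alt_a <- alt[, a] > 0; alt_b <- alt[, b] > 0
    out[i, 1] <- masked_mean(score[, a], !alt_b)
    out[i, 2] <- masked_mean(score[, a], alt_b)
    out[i, 3] <- masked_mean(score[, b], !alt_a)
    out[i, 4] <- masked_mean(score[, b], alt_a)
  }
  out
}

#' CRISPR dependency features for one gene pair
#'
#' The four-feature summary of a dependency screen conditioned on partner
#' alteration status: average dependency of the first (second) gene across
#' cell lines where the second (first) gene was unaltered, and across cell
#' lines where it was altered. An empty selection (e.g. the partner is
#' never altered) yields a missing value, not zero.
#'
#' @param pair one-row `gene_pairs`.
#' @param dependency sample x gene dependency matrix.
#' @param alt binary sample x gene alteration matrix (see
#'   [call_alterations()]).
#' @return numeric vector of length 4:
#'   `(dep_a|b_unalt, dep_a|b_alt, dep_b|a_unalt, dep_b|a_alt)`.
#' @export
crispr_pair_features <- function(pair, dependency, alt) {
  stopifnot(inherits(pair, "gene_pairs"))
  v <- conditional_pair_means(pair[1, , drop = FALSE], dependency, alt)[1, ]
  names(v) <- c("dep_a_partner_unalt", "dep_a_partner_alt",
                "dep_b_partner_unalt", "dep_b_partner_alt")
  v
}

#' Cell-line feature blocks: CRISPR with mutation / with expression
#'
#' Builds the two cell-line feature sets: conditional dependency means with
#' partner alteration defined by the mutation channel (`crispr_mut`) and by
#' the expression channel (`crispr_expr`). Each block has exactly 4
#' columns. The bundle should already be filtered to the target context
#' (see [filter_context()]).
#'
#' @param pairs a `gene_pairs` object.
#' @param bundle an `omics_bundle` with `dependency` plus mutation and/or
#'   expression layers.
#' @param ... passed to [call_alterations()] (thresholds, variant classes).
#' @return named list of two `feature_block`s: `crispr_mut`, `crispr_expr`.
#' @export
cellline_feature_blocks <- function(pairs, bundle, ...) {
  stopifnot(inherits(bundle, "omics_bundle"))
  if (is.null(bundle$dependency)) stop("bundle has no dependency layer")
  cn <- c("dep_a_partner_unalt", "dep_a_partner_alt",
          "dep_b_partner_unalt", "dep_b_partner_alt")
  mk <- function(channel, tag) {
    alt <- call_alterations(bundle, channel, ...)
    m <- conditional_pair_means(pairs, bundle$dependency, alt)
    colnames(m) <- paste0(tag, "_", cn)
    feature_block(pairs, m, tag)
  }
  list(crispr_mut = mk("mutation", "crispr_mut"),
       crispr_expr = mk("expression", "crispr_expr"))
}
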