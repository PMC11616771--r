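#' Group a patient cohort by co-alteration status of a gene pair
#'
#' A tumour sample is co-altered for a pair when both genes carry an
#' alteration in that sample, where an alteration in any one omics layer
#' (non-silent mutation, extreme expression z-score, deep copy-number
#' event) is sufficient.
#'
#' @param pair one-row `gene_pairs`.
#' @param bundle a tissue `omics_bundle`.
#' @param alt optional precomputed any-channel alteration matrix; computed
#'   from the bundle when omitted.
#' @return named logical vector over cohort samples: `TRUE` = co-altered.
#' @export
comutation_grouping <- function(pair, bundle, alt = NULL) {
  stopifnot(inherits(pair, "gene_pairs"))
  if (is.null(alt)) alt <- call_alterations(bundle, "any")
  a <- pair$gene_a[1]; b <- pair$gene_b[1]
  grp <- stats::setNames(rep(FALSE, nrow(alt)), rownames(alt))
  if (a %in% colnames(alt) && b %in% colnames(alt)) {
    grp[] <- alt[, a] > 0 & alt[, b] > 0
  }
  grp
}

# CoxPH of survival time on a binary group indicator with age/sex/cancer
# covariates; degenerate designs are reduced rather than allowed to fail
cox_group_pvalue <- function(clinical, group, min_group_size = 1) {
  cl <- clinical[!is.na(clinical$time) & !is.na(clinical$event), ,
                 drop = FALSE]
  g <- group[match(as.character(cl$sample), names(group))]
  ok <- !is.na(g)
  cl <- cl[ok, , drop = FALSE]; g <- g[ok]
  n_co <- sum(g)
  if (n_co < min_group_size || n_co == length(g)) {
    return(list(p = NA_real_, hr = NA_real_, fit = NULL, group = g))
  }
  df <- data.frame(time = cl$time, event = cl$event, group = as.integer(g))
  covars <- "group"
  if ("age" %in% names(cl) && length(unique(cl$age[!is.na(cl$age)])) > 1) {
    df$age <- cl$age; covars <- c(covars, "age")
  }
  if ("sex" %in% names(cl) &&
      length(unique(cl$sex[!is.na(cl$sex)])) > 1) {
    df$sex <- factor(cl$sex); covars <- c(covars, "sex")
  }
  if ("cancer" %in% names(cl) &&
      length(unique(cl$cancer[!is.na(cl$cancer)])) > 1) {
    df$cancer <- factor(cl$cancer); covars <- c(covars, "cancer")
  }
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(covars, collapse = " + ")))
  fit <- tryCatch(
    suppressWarnings(survival::coxph(fml, data = df, ties = "efron")),
    error = function(e) NULL)
  if (is.null(fit) || !"group" %in% names(stats::coef(fit)) ||
      !is.finite(stats::coef(fit)[["group"]])) {
    return(list(p = NA_real_, hr = NA_real_, fit = NULL, group = g))
  }
  sm <- summary(fit)
  p <- sm$coefficients["group", "Pr(>|z|)"]
  hr <- sm$coefficients["group", "exp(coef)"]
  list(p = unname(p), hr = unname(hr), fit = fit, group = g)
}

#' Co-mutation survival feature for a gene pair
#'
#' The Wald p-value of the co-alteration group coefficient in a Cox
#' proportional-hazards model of survival time, with covariates for age,
#' sex and cancer type (each included only when it varies in the cohort;
#' ties handled by the Efron approximation). Cohorts where the co-altered
#' group is empty, too small, or where the fit is degenerate yield a
#' missing value.
#'
#' @param pair one-row `gene_pairs`.
#' @param bundle a tissue `omics_bundle` with a clinical table.
#' @param min_group_size minimum co-altered group size for a reported fit.
#' @param alt optional precomputed any-channel alteration matrix.
#' @return Wald p-value (scalar) or `NA`.
#' @export
survival_feature <- function(pair, bundle, min_group_size = 1, alt = NULL) {
  if (is.null(bundle$clinical)) return(NA_real_)
  grp <- comutation_grouping(pair, bundle, alt = alt)
  cox_group_pvalue(bundle$clinical, grp, min_group_size)$p
}

#' Conditional average expression features for a gene pair
#'
#' Average expression level (log2(x+1)-transformed) of the first (second)
#' gene in tumour samples where the second (first) gene was unaltered or
#' altered — four features, with any-channel alterations and the same
#' empty-selection-is-missing contract as the CRISPR features.
#'
#' @param pair one-row `gene_pairs`.
#' @param bundle a tissue `omics_bundle` with `expr_level`.
#' @param alt optional precomputed any-channel alteration matrix.
#' @param log2p1 log-transform expression levels before averaging.
#' @return numeric vector of length 4.
#' @export
avg_expression_features <- function(pair, bundle, alt = NULL, log2p1 = TRUE) {
  stopifnot(inherits(pair, "gene_pairs"))
  if (is.null(bundle$expr_level)) {
    return(stats::setNames(rep(NA_real_, 4),
                           c("expr_a_partner_unalt", "expr_a_partner_alt",
                             "expr_b_partner_unalt", "expr_b_partner_alt")))
  }
  if (is.null(alt)) alt <- call_alterations(bundle, "any")
  expr <- bundle$expr_level
  if (log2p1) expr <- log2(expr + 1)
  v <- conditional_pair_means(pair[1, , drop = FALSE], expr, alt)[1, ]
  names(v) <- c("expr_a_partner_unalt", "expr_a_partner_alt",
                "expr_b_partner_unalt", "expr_b_partner_alt")
  v
}

# correlation of two gene columns of a matrix; missing when undefined
.gene_cor <- function(m, a, b, method, log2p1 = FALSE, min_n = 3) {
  if (is.null(m) || !(a %in% colnames(m)) || !(b %in% colnames(m))) {
    return(c(NA_real_, NA_real_))
  }
  x <- m[, a]; y <- m[, b]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < min_n || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(c(NA_real_, NA_real_))
  }
  if (log2p1) { x <- log2(x + 1); y <- log2(y + 1) }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = method, alternative = "two.sided",
                    exact = FALSE))
  c(unname(ct$estimate), ct$p.value)
}

#' Coexpression features for a gene pair
#'
#' Pearson correlation and two-sided p-value between the (log2(x+1))
#' expression levels of the two genes, in three sample compartments:
#' tumour, matched normal tissue, healthy donor tissue — six features in
#' that order. A compartment with fewer than 3 usable samples or a
#' constant expression vector yields missing values.
#'
#' @param pair one-row `gene_pairs`.
#' @param bundle a tissue `omics_bundle` (`expr_level`, `expr_normal`,
#'   `expr_healthy`).
#' @return numeric vector of length 6: `(r, p)` for tumour, normal,
#'   healthy.
#' @export
coexpression_features <- function(pair, bundle) {
  stopifnot(inherits(pair, "gene_pairs"))
  a <- pair$gene_a[1]; b <- pair$gene_b[1]
  v <- c(.gene_cor(bundle$expr_level, a, b, "pearson", log2p1 = TRUE),
         .gene_cor(bundle$expr_normal, a, b, "pearson", log2p1 = TRUE),
         .gene_cor(bundle$expr_healthy, a, b, "pearson", log2p1 = TRUE))
  names(v) <- c("coexpr_tumour_r", "coexpr_tumour_p",
                "coexpr_normal_r", "coexpr_normal_p",
                "coexpr_healthy_r", "coexpr_healthy_p")
  v
}

#' Copy-number correlation features for a gene pair
#'
#' Spearman rank correlation and two-sided p-value of the discrete
#' copy-number scores of the two genes across tumour samples.
#'
#' @param pair one-row `gene_pairs`.
#' @param bundle a tissue `omics_bundle` with `cna`.
#' @return numeric vector of length 2: `(rho, p)`.
#' @export
cna_correlation_features <- function(pair, bundle) {
  stopifnot(inherits(pair, "gene_pairs"))
  v <- .gene_cor(bundle$cna, pair$gene_a[1], pair$gene_b[1], "spearman")
  names(v) <- c("cna_rho", "cna_p")
  v
}

#' Tissue feature block (13 features per pair)
#'
#' Assembles the tissue source: co-mutation survival p-value (1), average
#' conditional expression (4), coexpression r/p in tumour, normal and
#' healthy compartments (6), and copy-number Spearman rho/p (2). Column
#' order is fixed: `survival_p`, the four `expr_*`, the six `coexpr_*`,
#' `cna_rho`, `cna_p`.
#'
#' @param pairs a `gene_pairs` object.
#' @param bundle a tissue `omics_bundle`, already context-filtered.
#' @param min_group_size minimum co-altered group size for the survival
#'   feature.
#' @return a `feature_block` of dimension N x 13 with source `"tissue"`.
#' @export
tissue_feature_block <- function(pairs, bundle, min_group_size = 1) {
  stopifnot(inherits(pairs, "gene_pairs"), inherits(bundle, "omics_bundle"))
  alt <- tryCatch(call_alterations(bundle, "any"), error = function(e) NULL)
  n <- nrow(pairs)
  m <- matrix(NA_real_, n, 13)
  for (i in seq_len(n)) {
    p1 <- pairs[i, , drop = FALSE]
    class(p1) <- c("gene_pairs", "data.frame")
    sp <- if (is.null(alt)) NA_real_ else
      survival_feature(p1, bundle, min_group_size, alt = alt)
    ae <- if (is.null(alt))
      rep(NA_real_, 4) else avg_expression_features(p1, bundle, alt = alt)
    m[i, ] <- c(sp, ae, coexpression_features(p1, bundle),
                cna_correlation_features(p1, bundle))
  }
  colnames(m) <- c("survival_p",
                   "expr_a_partner_unalt", "expr_a_partner_alt",
                   "expr_b_partner_unalt", "expr_b_partner_alt",
                   "coexpr_tumour_r", "coexpr_tumour_p",
                   "coexpr_normal_r", "coexpr_normal_p",
                   "coexpr_healthy_r", "coexpr_healthy_p",
                   "cna_rho", "cna_p")
  feature_block(pairs, m, "tissue")
}

#' Gene-family co-mutation survival analysis
#'
#' Stratifies a patient cohort by family-level co-mutation status: a
#' sample is in the co-altered group when at least one member of each of
#' two gene families carries an alteration. Fits the covariate-adjusted
#' CoxPH model for the group variable and estimates Kaplan-Meier survival
#' curves for the co-altered group, its complement, and the two subgroups
#' of the complement (altered in exactly one family; unaltered in both).
#' With singleton families this reduces exactly to the pairwise grouping.
#'
#' @param family_a,family_b non-empty character vectors of gene symbols.
#' @param bundle a tissue `omics_bundle` with a clinical table.
#' @param min_group_size minimum co-altered group size for a reported
#'   p-value (curves are emitted regardless).
#' @return list of class `"family_survival"`: `p` (Wald p for the group
#'   variable), `hr` (hazard ratio), `groups` (factor per sample:
#'   `both`, `one_family`, `unaltered`), `group_sizes`, `median_survival`
#'   (per group), `km` (data frame of KM step functions: group, time,
#'   surv, n.risk), `fit` (the coxph fit or NULL).
#' @export
family_comutation_survival <- function(family_a, family_b, bundle,
                                       min_group_size = 1) {
  if (length(family_a) == 0 || length(family_b) == 0) {
    stop("gene families must be non-empty")
  }
  if (is.null(bundle$clinical)) stop("bundle has no clinical table")
  alt <- call_alterations(bundle, "any")
  any_alt <- function(fam) {
    fam <- intersect(fam, colnames(alt))
    if (length(fam) == 0) {
      return(stats::setNames(rep(FALSE, nrow(alt)), rownames(alt)))
    }
    rowSums(alt[, fam, drop = FALSE]) > 0
  }
  alt_a <- any_alt(family_a); alt_b <- any_alt(family_b)
  co <- alt_a & alt_b
  one <- (alt_a | alt_b) & !co
  groups <- factor(ifelse(co, "both", ifelse(one, "one_family", "unaltered")),
                   levels = c("both", "one_family", "unaltered"))
  names(groups) <- rownames(alt)
  res <- cox_group_pvalue(bundle$clinical, co, min_group_size)
  cl <- bundle$clinical
  g3 <- groups[match(as.character(cl$sample), names(groups))]
  # coarse two-group view for reporting alongside the subgroups
  g2 <- factor(ifelse(g3 == "both", "both", "not_both"),
               levels = c("both", "not_both"))
  km_df <- NULL
  med <- c()
  for (lev in list(c("both", "not_both"), levels(g3))) {
    g <- if (length(lev) == 2) g2 else g3
    for (l in lev) {
      idx <- !is.na(g) & g == l
      if (!any(idx)) next
      sf <- survival::survfit(
        survival::Surv(cl$time[idx], cl$event[idx]) ~ 1)
      km_df <- rbind(km_df, data.frame(
        group = l, time = sf$time, surv = sf$surv, n_risk = sf$n.risk,
        stringsAsFactors = FALSE))
      med[l] <- unname(summary(sf)$table["median"])
    }
  }
  structure(list(p = res$p, hr = res$hr, groups = groups,
                 group_sizes = table(g3),
                 median_survival = med, km = km_df, fit = res$fit),
            class = "family_survival")
}

#' @export
print.family_survival <- function(x, ...) {
  cat("Family co-mutation survival analysis\n")
  cat("  group sizes:",
      paste(names(x$group_sizes), as.integer(x$group_sizes), sep = "=",
            collapse = ", "), "\n")
  cat(sprintf("  CoxPH group HR = %.3f, Wald p = %.4g\n", x$hr, x$p))
  meds <- x$median_survival
  cat("  median survival:",
      paste(names(meds), signif(meds, 3), sep = "=", collapse = ", "), "\n")
  invisible(x)
}
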