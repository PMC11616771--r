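#' Configuration of a synthetic multi-omics world
#'
#' The generator emulates every input the SL prediction pipeline consumes
#' — protein sequences, a PPI network, a cell-line screen (dependency,
#' expression, mutation, copy number) and a patient tissue cohort
#' (expression in tumour/normal/healthy compartments, mutation, copy
#' number, clinical follow-up) — with planted SL signal of configurable
#' effect size in each channel:
#' sequences of SL partners share a common motif; SL partners sit in a
#' common PPI neighbourhood; the dependency score of a gene drops by
#' `delta` in cell lines where its SL partner is altered; tumour
#' expression of SL partners is correlated at `r_target`; and the hazard
#' of co-altered patients is multiplied by `hazard_ratio`.
#'
#' @param n_genes,n_cell_lines,n_patients universe sizes.
#' @param n_sl_pairs,n_nonsl_pairs planted positive / negative pairs
#'   (disjoint pair sets).
#' @param delta dependency shift (score units) for an SL gene in lines
#'   where its partner is altered.
#' @param r_target Pearson correlation of SL partners' log-expression in
#'   tumour samples (also used as the copy-number coupling probability).
#' @param hazard_ratio multiplicative hazard for patients co-altered in at
#'   least one SL pair (< 1 = protective, > 1 = deleterious).
#' @param alteration_rate per-sample per-gene mutation probability.
#' @param noise_sd standard deviation of dependency noise.
#' @param seq_length,motif_length amino-acid sequence and shared-motif
#'   lengths.
#' @param d_seq,d_ppi embedding dimensions for the sequence and PPI
#'   sources.
#' @param cancer_types cancer-type code(s) assigned to patients.
#' @return list of class `"synthetic_world_config"`.
#' @export
synthetic_world_config <- function(n_genes = 100L, n_cell_lines = 200L,
                                   n_patients = 400L, n_sl_pairs = 50L,
                                   n_nonsl_pairs = 50L, delta = 1.0,
                                   r_target = 0.6, hazard_ratio = 0.5,
                                   alteration_rate = 0.2, noise_sd = 0.2,
                                   seq_length = 120L, motif_length = 12L,
                                   d_seq = 1024L, d_ppi = 64L,
                                   cancer_types = "BRCA") {
  cfg <- list(n_genes = as.integer(n_genes),
              n_cell_lines = as.integer(n_cell_lines),
              n_patients = as.integer(n_patients),
              n_sl_pairs = as.integer(n_sl_pairs),
              n_nonsl_pairs = as.integer(n_nonsl_pairs),
              delta = delta, r_target = r_target,
              hazard_ratio = hazard_ratio,
              alteration_rate = alteration_rate, noise_sd = noise_sd,
              seq_length = as.integer(seq_length),
              motif_length = as.integer(motif_length),
              d_seq = as.integer(d_seq), d_ppi = as.integer(d_ppi),
              cancer_types = as.character(cancer_types))
  stopifnot(cfg$n_genes >= 4, cfg$n_cell_lines >= 1, cfg$n_patients >= 1,
            cfg$n_sl_pairs >= 1, cfg$n_nonsl_pairs >= 1,
            cfg$alteration_rate > 0, cfg$alteration_rate < 1,
            cfg$hazard_ratio > 0, cfg$r_target >= 0, cfg$r_target < 1)
  if (cfg$n_sl_pairs + cfg$n_nonsl_pairs > choose(cfg$n_genes, 2)) {
    stop("more planted pairs than available gene pairs")
  }
  class(cfg) <- "synthetic_world_config"
  cfg
}

AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Generate a synthetic multi-omics world
#'
#' See [synthetic_world_config()] for the planted-effect model. The same
#' seed always reproduces the world bit for bit.
#'
#' @param config a `synthetic_world_config`.
#' @param seed integer seed.
#' @return list of class `"synthetic_world"`: `genes`, `sequences`,
#'   `ppi_edges`, `cellline` (an `omics_bundle`), `tissue` (an
#'   `omics_bundle` with clinical and normal/healthy compartments),
#'   `labels` (the planted truth as an `sl_labels` table), `config`,
#'   `seed`.
#' @export
generate_world <- function(config, seed = 1L) {
  stopifnot(inherits(config, "synthetic_world_config"))
  cfg <- config
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(seed)

  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  n_pairs <- cfg$n_sl_pairs + cfg$n_nonsl_pairs
  all_idx <- utils::combn(cfg$n_genes, 2)
  pick <- sample(ncol(all_idx), n_pairs)
  sl_idx <- all_idx[, pick[seq_len(cfg$n_sl_pairs)], drop = FALSE]
  nsl_idx <- all_idx[, pick[-seq_len(cfg$n_sl_pairs)], drop = FALSE]
  sl_pairs <- gene_pairs(genes[sl_idx[1, ]], genes[sl_idx[2, ]])
  nonsl_pairs <- gene_pairs(genes[nsl_idx[1, ]], genes[nsl_idx[2, ]])

  # --- sequences: random AA strings; SL partners share a planted motif
  sequences <- vapply(genes, function(g)
    paste(sample(AA_ALPHABET, cfg$seq_length, replace = TRUE),
          collapse = ""), character(1))
  if (cfg$motif_length > 0) {
    for (i in seq_len(nrow(sl_pairs))) {
      motif <- paste(sample(AA_ALPHABET, cfg$motif_length, replace = TRUE),
                     collapse = "")
      for (g in c(sl_pairs$gene_a[i], sl_pairs$gene_b[i])) {
        pos <- sample.int(cfg$seq_length - cfg$motif_length + 1L, 1L)
        substr(sequences[[g]], pos, pos + cfg$motif_length - 1L) <- motif
      }
    }
  }

  # --- PPI: sparse background + a shared neighbourhood per SL pair
  n_bg <- 2L * cfg$n_genes
  bg <- matrix(genes[sample.int(cfg$n_genes, 2L * n_bg, replace = TRUE)],
               ncol = 2)
  bg <- bg[bg[, 1] != bg[, 2], , drop = FALSE]
  ev <- sample(c("experimental", "curated", "textmining"), nrow(bg),
               replace = TRUE, prob = c(0.5, 0.3, 0.2))
  edges <- data.frame(gene1 = bg[, 1], gene2 = bg[, 2],
                      evidence_class = ev, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(sl_pairs))) {
    nb <- sample(setdiff(genes, c(sl_pairs$gene_a[i], sl_pairs$gene_b[i])),
                 3L)
    edges <- rbind(edges, data.frame(
      gene1 = rep(c(sl_pairs$gene_a[i], sl_pairs$gene_b[i]), each = 3L),
      gene2 = rep(nb, 2L), evidence_class = "experimental",
      stringsAsFactors = FALSE))
  }

  # --- helper: mutation calls + expression z + discrete CNA for a cohort
  gen_alteration_layers <- function(samples) {
    n <- length(samples)
    mut_mask <- matrix(stats::runif(n * cfg$n_genes) < cfg$alteration_rate,
                       n, cfg$n_genes, dimnames = list(samples, genes))
    hits <- which(mut_mask, arr.ind = TRUE)
    classes <- sample(c(NONSILENT_CLASSES, "silent"), nrow(hits),
                      replace = TRUE,
                      prob = c(rep(0.9 / length(NONSILENT_CLASSES),
                                   length(NONSILENT_CLASSES)), 0.1))
    mutations <- data.frame(sample = samples[hits[, 1]],
                            gene = genes[hits[, 2]],
                            variant_class = classes,
                            stringsAsFactors = FALSE)
    expr_z <- matrix(stats::rnorm(n * cfg$n_genes), n, cfg$n_genes,
                     dimnames = list(samples, genes))
    cna <- matrix(sample(c(-2L, -1L, 0L, 1L, 2L), n * cfg$n_genes,
                         replace = TRUE,
                         prob = c(0.05, 0.1, 0.7, 0.1, 0.05)),
                  n, cfg$n_genes, dimnames = list(samples, genes))
    list(mutations = mutations, expr_z = expr_z, cna = cna)
  }

  # --- cell lines: dependency drops by delta under partner alteration
  cl_samples <- sprintf("CL%04d", seq_len(cfg$n_cell_lines))
  cl <- gen_alteration_layers(cl_samples)
  cl_bundle0 <- omics_bundle(expr_z = cl$expr_z, mutations = cl$mutations,
                             cna = cl$cna)
  cl_alt <- call_alterations(cl_bundle0, "any")
  dependency <- matrix(stats::rnorm(cfg$n_cell_lines * cfg$n_genes,
                                    sd = cfg$noise_sd),
                       cfg$n_cell_lines, cfg$n_genes,
                       dimnames = list(cl_samples, genes))
  for (i in seq_len(nrow(sl_pairs))) {
    a <- sl_pairs$gene_a[i]; b <- sl_pairs$gene_b[i]
    dependency[cl_alt[, b] > 0, a] <- dependency[cl_alt[, b] > 0, a] -
      cfg$delta
    dependency[cl_alt[, a] > 0, b] <- dependency[cl_alt[, a] > 0, b] -
      cfg$delta
  }
  cellline <- omics_bundle(dependency = dependency, expr_z = cl$expr_z,
                           mutations = cl$mutations, cna = cl$cna,
                           sample_context = stats::setNames(
                             rep(cfg$cancer_types[1], cfg$n_cell_lines),
                             cl_samples))

  # --- tissue: correlated tumour expression, coupled CNA, survival
  pt_samples <- sprintf("PT%04d", seq_len(cfg$n_patients))
  ti <- gen_alteration_layers(pt_samples)
  latent <- matrix(stats::rnorm(cfg$n_patients * cfg$n_genes),
                   cfg$n_patients, cfg$n_genes,
                   dimnames = list(pt_samples, genes))
  # correlation can be planted only for pairs whose genes are not already
  # claimed by an earlier pair; the world records which pairs carry it
  assigned <- character(0)
  r_planted <- rep(FALSE, nrow(sl_pairs))
  if (cfg$r_target > 0) {
    for (i in seq_len(nrow(sl_pairs))) {
      a <- sl_pairs$gene_a[i]; b <- sl_pairs$gene_b[i]
      if (a %in% assigned || b %in% assigned) next
      z <- stats::rnorm(cfg$n_patients)
      r <- cfg$r_target
      latent[, a] <- sqrt(r) * z + sqrt(1 - r) * stats::rnorm(cfg$n_patients)
      latent[, b] <- sqrt(r) * z + sqrt(1 - r) * stats::rnorm(cfg$n_patients)
      assigned <- c(assigned, a, b)
      r_planted[i] <- TRUE
      # couple partner copy-number calls at the same strength
      copy <- stats::runif(cfg$n_patients) < r
      ti$cna[copy, b] <- ti$cna[copy, a]
    }
  }
  expr_level <- 2^(8 + latent)   # RSEM-like positive levels
  n_ref <- max(4L, cfg$n_patients %/% 4L)
  nm_samples <- sprintf("NM%04d", seq_len(n_ref))
  hd_samples <- sprintf("HD%04d", seq_len(n_ref))
  expr_normal <- 2^(8 + matrix(stats::rnorm(n_ref * cfg$n_genes), n_ref,
                               cfg$n_genes,
                               dimnames = list(nm_samples, genes)))
  expr_healthy <- 2^(8 + matrix(stats::rnorm(n_ref * cfg$n_genes), n_ref,
                                cfg$n_genes,
                                dimnames = list(hd_samples, genes)))
  ti_bundle0 <- omics_bundle(expr_z = ti$expr_z, mutations = ti$mutations,
                             cna = ti$cna)
  ti_alt <- call_alterations(ti_bundle0, "any")
  # hazard acts multiplicatively per co-altered SL pair, so each pair's
  # co-alteration contrast carries the planted ratio even when a patient
  # is co-altered in several pairs
  co_count <- rep(0L, cfg$n_patients)
  for (i in seq_len(nrow(sl_pairs))) {
    co_count <- co_count + (ti_alt[, sl_pairs$gene_a[i]] > 0 &
                              ti_alt[, sl_pairs$gene_b[i]] > 0)
  }
  base_rate <- 1 / 24           # months^-1: median ~17 months untreated
  rate <- base_rate * cfg$hazard_ratio^co_count
  t_event <- stats::rexp(cfg$n_patients, rate)
  censor <- stats::runif(cfg$n_patients, 12, 60)
  clinical <- data.frame(
    sample = pt_samples,
    time = pmin(t_event, censor),
    event = as.integer(t_event <= censor),
    age = round(stats::rnorm(cfg$n_patients, 62, 11)),
    sex = sample(c("F", "M"), cfg$n_patients, replace = TRUE),
    cancer = sample(cfg$cancer_types, cfg$n_patients, replace = TRUE),
    stringsAsFactors = FALSE)
  tissue <- omics_bundle(expr_z = ti$expr_z, expr_level = expr_level,
                         mutations = ti$mutations, cna = ti$cna,
                         clinical = clinical,
                         expr_normal = expr_normal,
                         expr_healthy = expr_healthy)

  labels <- sl_labels(c(sl_pairs$gene_a, nonsl_pairs$gene_a),
                      c(sl_pairs$gene_b, nonsl_pairs$gene_b),
                      c(rep(1L, nrow(sl_pairs)), rep(0L, nrow(nonsl_pairs))),
                      source = "synthetic", cancer = cfg$cancer_types[1])

  structure(list(genes = genes, sequences = sequences, ppi_edges = edges,
                 cellline = cellline, tissue = tissue, labels = labels,
                 sl_pairs = sl_pairs, nonsl_pairs = nonsl_pairs,
                 r_planted = r_planted, config = cfg, seed = seed),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("synthetic world (seed %d): %d genes, %d cell lines, %d patients\n",
              x$seed, cfg$n_genes, cfg$n_cell_lines, cfg$n_patients))
  cat(sprintf("  planted: %d SL + %d non-SL pairs; delta=%.2f r=%.2f HR=%.2f\n",
              cfg$n_sl_pairs, cfg$n_nonsl_pairs, cfg$delta, cfg$r_target,
              cfg$hazard_ratio))
  invisible(x)
}

#' Featurize a synthetic world into the five source blocks
#'
#' Computes the standard k = 5 feature sources for the world's labelled
#' pairs: sequence-embedding absolute differences (`seq`), PPI-embedding
#' absolute differences (`ppi`), the two conditional CRISPR dependency
#' sets (`crispr_mut`, `crispr_expr`), and the 13 tissue features
#' (`tissue`).
#'
#' @param world a `synthetic_world`.
#' @param pairs `gene_pairs` to featurize (default: the labelled pairs).
#' @param seed seed for the PPI walk embedding (default: the world's).
#' @return named list of five `feature_block`s.
#' @export
featurize_world <- function(world, pairs = NULL, seed = NULL) {
  stopifnot(inherits(world, "synthetic_world"))
  cfg <- world$config
  if (is.null(seed)) seed <- world$seed
  if (is.null(pairs)) {
    pairs <- gene_pairs(world$labels$gene_a, world$labels$gene_b)
  }
  emb_seq <- embed_sequences(world$sequences, hash_embedder(d = cfg$d_seq))
  g <- build_ppi_graph(world$ppi_edges)
  emb_ppi <- embed_ppi_nodes(g, d = cfg$d_ppi, seed = seed)
  blocks <- list(
    seq = pair_absdiff_block(pairs, emb_seq, "seq"),
    ppi = suppressMessages(pair_absdiff_block(pairs, emb_ppi, "ppi")))
  blocks <- c(blocks, cellline_feature_blocks(pairs, world$cellline))
  blocks$tissue <- tissue_feature_block(pairs, world$tissue)
  blocks
}

#' Check that planted effects are recovered by their natural estimators
#'
#' Estimates each planted parameter from the generated world — the
#' dependency shift delta (difference of conditional dependency means over
#' SL pairs), the tumour coexpression r (mean Pearson correlation over SL
#' pairs), and the co-alteration hazard ratio (CoxPH estimate) — and flags
#' any estimate more than 3 standard errors from its configured value.
#'
#' @param world a `synthetic_world`.
#' @param config its configuration (defaults to `world$config`).
#' @return data frame with columns `parameter`, `target`, `estimate`,
#'   `se`, `flag`.
#' @export
verify_planted_effects <- function(world, config = world$config) {
  sl <- world$sl_pairs
  # delta: planted as a drop, estimated as unaltered-minus-altered mean
  alt <- call_alterations(world$cellline, "any")
  cm <- conditional_pair_means(sl, world$cellline$dependency, alt)
  d_hat <- c(cm[, 1] - cm[, 2], cm[, 3] - cm[, 4])
  d_hat <- d_hat[!is.na(d_hat)]
  # r: tumour log-expression correlation over the pairs that carry the
  # planted correlation (genes shared between SL pairs can host only one)
  le <- log2(world$tissue$expr_level + 1)
  rp <- world$r_planted %||% rep(TRUE, nrow(sl))
  r_idx <- if (any(rp)) which(rp) else seq_len(nrow(sl))
  r_hat <- vapply(r_idx, function(i)
    stats::cor(le[, sl$gene_a[i]], le[, sl$gene_b[i]]), numeric(1))
  # hazard ratio: CoxPH on the co-alteration count across SL pairs
  ti_alt <- call_alterations(world$tissue, "any")
  co_count <- rep(0, nrow(ti_alt))
  for (i in seq_len(nrow(sl))) {
    co_count <- co_count + (ti_alt[, sl$gene_a[i]] > 0 &
                              ti_alt[, sl$gene_b[i]] > 0)
  }
  cl <- world$tissue$clinical
  cnt <- co_count[match(as.character(cl$sample), rownames(ti_alt))]
  hr <- h_se <- NA_real_
  if (stats::sd(cnt) > 0) {
    fit <- survival::coxph(survival::Surv(cl$time, cl$event) ~ cnt,
                           ties = "efron")
    hr <- unname(exp(stats::coef(fit)[["cnt"]]))
    h_se <- sqrt(diag(stats::vcov(fit))[["cnt"]]) * hr  # delta method
  }
  out <- data.frame(
    parameter = c("delta", "r_target", "hazard_ratio"),
    target = c(config$delta, config$r_target, config$hazard_ratio),
    estimate = c(mean(d_hat), mean(r_hat), hr),
    se = c(stats::sd(d_hat) / sqrt(length(d_hat)),
           stats::sd(r_hat) / sqrt(length(r_hat)), h_se),
    stringsAsFactors = FALSE)
  out$flag <- !is.na(out$se) & abs(out$estimate - out$target) > 3 * out$se
  out
}

#' Write / read a synthetic world in the standard on-disk formats
#'
#' `write_world` materializes every table in the formats the readers
#' consume — FASTA for sequences, TSV matrices, edge lists and label
#' tables — plus `truth.tsv` with the planted SL/non-SL pairs.
#'
#' @param world a `synthetic_world`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(dir, ...)
  write_protein_fasta(world$sequences, fp("sequences.fasta"))
  utils::write.table(world$ppi_edges, fp("ppi_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_omics_matrix(world$cellline$dependency, fp("cellline_dependency.tsv"))
  write_omics_matrix(world$cellline$expr_z, fp("cellline_expr_z.tsv"))
  write_omics_matrix(world$cellline$cna, fp("cellline_cna.tsv"))
  utils::write.table(world$cellline$mutations, fp("cellline_mutations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_omics_matrix(world$tissue$expr_z, fp("tissue_expr_z.tsv"))
  write_omics_matrix(world$tissue$expr_level, fp("tissue_expr_level.tsv"))
  write_omics_matrix(world$tissue$cna, fp("tissue_cna.tsv"))
  write_omics_matrix(world$tissue$expr_normal, fp("tissue_expr_normal.tsv"))
  write_omics_matrix(world$tissue$expr_healthy, fp("tissue_expr_healthy.tsv"))
  utils::write.table(world$tissue$mutations, fp("tissue_mutations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(world$tissue$clinical, fp("tissue_clinical.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_sl_labels(world$labels, fp("labels.tsv"))
  truth <- data.frame(
    gene1 = c(world$sl_pairs$gene_a, world$nonsl_pairs$gene_a),
    gene2 = c(world$sl_pairs$gene_b, world$nonsl_pairs$gene_b),
    planted = c(rep("SL", nrow(world$sl_pairs)),
                rep("non-SL", nrow(world$nonsl_pairs))))
  utils::write.table(truth, fp("truth.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(dir)
}
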