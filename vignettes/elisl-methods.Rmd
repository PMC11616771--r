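---
title: "Methods: early–late integrated SL prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: early–late integrated SL prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its statistical machinery: the
integration model, the featurization of gene pairs, the evaluation
protocols, the synthetic-data generator, and the numerical and design
choices behind each. Nothing here reports an empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## The prediction problem

The unit of prediction is an unordered pair of genes, stored canonically
with the lexicographically smaller symbol first. All "first gene / second
gene" features are defined relative to this canonical order, which makes
feature vectors well-defined and invariant under swapping the input order
of a pair. Labels are binary (SL / non-SL), carried with label-study and
cancer-type provenance; harmonization removes any (pair, cancer) whose
label disagrees across studies and is performed **per cancer type** — a
pair may legitimately be SL in one tissue context and not in another.
Pooling across cancers while a pair carries different labels in two
cancers is ambiguous territory; we keep the per-cancer records and leave
any pooling policy to the caller.

## Feature sources

**Sequence (1024 per pair).** Any deterministic embedder mapping an
amino-acid string to a fixed-length vector can be plugged in, and
precomputed per-gene embedding tables (e.g. from a protein language
model) can be imported from TSV and used directly; how a language model's
per-residue, per-layer outputs are pooled to one vector is left to the
table producer rather than fixed here. The built-in `hash_embedder()`
hashes overlapping k-mers (k = 3) into signed positions of a d-dimensional
vector and normalizes; it carries genuine sequence-similarity signal
(shared subsequences land in shared positions) at negligible cost, which
is all the framework itself needs. The pair feature is the elementwise
absolute difference of the two genes' vectors — symmetric, non-negative,
and zero exactly where the embeddings agree.

**PPI (64 per pair).** Edges are kept only when their evidence class is
curated or experimental; self-loops and duplicate/reciprocal records are
collapsed into a simple undirected graph. Node embeddings use unbiased
truncated random walks (10 walks per node, length 80, the canonical
defaults of walk-based node embedding with unit bias p = q = 1), window-10
co-occurrence counts, and truncated SVD of the positive pointwise mutual
information (PPMI) matrix to d = 64. PPMI + SVD is the classical matrix
factorization that skip-gram walk embeddings implicitly perform; it is
deterministic given the walk sample, and the SVD sign ambiguity is fixed
by orienting each singular vector so its largest-magnitude entry is
positive, making output bit-reproducible under a fixed seed. The dense
co-occurrence matrix limits this implementation to graphs of a few
thousand nodes, which covers the package's simulation scale. Genes absent
from the graph get zero vectors; pairs with a gene absent from an
embedding table get missing features, imputed at fit time, so N stays
constant across sources.

**Cell line (4 + 4 per pair).** An alteration is a non-silent mutation
(default classes: missense, nonsense, frameshift, splice site, nonstop,
in-frame indel — configurable, since "non-silent" is a convention), an
expression z-score with |z| **strictly** greater than 1.96 (the two-sided
95% bound; strict comparison is the literal reading of "larger than" and
is documented so it is auditable), or a discrete copy-number score of
exactly ±2 (deep events only). The two CRISPR feature sets are the four
conditional means of the dependency score of each gene given its
partner's alteration status, once with mutation-channel alterations and
once with expression-channel alterations. An empty conditioning set
yields a missing value, never zero: zero is a meaningful dependency score
and conflating the two would bias the features.

**Tissue (13 per pair).** Co-alteration uses the any-channel rule: a
sample is co-altered when both genes carry an alteration in *any* omics
layer. The survival feature is the Wald p-value of the co-alteration
group coefficient in a Cox proportional-hazards model with age, sex and
cancer-type covariates; each covariate is included only when it varies in
the cohort (single-sex or single-cancer cohorts would otherwise give
singular designs), and ties use the Efron approximation. Expression
levels are transformed log2(x + 1) before averaging and correlation — the
standard variance-stabilizing choice; z-scores are used only for
alteration calling. Coexpression is Pearson r with two-sided p in three
compartments (tumour, matched normal, healthy donor); copy-number
association is Spearman's ρ on the discrete scores. Correlations need at
least 3 usable samples and non-constant vectors, else missing. The
column order of the 13-feature block is fixed and documented.

The family-level survival analysis generalizes the pairwise grouping to
gene families (co-altered = at least one altered member in each family),
reports the same covariate-adjusted CoxPH Wald p, and emits Kaplan–Meier
step functions for the co-altered group, its complement, and the
complement's two subgroups (altered in exactly one family; fully
unaltered). `min_group_size` (default 1 here; raise to ~5 for sparse
cohorts) suppresses p-values from vanishingly small co-altered groups
while still emitting curves.

## The integration ensemble

Given k source blocks over the same pair list, the model fits k + 1 tree
ensembles: one per source and one on the column-concatenation (early
integration). One shared hyperparameter configuration is used for all
k + 1 submodels per trial — shared tuning is part of the integration
design, not a shortcut. The default grid is trees {100, 200, 500} ×
max depth {4, 8, unlimited} × min leaf {1, 5, 10}, with learning rate
{0.05, 0.1, 0.3} added for the gradient-boosted variant; the search is
sequential model-based optimization over that finite grid (random
initialization, then proposals by an inverse-distance surrogate with a
small exploration bonus), with a configurable budget (default 25 trials)
falling back to exhaustive evaluation when the grid is smaller than the
budget. Trials are scored by the mean 5-fold cross-validated AUPRC of the
weighted ensemble; folds are stratified by label and seeded.

The validation performance p_i of each submodel is its own mean fold
AUPRC (the alternative — scoring each submodel inside the ensemble
objective — is not what "validation performance of the individual models"
naturally means, and the simple reading keeps weights interpretable).
Weights are w_i = p_i / Σ p_j, with a uniform fallback if all p_i = 0,
and the prediction is ŷ = Σ w_i ŷ_i over submodel class-probabilities, so
ŷ is always a convex combination in [0, 1]. Missing features are imputed
by per-column training medians frozen at fit time; median imputation
makes behaviour independent of how a particular tree library treats
missing values. Pan-cancer models re-use already-fitted per-cancer
models, weighting their scores by validation performance normalized over
the included models, optionally excluding the target cancer
(leave-one-cancer-out).

## Evaluation protocols

The standard protocol makes **one** global pair-disjoint 80/20 split and
then draws runs (default 10) by independently undersampling the majority
class within train and within test — balancing both sides keeps AUPRC
comparable across runs; `balance = "train"` reproduces the
train-only-balancing reading, and `balance = "none"` exists for
diagnostics. Double gene holdout partitions the gene universe per run and
keeps a pair only when both genes fall on one side, so train and test
share no genes; the gene-side fraction q is solved from the target test
share t via q²/(q² + (1−q)²) = t (t = 0.2 gives q = 1/3), and partitions
leaving a side single-class are resampled up to a retry budget (50).
Cross-source runs train on one label study and test on another with
shared pairs removed from the test side.

AUPRC is average precision (step interpolation over unique score
thresholds) — trapezoidal PR interpolation is known to be optimistic.
AUROC is the Mann–Whitney statistic with midrank tie handling. Model
comparison uses the two-sided Wilcoxon signed-rank test on per-run
metrics, dropping zero differences per convention; the all-zero case
returns p = 1 with a warning rather than an error.

Permutation category importance jointly row-permutes **all** columns of
one source in the test blocks (one shared permutation per permuted test
set, preserving within-category structure while breaking the
feature–label link); the concatenated block is rebuilt from the permuted
source, so its columns change accordingly. The score is the mean over
permutations (default 20) of (1 − AUPRC)_permuted / (1 − AUPRC)_original.
Mean-of-ratios is the headline (the per-permutation ratios are returned,
so ratio-of-means is recoverable). A model with zero original error has
undefined ratios and reports an infinite sentinel with a warning —
importance should be measured on held-out pairs, where tree ensembles do
not trivially reach zero error.

## The synthetic world

The generator emulates every input the pipeline consumes: protein
sequences (FASTA), a PPI edge list with evidence classes, a cell-line
bundle (dependency, expression z, mutations, discrete CNA) and a patient
bundle (tumour expression level and z, mutations, CNA, clinical
follow-up, plus normal and healthy expression compartments), with labels
emitted from the planted truth. Planted effects:

* SL partners share a per-pair sequence motif (12 aa by default), so the
  hash embedder's absolute differences shrink for SL pairs;
* SL partners are wired to a common 3-gene PPI neighbourhood over an
  Erdős–Rényi background with mixed evidence classes;
* the dependency of each SL gene drops by δ in cell lines where its
  partner is altered (symmetric in both genes, any-channel alterations);
* tumour log-expression of SL partners is correlated at r via a shared
  latent factor, and partner copy-number calls are coupled with
  probability r. A gene can host only one such latent correlation, so
  when planted pairs share genes the correlation is planted for the
  first pair claiming each gene and the world records which pairs carry
  it; the verifier estimates r over exactly those pairs;
* survival is exponential (baseline rate 1/24 per month, i.e. a ~17-month
  median, with uniform 12–60-month censoring) and the hazard is
  multiplied by h **per co-altered SL pair**. A single "co-altered in any
  SL pair" indicator saturates at realistic alteration rates (with ~50
  planted pairs nearly every patient is co-altered somewhere), destroying
  the contrast; the multiplicative count model preserves the pairwise
  hazard ratio h that each pair's survival feature sees.

Alteration events are sampled independently per sample and gene at the
configured base rate (default 0.2) — the simplest exchangeable model;
real tumours show mutual exclusivity and signature structure the
generator does not attempt. Other things it does not emulate: realistic
mutational signatures, copy-number segment structure, DepMap/TCGA
marginal distributions, and any language-model structure in sequences.
Passing tests therefore demonstrate that the framework can discover and
exploit each kind of planted signal at desk scale — not that it matches
published performance on real cohorts.

`verify_planted_effects()` closes the loop: δ from the difference of
conditional dependency means over SL pairs, r from mean tumour
log-expression correlation over the planted pairs, h from a CoxPH fit on
the co-alteration count, each flagged when more than 3 standard errors
from its target.

## Problem sizes and numerical choices

The test suite and acceptance script run the full pipeline at deliberate
desk scale: worlds of 40–200 genes, 80–300 cell lines, 100–1000 patients,
sequence/PPI embedding dimensions reduced to 8–128/8–32 (the defaults
1024/64 are interface contracts, exercised for shape, not for every model
fit), search budgets of 1–3 trials over the default grid, and 1–2
evaluation runs per fitted experiment where a fit is needed repeatedly.
These sizes recover all planted effects within sampling error while
keeping each file's runtime in seconds to a couple of minutes.

Numerical details worth knowing:

* string ordering (pair canonicalization, tie-breaks) uses C collation,
  independent of the session locale;
* random-number state is saved and restored around every seeded
  operation, so package calls do not perturb a caller's RNG stream;
* `exact = FALSE` correlation p-values (two-sided) avoid exact-ties
  errors on discrete copy-number data;
* Cox fits that fail, do not converge to finite coefficients, or have an
  empty/undersized co-altered group yield missing values, never
  exceptions, because one degenerate pair must not abort a 13 × N block;
* all-missing feature columns impute to 0; weights fall back to uniform
  only when every submodel's validation AUPRC is 0.

## Limitations

The walk-embedding implementation is dense-matrix and desk-scale; a
production deployment on a full interactome would swap in a sparse
factorization behind the same interface. The hash embedder is a
benchmarking device, not a biological sequence model. Output
probabilities are not calibrated (ranking metrics are the target), and
hyperparameters are shared across submodels by design — per-submodel
tuning is out of scope, as are neural or matrix-factorization submodels
and multiple-testing correction across candidate-pair survival screens
(raw Wald p-values are reported).
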