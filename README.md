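# elisl — early–late integrated ensembles for synthetic-lethality prediction

Synthetic lethality (SL) is the relationship in which simultaneous loss of
two genes kills a cell while loss of either alone is tolerated; it is the
basis of targeted therapies such as PARP inhibition in BRCA-deficient
tumours. Finding new SL pairs by screening is expensive, so supervised
models that score candidate gene pairs from molecular data are widely used.
This package is for computational biologists who want to featurize gene
pairs from heterogeneous data sources, train integrated tree-ensemble
predictors, and evaluate them with protocols that are robust to the gene
selection bias that inflates naive benchmarks.

## The model

A gene pair is represented by *k* feature sets, one per data source
(X_i ∈ R^(N×f_i)):

| source        | f_i  | content                                                               |
|---------------|------|-----------------------------------------------------------------------|
| `seq`         | 1024 | elementwise \|v(a) − v(b)\| of protein-sequence embeddings            |
| `ppi`         | 64   | \|v(a) − v(b)\| of PPI-network walk embeddings (curated/experimental edges only) |
| `crispr_mut`  | 4    | mean CRISPR dependency of each gene in cell lines where the partner is mutated / unmutated |
| `crispr_expr` | 4    | same, with partner alteration called from expression z-scores (\|z\| > 1.96) |
| `tissue`      | 13   | co-mutation CoxPH survival p (1), conditional average expression (4), tumour/normal/healthy coexpression r and p (6), copy-number Spearman ρ and p (2) |

The early–late integration ensemble fits k per-source tree models plus one
on the concatenation X_(k+1) (early integration), all sharing one
hyperparameter configuration chosen by sequential model-based search with
5-fold cross-validation on ensemble AUPRC. Each submodel's validation
AUPRC p_i sets its weight

    w_i = p_i / Σ_j p_j ,     ŷ = Σ_i w_i ŷ_i ,

so the prediction is a convex combination of submodel class-probabilities
(late integration). Random-forest (`rf`, via ranger) and gradient-boosted
(`gb`, via xgboost) variants are provided.

Evaluation follows a 10-run protocol: one pair-disjoint 80/20 split, then
per run random undersampling of the majority class in train and test, with
AUPRC/AUROC metrics and paired two-sided Wilcoxon comparisons. Two
bias-probing protocols are included: **double gene holdout** (train and
test share no genes at all) and **cross-label-source** transfer (train on
one label study, test on another, shared pairs removed). Feature-category
importance is the mean ratio of permuted to original prediction error
(1 − AUPRC) over 20 joint row-permutations of a source's features.

A synthetic multi-omics world generator plants SL signal of configurable
effect size in every channel (shared sequence motifs, common PPI
neighbourhoods, a dependency shift −δ under partner alteration, tumour
coexpression r, a per-co-altered-pair hazard ratio h), so the whole
pipeline is testable without any external data.

## Worked example

```r
library(elisl)

cfg <- synthetic_world_config(n_genes = 60, n_cell_lines = 120,
                              n_patients = 150, d_seq = 64, d_ppi = 16)
world  <- generate_world(cfg, seed = 1)
blocks <- featurize_world(world)
fit    <- elisl(blocks, world$labels, ensemble = "rf",
                search_budget = 3, seed = 1)
fit
```

```
Early-late integrated SL ensemble (RF), 5 sources + concat, 100 training pairs
  weights:
    seq          w = 0.092  (validation AUPRC 0.451)
    ppi          w = 0.144  (validation AUPRC 0.706)
    crispr_mut   w = 0.203  (validation AUPRC 1.000)
    crispr_expr  w = 0.201  (validation AUPRC 0.986)
    tissue       w = 0.158  (validation AUPRC 0.777)
    concat       w = 0.203  (validation AUPRC 0.996)
  ensemble CV AUPRC: 0.996
```

The dependency screen carries the strongest planted effect (δ = 1), so the
CRISPR sources earn the largest weights; the sequence source is weakest at
these sizes. Held-out evaluation and generator diagnostics:

```r
runs <- make_standard_runs(world$labels, n_runs = 2, seed = 1)
run_experiment(runs, blocks, ensemble = "rf", search_budget = 2, seed = 1)
#> evaluation over 2 runs
#>   AUPRC mean 1.000 (median 1.000), AUROC mean 1.000 (median 1.000)

verify_planted_effects(world)
#>      parameter target estimate     se  flag
#> 1        delta    1.0    1.025 0.0112 FALSE
#> 2     r_target    0.6    0.591 0.0116 FALSE
#> 3 hazard_ratio    0.5    0.533 0.0890 FALSE
```

Every planted parameter is recovered within sampling error, and the
ensemble separates planted SL from non-SL pairs on held-out pairs.

A command-line front end over the same functions ships in
`inst/cli/elisl.R` with subcommands `simulate`, `featurize`, `train`,
`predict`, `evaluate`, `importance`.

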