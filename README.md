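# pathgcn

Pathway-level feature importance for two-class expression phenotypes, from a
graph convolutional network (GCN) explained with Shapley values.

## The problem

Differential-expression tools such as gene set enrichment analysis (GSEA)
rank pathways by how strongly their member genes' *individual* expression
levels track a phenotype. But a pathway can matter for a phenotype without
any single gene shifting its mean — for example when the *co-expression
structure* among its genes differs between classes. A classifier that sees
the pathway's genes jointly, through the pathway's own interaction graph,
can exploit such signal; attributing the classifier's decisions back to
pathways then surfaces associations that enrichment analysis misses.

`pathgcn` implements that workflow end to end for bulk or single-cell
transcriptomics with a binary phenotype (its motivating use case is
classifying diffuse large B-cell lymphoma expression subtypes, GCB vs ABC,
over KEGG pathway graphs):

1. **Per-pathway gene graphs.** Each curated gene set (GMT file) becomes an
   undirected, unweighted graph over its member genes, with edges from a
   within-pathway relation list. Convolution uses the symmetric-normalized
   operator with self-loops,
   `S_k = D̃_k^{-1/2} (A_k + I) D̃_k^{-1/2}`, `D̃_ii = Σ_j (A_k + I)_ij`.
2. **GCN classifier.** Two graph-convolution layers with weights **shared
   across all K pathway graphs** (`H^(l+1) = σ(S_k H^(l) W^(l))`, σ = ReLU,
   batch norm + dropout after each), per-graph average pooling to
   `pool_channels` values per pathway (10 by default — 186 KEGG pathways
   give a 1860-dimensional pooled layer), and a linear softmax head. Trained
   by Adam on class-weighted cross-entropy with L2, early stopping after 5
   non-improving epochs, Youden-index decision cutoff. MLP and GCN-MLP
   baselines, random hyperparameter search and stratified 5-fold CV are
   included.
3. **Shapley attribution.** The logit margin is attributed to the pooled
   features; because the GCN head is linear in them, the Shapley values are
   *exact* (`φ_i = w_i (z_i − E[z_i])`) and satisfy local accuracy to
   machine precision. Per-pathway importance is the mean absolute Shapley
   value over that pathway's channels and all samples. Gene-level
   attributions use expected gradients. A self-contained phenotype-permutation
   GSEA (signal-to-noise ranking, weighted KS enrichment score, NES / p /
   FDR q) provides the comparator ranking.
4. **Validation by rank windows.** L2 logistic regressions on consecutive
   importance windows (5 pathways or 100 genes at a time) quantify how
   classification performance decays down the ranking.
5. **Synthetic fixtures.** A generator plants two effect types into
   realistic pathway collections: mean shifts (GSEA-visible) and
   class-dependent correlation flips with identical per-gene marginals
   (GSEA-blind, GCN-visible), with the planted truth recorded in a manifest.

Everything — the network, its training, the explainer, the enrichment
comparator — is implemented in R on sparse `Matrix` algebra; no GPU or deep
learning framework is needed at these problem sizes.

## Worked example

```r
library(pathgcn)
fx  <- make_fixture(fixture_spec())   # 40 pathways, 4 planted, 100 samples/class
fit <- train_model(fx$train, fx$graphs, model_config(seed = 11))
compute_metrics(predict_class(fit, fx$test), fx$test$labels, "class1")
imp <- aggregate_pathway_importance(shap_pooling(fit, fx$train))
enr <- permutation_stats(fx$train, fx$sets, n_perm = 1000, seed = 11)
cmp <- compare_rankings(imp, enr, top_n = 5)
rw  <- rank_window_validation(imp, fx$sets, fx$train, fx$test, "pathways", 5)
```

Output (abridged):

```
trained GCN model: 20 epochs run, best epoch 15, cutoff 0.992
accuracy 0.965  precision 1.000  recall 0.930  F1 0.964 (positive: class1)
importance_table (pathway level), top entries:
    id mean_abs_shap rank
 PW002    0.45878465    1
 PW001    0.39974510    2
 PW003    0.22955263    3
 PW004    0.17575647    4
 PW015    0.06365657    5
SHAP top-5:  PW002 PW001 PW003 PW004 PW015
GSEA top-5:  PW002 PW001 PW004 PW033 PW015
planted   :  PW001 PW002 PW003 PW004  (correlation-flip: PW003 PW004)
window F1 :  1.00 0.51 0.54 0.53 0.53 0.44 0.52 0.50   (OLS slope -0.044)
```

Reading this: the held-out test accuracy is 0.965; all four planted
pathways occupy the top four importance ranks; the correlation-flip pathway
`PW003` — whose genes have *identical* marginal distributions in both
classes — is recovered by the Shapley ranking but absent from GSEA's top
five; and logistic regressions built from successive 5-pathway importance
windows collapse from F1 = 1.00 (top window, which holds the planted
pathways) to chance, with a negative F1-vs-rank slope.

A command-line front end over the same functions ships in
`inst/cli/pathgcn.R` (`simulate`, `graph-stats`, `train`, `evaluate`,
`gsea`, `explain`, `validate-ranks`); run it with `Rscript` and `--help`-style
usage in the file header.

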