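# gatm5c

Graph-attention prioritization of RNA 5-methylcytosine (m5C) modified
genes in protein–protein interaction (PPI) networks.

## What problem this solves

MeRIP-seq yields, per gene and dataset, an RPM-normalized expression level
and an m5C peak enrichment. Thousands of genes carry peaks; the question
is which of them are *functionally important*. `gatm5c` answers it by
scoring every gene of a PPI network with a three-layer graph attention
network (GAT) trained on the modification data itself, and ships the
standard comparator (random walk with restart, RWR), the
robustness/efficiency benchmark protocol, AUROC evaluation against
functional-gene lists, a hypergeometric over-representation test, and a
synthetic fixture generator so the whole method is trainable and testable
without any external download.

It is aimed at computational epitranscriptomics: you have exomePeak2-style
quantification tables, an edge list merged from PPI databases (BioGRID,
HuRI, PICKLE, …), and optionally ground-truth gene lists (COSMIC /
IntOGen / DisGeNET exports) as plain files.

## The model

Per dataset, each gene carries a 2-vector of Z-scored (expression, m5C)
levels; genes with a retained peak are labeled y = 1, all other network
genes y = 0. Peaks aggregate per gene by summed RPM and are filtered at
< 1.0 RPM expression / < 0.1 RPM m5C. Every PPI is stored as two directed
unit-weight edges. A head of the attention model computes, for target gene
*i* and source *j* with edge type *t*,

    e_ij = LeakyReLU( a_dstᵀ W h_i + a_srcᵀ W h_j + a_e · pᵀ g(t) )
    α_ij = softmax over j ∈ N(i) ∪ {i} of e_ij
    h'_i = Σ_j α_ij W h_j + b

with a learned 32-dimensional edge-type embedding g per layer. The
architecture is 2 → 2 heads × 16 → 2 heads × 16 → 1 logit → sigmoid, with
batch normalization after layers 1–2, ELU activations, dropout 0.3,
structural self-loops with a reserved edge type, Adam (lr 5e-4, weight
decay 1e-4), binary cross-entropy on a stratified 80/20 (gene, dataset)
split, early stopping with patience 30 within at most 200 epochs. Scores
are averaged over datasets and reported raw, Min-Max- and Z-normalized.

The fast stability filter ranks candidates by degree information only
(`degree × mean seed degree`), which makes its top-k sets exactly
invariant under degree-preserving network randomization — the property
the robustness benchmark measures.

## Worked example

```r
library(gatm5c)

sim <- generate_synthetic(synthetic_spec(n_genes = 300, n_datasets = 3, seed = 11))
sim$network
#> <ppi_network> 300 genes, 894 undirected interactions (1788 directed edges)
#>   edge types: synthetic

fit <- gat_train(sim$features, sim$network, gat_config(), train_config(seed = 11))
fit
#> <gat_fit> 300 genes, stopped at epoch 93 (best epoch 63, val loss 0.6212)

scores <- score_genes(fit, sim$network, sim$features)
head(scores, 5)
#> # A tibble: 5 × 5
#>   gene_id raw_score minmax_score z_score  rank
#>   <chr>       <dbl>        <dbl>   <dbl> <int>
#> 1 G00271      0.487        1        3.98     1
#> 2 G00277      0.474        0.915    3.44     2
#> 3 G00285      0.472        0.906    3.38     3
#> 4 G00267      0.456        0.802    2.72     4
#> 5 G00114      0.455        0.795    2.68     5

auroc(scores, sim$truth)
#> [1] 0.765
```

The score table ranks genes by the model's importance score; `auroc()`
reports how well the ranking recovers the planted functional genes (0.765
on this deliberately small 300-gene fixture; recovery strengthens with
the default 2000-gene, six-dataset design). The robustness protocol
contrasts the degree-information filter with RWR across two ensembles of
degree-preserving random networks:

```r
seeds <- sample_seed_genes(sim$features, 50, seed = 1)
robustness_protocol(sim$network, seeds, n_networks = 20, k = 50,
                    methods = c("degree_filter", "rwr"), seed = 2)[, 1:2]
#> # A tibble: 2 × 2
#>   method        n_differing
#>   <chr>               <int>
#> 1 degree_filter           0
#> 2 rwr                    12
```

`n_differing` counts genes by which the two ensembles' consensus candidate
sets disagree: 0 for the degree filter (exactly stable by construction),
nonzero for RWR, whose scores depend on rewired distances.

## Package layout

- `R/` — readers/writers (`read_edge_list`, `read_quantification`, …),
  feature engineering (`aggregate_peaks`, `filter_low_signal`,
  `zscore_by_dataset`, `filter_differential_peaks`), the graph
  (`build_network`, `degree_preserving_randomize`, `align_features`), the
  model (`gat_config`, `gat_forward`, `attention_coefficients`), training
  (`gat_train`, `score_genes`, checkpoints), the baseline (`rwr`,
  `sample_seed_genes`) and the benchmark (`auroc`,
  `degree_based_candidate_filter`, `robustness_protocol`,
  `over_representation`, `timing_harness`).
- `vignettes/gene-prioritization-methods.Rmd` — the models, their
  assumptions, parameter meanings and design decisions.
- `tests/testthat/` — unit, property and end-to-end suites with
  independent oracles (scalar attention recomputation, dense linear
  solves, exhaustive pair counting, brute-force recounts).
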