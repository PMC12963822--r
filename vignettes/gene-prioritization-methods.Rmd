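---
title: "Prioritizing m5C-modified genes with graph attention: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing m5C-modified genes with graph attention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gatm5c)
```

## The problem

MeRIP-seq experiments report, per gene and per dataset, an RPM-normalized
expression level and an RPM-normalized 5-methylcytosine (m5C) peak
enrichment. Thousands of genes carry peaks; very few of them matter
functionally. `gatm5c` scores every gene in a protein–protein interaction
(PPI) network for functional importance by combining the two measured
channels with the network context, on the premise that functionally
important modified genes sit in informative neighborhoods of the
interactome rather than in isolation.

The pipeline is: read interaction and quantification tables → aggregate
peaks per gene, filter weak signal, Z-score per dataset → build the merged
directed PPI graph → train a three-layer graph attention network (GAT)
transductively on peak-presence labels → average eval-mode scores over
datasets → normalize, rank, and benchmark against a random-walk-with-restart
(RWR) baseline.

## Feature construction

Per dataset, peaks are collapsed to one m5C level per gene. The collapse is
a **sum** of the per-peak RPMs; summing treats total methylated mass as the
gene-level signal, and a `max` alternative is available for analyses that
prefer the strongest single site. A peak-bearing gene is kept as a positive
(`y = 1`) only if its expression is at least 1.0 RPM and its aggregated m5C
level at least 0.1 RPM; the filter removes strictly-below values, so exact
boundary values survive. Genes failing either threshold are **demoted to
negatives** (`y = 0`, m5C reset to 0) rather than deleted: the label
definition requires every network gene without a retained peak to remain in
the graph as a negative node, so deletion would silently shrink the
negative class.

Both channels are then standardized to mean 0 and standard deviation 1
within each dataset. We use the population (n-denominator) standard
deviation; at these sample sizes the distinction from the sample estimator
is cosmetic, but fixing one makes the tests exact. A constant channel maps
to all zeros. The per-dataset means and standard deviations travel with the
feature table so that network genes missing from a quantification table can
be imputed at the standardized value corresponding to 0 RPM — the value a
gene with no reads would have received.

Differential peaks are filtered at |log2 FC| ≥ log2(1.5) and p < 0.05,
counting up- and down-regulated survivors; the absolute value covers both
directions of regulation.

## The interaction graph

Interactions merged from several source databases are deduplicated over
unordered pairs; each retained pair becomes **two directed, unit-weight
edges**, which lets message passing run in both directions while keeping
the undirected biology. When sources disagree about a pair, the edge type
follows a declared precedence order (first source wins); the edge-type
vocabulary defaults to the source database because no richer typing is
available in standard PPI exports. Self-interactions are dropped at read
time — structural self-loops are added later, explicitly, by the model, so
that the neighborhood of every node (including isolated ones) is
well-defined and carries a reserved edge type the model can learn
separately.

Node order is lexicographic over gene symbols, making every downstream
computation reproducible across platforms.

## The attention model

Three cascaded graph attention layers map the 2-dimensional input to one
importance logit per gene: layer 1 has two 16-dimensional heads (outputs
concatenated to 32), layer 2 two further 16-dimensional heads on the
32-dimensional input, and layer 3 a single head producing 1 dimension,
followed by a sigmoid. For target gene $i$, source gene $j$, and edge type
$t_{ij}$, a head computes

$$e_{ij} = \mathrm{LeakyReLU}\!\big(a_{dst}^\top W h_i + a_{src}^\top W h_j
  + a_{e}\, p^\top g(t_{ij})\big), \qquad
\alpha_{ij} = \frac{\exp e_{ij}}{\sum_{j' \in N(i) \cup \{i\}} \exp e_{ij'}},$$

with $g$ the layer's 32-dimensional edge-type embedding table and $p$ its
projection, shared across the layer's heads; $h_i' = \sum_j \alpha_{ij} W
h_j + b$. The literature leaves the attention form open once edge features
enter the logit; we use the standard single-matrix formulation with the
embedding contribution added inside the LeakyReLU (slope 0.2, the usual
convention), which keeps the softmax normalization property exactly and is
the smallest extension that lets edge types influence attention.

Batch normalization follows layers 1 and 2 (batch = node dimension,
biased variance, momentum 0.1, eps 1e-5), ELU activations avoid dead
units, and dropout at rate 0.3 is applied to node representations after
each activation. Dropout on attention coefficients themselves is
implemented but off by default — whether it belongs in the original recipe
is not decidable, and representation dropout alone already regularizes
well at this scale. In eval mode dropout is the identity and batch
normalization uses running statistics, so scoring is a pure function:
repeated calls agree bitwise, and relabeling the graph permutes the scores
without changing them.

The forward and backward passes are written directly in vectorized R
(sparse segment-sum operators over the edge list); gradient correctness is
pinned by a central-finite-difference check at relative tolerance 1e-4 in
the test suite.

## Training protocol

Samples are (gene, dataset) pairs. The 80/20 split is stratified by
dataset × label — stratifying by dataset alone would satisfy "maintain the
dataset distribution", but adding the label dimension is the conservative
superset and keeps the positive rate stable in the validation set. Within
each stratum the validation count is `round(0.2 × size)` with exact .5
resolved downward.

Each dataset is one full-graph sample sharing the topology and all
parameters; an epoch performs one forward/backward pass and Adam update
per dataset (learning rate 5e-4, weight decay 1e-4 added to the gradient,
PyTorch-style) and reports the across-dataset mean of the masked binary
cross-entropy. Both losses are computed on the full graph with node masks,
the standard transductive protocol. Training stops at the earlier of 200
epochs or 30 consecutive epochs without validation improvement, returning
the parameters of the best validation epoch. No learning-rate schedule is
used. Divergence (non-finite loss) is an error, not a warning.

Final scores are eval-mode forward passes per dataset, averaged per gene
over the datasets in which the gene was actually observed (genes observed
nowhere average over all datasets, since imputation makes their features
identical across datasets anyway). Min-Max and Z-score columns are added
for cross-method comparability; the degenerate constant-score vector maps
to 0.5 (Min-Max) and 0 (Z) so downstream consumers never see NaN.

## The RWR baseline

The comparator propagates scores from seed genes by
$p^{(t+1)} = (1-r)\,M p^{(t)} + r\,p_0$ with $M$ the column-stochastic
(degree-normalized) adjacency and $p_0$ uniform over seeds. The restart
probability is not pinned down by propagation conventions in this
literature; we default to $r = 0.7$ and expose it. Mass reaching
degree-zero nodes is returned through the restart vector, keeping the
score vector a probability distribution at every iteration — the property
the convergence test asserts. The iterative solver is validated against
the closed-form solve $(I - (1-r)M)^{-1} r p_0$ on dozens of random graphs
at L∞ 1e-6; seed-set mass is uniform (no weighting by m5C level, which the
quantification tables could support but nothing here requires).

## Robustness benchmark and the degree filter

The stability protocol compares candidate sets across two independent
ensembles of 100 degree-preserving random networks (double-edge swaps, 10×
the edge count per network, swaps creating self- or duplicate edges
rejected). Per network each method selects top-200 candidates from the
same 100 modified-gene seeds; an ensemble's consensus set contains the
genes present in at least 50% of its networks — the 100 per-network sets
must be collapsed to something comparable, and majority membership is the
simplest rule that is insensitive to single outlier networks. The reported
statistic is the size of the symmetric difference between the two
consensus sets.

The fast path scores a candidate gene as
`degree(gene) × mean(seed degrees)` and is deliberately a function of
degree information only; it is therefore *exactly* invariant under
degree-preserving randomization (symmetric difference 0 by construction),
while RWR — which reads distances, not just degrees — shifts its candidate
sets when rewiring changes seed-to-candidate paths. The particular
degree-only formula is one reconstruction of an under-specified family; it
is isolated behind a single function so alternatives can be swapped
without touching the protocol. Timing of the two methods is recorded by a
harness and asserted only as an ordering (the filter is faster), never as
a hardware-dependent ratio.

## Synthetic study conditions

The generator grows a scale-free graph by preferential attachment (3 edges
per new node, no multi-edges), plants 5% functional genes with a hub bias
(sampling weight `degree^(2·hub_bias)`) and a preference for mutual
adjacency (half of the picks extend the neighborhood of the current set),
and simulates six datasets: each gene is modified with probability
`frac_modified·(1 + effect_size)` (capped at 0.9) if functional and the
complementary background rate otherwise, so the overall prevalence stays
at `frac_modified = 0.3`. Modified genes draw m5C from a log-normal whose
log-mean is shifted by `effect_size` (default 2) standard deviations for
functional genes; expression receives half that shift. Modified genes are
truncated up to 1.0/0.1 RPM so every planted positive survives the
low-signal filter — the generator defines conditions under which the
pipeline's filters are label-neutral by design. Tying the
label-probability enrichment to `effect_size` makes the null construction
(`effect_size = 0`, `hub_bias = 0`) genuinely uninformative in all three
signal carriers: channels, labels and topology.

What the generator does *not* emulate: the real interactome's size
(~20k genes) and literature bias, correlated noise between expression and
methylation, dataset-specific library effects, and incomplete coverage of
the network by the quantification tables. Passing the recovery tests
therefore demonstrates that the implementation learns the signal it is
pointed at — not that the method's real-data prioritizations are correct.

Problem sizes used by the test suite, chosen to keep the full run at desk
scale: recovery training on the default 2000-gene/6-dataset design; the
null check on ten replicates at 1000 genes and 3 datasets (chance-level
recovery does not depend on scale); the robustness protocol at the full
2000-gene/100-network/100-seed design.

## Numerical choices and degenerate inputs

* Grouped softmax subtracts one global maximum (constant within every
  group) for overflow safety.
* Binary cross-entropy is computed from logits in the
  `max(z,0) − yz + log(1+exp(−|z|))` form.
* Glorot-uniform weight initialization, zero biases, small-uniform
  (±0.1) edge embeddings; all randomness flows through locally scoped
  seeds (`withr`), never the global RNG state.
* Ties in rankings break lexicographically by gene id everywhere a rank or
  a top-k set is produced, so outputs are total orders.
* Score tables serialize with six decimals; round-tripping reproduces
  scores to that precision.
* A constant feature channel Z-scores to zeros; a single-gene dataset is
  an error; an empty stratum falls back to training with a warning.

## Known limitations

* Full-graph forward passes only; no neighbor sampling. Fine at 10^4
  genes, not engineered for 10^6-edge interactomes.
* The transductive split means reported validation losses are on nodes the
  model has seen (unlabeled) during message passing, as is standard.
* Gene identifiers are assumed pre-harmonized symbols; no cross-database
  ID mapping is attempted.
* The degree-only fast filter is a reconstruction; its defining property
  (invariance under degree-preserving rewiring) is asserted, but other
  degree-only scores would satisfy it too.
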