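---
title: "Separating widely and rarely expressed genes by functional enrichment: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating widely and rarely expressed genes by functional enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enrichIFS)
```

## The problem

Across a panel of tissues and cancers, some genes are expressed everywhere
(FPKM > 1 in every sample) and some nowhere (FPKM < 1 in every sample).
Treating "widely expressed" as the positive class and "rarely expressed" as
the negative class turns the contrast into a binary classification problem
whose *features* are functional: how strongly each gene's protein-interaction
neighborhood overlaps each GO term and KEGG pathway. The features that drive
a good classifier are then the biological functions that distinguish the two
expression regimes.

This vignette documents the models, the tunable parameters, the numerical
conventions, and the limits of what the synthetic validation shows.

## Gene labeling

`label_genes_by_expression()` applies strict inequalities on both sides:
positive iff FPKM > *t* in **every** sample, negative iff FPKM < *t* in
**every** sample (*t* = 1 by default, the conventional detected/not-detected
FPKM boundary). A gene exactly at the threshold in any sample, or above in
some samples and below in others, belongs to neither regime and is omitted.
Missing expression values are rejected rather than imputed: the rule is a
universally-quantified condition and is undefined on missing data. The rule
is scale-equivariant — multiplying all FPKM values and the threshold by the
same constant leaves the labels unchanged (tested).

## Enrichment encoding

For gene *g*, the neighbor set *GS(g)* holds the genes sharing a PPI edge
with *g* (the gene itself is excluded by default; `include_self` flips
this). For a term with annotated set of size *M* inside a universe of *N*
genes, with *n* = |GS(g)| and overlap *m*, the score is

$$S(g, T) = -\log_{10} \sum_{k=m}^{n} \frac{\binom{M}{k}\binom{N-M}{n-k}}{\binom{N}{n}},$$

the inclusive upper tail P(X ≥ m) of the hypergeometric distribution,
computed via `stats::phyper` (stable far beyond N = 10⁵; the test suite
checks it against direct summation to 1e-10). Conventions:

* **Universe size N.** Default: the number of nodes in the PPI network —
  self-consistent with the source of the neighbor sets. An explicit N or
  the union of network nodes and annotated genes can be requested. Term
  sets are intersected with the universe before computing *M*, so *M ≤ N*
  always holds.
* **Score cap.** P-values below 1e-300 underflow; they are reported at
  `score_cap` = 300. The cap keeps features bounded, which matters for the
  equal-frequency binning downstream.
* **Degenerate genes.** A gene with an empty neighbor set has no enrichment
  information; it is discarded from the matrix and listed in the
  `discarded` attribute, mirroring how unencodable genes are dropped before
  classification.
* **Feature order.** GO namespaces (BP, CC, MF) then KEGG, ids sorted
  within each — fixed and recorded in the column names, so ranked lists are
  comparable across runs.

No GO-graph propagation is performed: terms are flat sets. If the
annotation source propagates ancestors, that decision belongs to the caller
preparing the GMT files.

## mRMR ranking

Mutual information is estimated by the plug-in (empirical frequency)
estimator after equal-frequency discretization of each feature
(`n_bins` = 4, a standard choice balancing resolution against sparse joint
tables; the class label is used as-is). Natural logarithms — the base only
scales all MI values and cannot change the ranking. The greedy selection
maximizes *D − R* (relevance minus mean redundancy to the already-selected
set, R = 0 at the first step); ties break toward the lowest column index so
the ranking is deterministic. Redundancy sums are cached incrementally —
selecting feature *s* adds I(f_s, f_j) to each remaining *j* — which the
suite verifies against a naive oracle that recomputes every pairwise MI at
every step. `max_rank_depth` ranks only a prefix when the full permutation
is not needed; the unranked tail is appended in relevance order.

Binning convention: boundaries are type-1 quantiles (order statistics), and
values equal to a boundary fall in the lower bin. Heavy ties collapse
boundaries — a constant feature lands in one bin and contributes zero MI.

## Classifier engines

**LSTM.** The forward pass is the standard gate system: at each step
f, i, o = sigmoid gates, candidate = tanh, cell state
c_t = f⊙c_{t−1} + i⊙candidate, hidden state h_t = o⊙tanh(c_t). (One
published form of the last equation reads tanh(h_t), which is
self-referential; the package uses tanh(c_t), the standard formulation.)
Since a gene's feature vector has no intrinsic temporal order, it is fed as
a sequence of `chunk_size` = 32 consecutive slices, the last zero-padded;
the readout is a sigmoid on a linear map of h_T, thresholded at 0.5 with
logit 0 called positive. Training is full-batch gradient descent on
(optionally class-weighted) cross-entropy via backpropagation through time,
with features standardized by training-set mean/SD. Defaults: hidden 16,
200 epochs, learning rate 0.2 — at substantially smaller rates the
full-batch optimizer can sit on the majority-class plateau for hundreds of
epochs on imbalanced data before the minority class contributes usable
gradient. Weight init is uniform(−r, r) with r = (hidden + chunk)^(−1/2)
and forget-gate bias 1. The BPTT gradients are verified against finite
differences, and the forward pass against a scalar per-gate reference, in
the test suite.

**Random forest.** The comparison engine delegates to the `randomForest`
package (100 trees by default). It draws its bootstraps from R's own RNG,
which makes fits bit-reproducible across processes and platforms from the
spec's seed — a property tested, and one reason it is preferred here over
faster forest implementations whose split tie-breaking is not
process-stable on heavily tied enrichment scores.

Both engines are deterministic given the spec's mandatory seed.

## Cross-validation and metrics

`kfold_assign()` produces balanced folds (sizes differ by ≤ 1), stratified
by class by default: with a ~4.7:1 imbalance and ten folds, unstratified
draws can starve a fold of negatives and make specificity unstable. A
single global counter chains the cyclic assignment across strata, so the
overall fold sizes stay balanced too. An unstratified mode exists for
fidelity studies. Held-out predictions are **pooled** into one confusion
table per model (rather than averaging per-fold metrics), which is the
convention that yields a single SN/SP/ACC/MCC/J row per evaluated model.

MCC's denominator convention: if any factor is zero, MCC = 0. Youden's
*J = SN + SP − 1* is the selection criterion because it weighs the minority
class equally; ACC on 4.7:1 data rewards majority-class collapse.

## Two-step incremental feature selection

Evaluating every prefix of a 20,978-feature list is prohibitive, so stage 1
scans prefixes at step 10 (plus the full length if not a multiple) and
stage 2 exhaustively scans `best ± width` (default width 50, clipped to
[1, N]); an explicit interval override exists for replication of
hand-chosen intervals. One fold assignment is drawn once and reused for
every size so the curves are comparable; the optimum is the global Youden
argmax with ties broken toward the smaller (cheaper) prefix, and the
optimum classifier is retrained on all data with that prefix. The suite
re-derives the curves by independent re-evaluation on the same folds.

## Synthetic data: what it emulates and what it does not

`generate_dataset()` plants the signal **at the network level**: a
background Erdős–Rényi interactome (mean degree 10, confidences uniform on
[0.4, 1]), term sets sampled uniformly (sizes 10–30) across four namespaces
(BP 150, CC 50, MF 60, KEGG 40 by default — BP-heavy like real GO), labels
at the 4.7:1 imbalance observed between widely and rarely expressed genes,
and, for each positive gene, an extra edge to each member of each
informative term's gene set with probability `effect_strength`. Positive
genes' neighborhoods thus genuinely overlap the informative terms more, and
the enrichment equations are exercised exactly as on real data. At
`effect_strength = 0` the construction is an exact null — the guard against
information leakage anywhere in the chain.

`generate_feature_matrix()` skips the network and emits folded-normal
(|N(0,1)|, right-skewed, nonnegative) feature scores with a mean shift on
informative columns — used only to unit-test ranking/selection in
isolation.

The generators do **not** mimic STRING's heavy-tailed degree distribution,
GO's DAG structure and annotation propagation, inter-term correlation from
shared pathways, or the confounding between a gene's degree and its
annotation richness in curated databases. Passing the planted-signal
recovery tests therefore demonstrates the pipeline's statistical machinery
is correct and leak-free, not that comparable Youden indices would be
reached on any particular real compendium.

## Benchmark problem sizes

The end-to-end validation runs at 600 genes / 300 terms / 15 informative /
effect 0.5 (strong) or 0 (null), with IFS at step 10, half-width 20,
10 folds, and the random-forest engine at 60 trees — sizes at which a full
run completes in about a minute while still exercising every stage at
realistic imbalance. Measured behavior at these settings: the strong run
puts 14/15 informative terms in the mRMR top 30 and reaches optimum J = 1.0;
null runs stay below |J| ≤ 0.1. The random-forest engine is used for these
benchmark loops because it needs no per-size optimizer tuning; the LSTM's
correctness is pinned separately (forward-pass oracle, gradient check,
Youden > 0.8 on well-separated data).

## Known limitations

* The mRMR MI estimator is the discretized plug-in; kernel or k-NN
  estimators (and the MIQ quotient variant) are out of scope.
* The LSTM is single-layer, unidirectional, full-batch — adequate for the
  moderate feature counts used here, not tuned for 20k-dimensional inputs.
* No ROC/AUC: selection happens at the fixed 0.5 threshold via Youden's J.
* No identifier mapping: gene ids are opaque strings and must already agree
  across the expression table, network and annotation files.
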