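# enrichIFS

Classify **widely expressed genes** (FPKM > 1 in every tissue/cancer sample)
against **rarely expressed genes** (FPKM < 1 in every sample) from functional
annotation alone, and extract the GO terms and KEGG pathways that carry the
distinction.

The package is aimed at computational biologists who want to ask not *which*
genes sit in a ubiquitous-vs-silent expression regime, but *which biological
functions* separate the two regimes — and who need every stage of that
analysis (encoding, ranking, selection, evaluation) reproducible and testable
without large external downloads.

## The method

1. **Enrichment encoding.** For gene *g* with PPI-neighbor set *GS(g)* and a
   term *T* annotating gene set *GS_T* inside a universe of *N* genes, the
   feature value is the upper-tail hypergeometric surprise of their overlap:

   *S(g, T) = −log₁₀ Σₖ₌ₘⁿ C(M, k) · C(N−M, n−k) / C(N, n)*

   with *M = |GS_T|*, *n = |GS(g)|*, *m = |GS(g) ∩ GS_T|*. One score per GO
   term and KEGG pathway turns each gene into a long nonnegative vector
   (20,681 GO + 297 KEGG terms give a 20,978-dimensional encoding).

2. **mRMR ranking.** Features are ordered greedily by mutual information:
   each step selects the feature maximizing *D − R*, where *D = I(class, f)*
   is relevance and *R* is the mean MI between *f* and the already-selected
   features (equal-frequency discretization, plug-in MI in nats).

3. **Two-step incremental feature selection (IFS).** Prefixes of the ranked
   list are evaluated by 10-fold cross-validation at step 10; an interval
   around the coarse Youden-index argmax is then scanned exhaustively. The
   prefix size maximizing *J = SN + SP − 1* defines the optimum classifier.

4. **Engines and metrics.** An LSTM recurrent network (standard
   forget/input/output gate equations, trained by full-batch gradient
   descent with backpropagation through time) and a random-forest comparison
   engine; pooled confusion counts yield SN, SP, ACC, MCC and Youden's *J* —
   *J* being the selection criterion because the classes are ~4.7:1
   imbalanced.

A synthetic-data module generates PPI networks, term collections and labels
with a *planted* signal (positive-class genes receive extra edges into the
gene sets of chosen informative terms), so the whole pipeline is validated
end to end by parameter recovery.

## Worked example

```r
library(enrichIFS)

# synthetic benchmark: 600 genes, 300 terms, 15 informative, 4.7:1 imbalance
ds <- generate_dataset(synthetic_config(seed = 101))
fm <- encode_genes(ds$labels$gene_id, ds$ppi, ds$terms)
lab <- ds$labels[ds$labels$gene_id %in% rownames(fm), ]

ranked <- mrmr_rank(fm, lab)
sum(head(ranked$feature_id, 30) %in% ds$informative_terms)
#> [1] 14        # 14 of the 15 planted terms sit in the mRMR top 30

ifs <- run_ifs(fm, lab, ranked,
               classifier_spec("random_forest", seed = 7, ntree = 60),
               step = 10, width = 20, folds = 10, seed = 13)
ifs
#> ifs_result: optimum 12 features; SN=1.000 SP=1.000 ACC=1.000 MCC=1.000 J=1.000

namespace_tally(head(ranked$feature_id, ifs$optimum_size), ds$terms)
```

The printed line means the two-step scan found a 12-feature prefix whose
10-fold cross-validated Youden index is 1.0 — the planted signal is fully
recovered. On a null dataset (`effect_strength = 0`) the same pipeline
returns an optimum *J* near 0 (|J| < 0.1 across seeds), confirming no
leakage.

A driver for file-based runs is provided (`run_pipeline()`, or
`inst/scripts/run_pipeline.R` from a shell); it writes every intermediate
artifact plus a checksum manifest.

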