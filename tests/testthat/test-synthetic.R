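test_that("dataset generation is deterministic and respects the imbalance ratio", {
  cfg <- synthetic_config(n_genes = 120, n_terms = c(BP = 15, CC = 5, MF = 5, KEGG = 5),
                          n_informative = 4, seed = 71)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$ppi$edges, d2$ppi$edges)
  expect_identical(d1$terms, d2$terms)
  expect_identical(d1$labels, d2$labels)
  expect_identical(d1$informative_terms, d2$informative_terms)

  # 4.7:1 on 570 genes splits 470/100
  cfg2 <- synthetic_config(n_genes = 570, n_terms = c(BP = 4, CC = 2, MF = 2, KEGG = 2),
                           n_informative = 2, seed = 72)
  tab <- table(generate_dataset(cfg2)$labels$label)
  expect_equal(unname(tab[["positive"]]), 470)
  expect_equal(unname(tab[["negative"]]), 100)
})

test_that("generated structures satisfy their own invariants", {
  d <- generate_dataset(synthetic_config(n_genes = 150,
                                         n_terms = c(BP = 10, CC = 4, MF = 4, KEGG = 4),
                                         n_informative = 3, seed = 73))
  e <- d$ppi$edges
  expect_true(all(e$gene_a != e$gene_b))                 # no self-loops
  expect_true(all(e$confidence >= 0 & e$confidence <= 1))
  expect_false(any(duplicated(paste(e$gene_a, e$gene_b))))
  expect_true(all(lengths(d$terms$genes) >= 1))
  expect_true(all(d$informative_terms %in% d$terms$term_id))
})

test_that("planted signal raises informative-term scores in the positive class", {
  d <- generate_dataset(synthetic_config(n_genes = 300,
                                         n_terms = c(BP = 40, CC = 10, MF = 10, KEGG = 10),
                                         n_informative = 8, effect_strength = 0.5,
                                         seed = 74))
  fm <- encode_genes(d$labels$gene_id, d$ppi, d$terms)
  lab <- d$labels[match(rownames(fm), d$labels$gene_id), ]
  pos <- lab$label == "positive"
  inf_scores <- rowMeans(fm[, d$informative_terms, drop = FALSE])
  p <- stats::wilcox.test(inf_scores[pos], inf_scores[!pos],
                          alternative = "greater")$p.value
  expect_lt(p, 0.01)
})

test_that("a zero effect strength is an exact null for informative terms", {
  d <- generate_dataset(synthetic_config(n_genes = 300,
                                         n_terms = c(BP = 40, CC = 10, MF = 10, KEGG = 10),
                                         n_informative = 8, effect_strength = 0,
                                         seed = 75))
  fm <- encode_genes(d$labels$gene_id, d$ppi, d$terms)
  lab <- d$labels[match(rownames(fm), d$labels$gene_id), ]
  pos <- lab$label == "positive"
  inf_scores <- rowMeans(fm[, d$informative_terms, drop = FALSE])
  p <- stats::wilcox.test(inf_scores[pos], inf_scores[!pos])$p.value
  expect_gt(p, 0.01)   # no class difference beyond sampling error
})

test_that("the direct matrix generator plants exactly what it claims", {
  g <- generate_feature_matrix(n_samples = 570, n_features = 50,
                               n_informative = 10, shift = 2,
                               imbalance = 4.7, seed = 76)
  expect_equal(dim(g$features), c(570, 50))
  tab <- table(g$labels$label)
  expect_equal(unname(tab[["positive"]]), 470)
  expect_true(all(g$features >= 0))
  inf <- attr(g$features, "informative")
  expect_length(inf, 10)
  pos <- g$labels$label == "positive"
  gap <- colMeans(g$features[pos, inf]) - colMeans(g$features[!pos, inf])
  expect_true(all(gap > 1))    # shift 2 dominates the folded-normal noise
  g2 <- generate_feature_matrix(570, 50, 10, 2, 4.7, seed = 76)
  expect_identical(unclass(g$features), unclass(g2$features))
})

test_that("at zero shift informative columns reach the top ranks only by chance", {
  hits <- vapply(1:4, function(s) {
    g <- generate_feature_matrix(200, 60, 12, shift = 0, imbalance = 4, seed = s)
    r <- mrmr_rank(g$features, g$labels)
    sum(head(r$feature_id, 12) %in% attr(g$features, "informative"))
  }, numeric(1))
  # chance rate is 12/60 = 0.2 -> expect ~2.4 of 12; demand no systematic pull
  expect_lt(mean(hits), 6)
})

test_that("config validation rejects impossible settings", {
  expect_error(synthetic_config(seed = 1, n_informative = 1000),
               class = "enrichIFS_domain_error")
  expect_error(synthetic_config(seed = 1, effect_strength = 1.5),
               class = "enrichIFS_domain_error")
  expect_error(synthetic_config(n_genes = 5, term_size_range = c(10, 30), seed = 1),
               class = "enrichIFS_domain_error")
  expect_error(synthetic_config(), "seed")
  expect_error(generate_feature_matrix(100, 5, 10, 1, seed = 1),
               class = "enrichIFS_domain_error")
})
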