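test_that("stage-1 size grids follow the step-and-remainder rule", {
  expect_identical(stage1_sizes(25, 10), c(10L, 20L, 25L))
  expect_identical(stage1_sizes(30, 10), c(10L, 20L, 30L))
  expect_identical(stage1_sizes(7, 10), 7L)
  expect_identical(stage1_sizes(1, 10), 1L)
  expect_error(stage1_sizes(0, 10), class = "enrichIFS_domain_error")
})

test_that("stage-2 intervals are symmetric and clipped", {
  expect_identical(stage2_interval(14890, 50, 20978), c(14840L, 14940L))
  expect_identical(stage2_interval(30, 50, 500), c(1L, 80L))
  expect_identical(stage2_interval(490, 50, 500), c(440L, 500L))
  expect_error(stage2_interval(0, 50, 10), class = "enrichIFS_domain_error")
})

# Shared small planted-signal instance for the run_ifs contract tests.
ifs_fixture <- function() {
  gfm <- generate_feature_matrix(n_samples = 150, n_features = 40,
                                 n_informative = 8, shift = 1.2,
                                 imbalance = 4, seed = 31)
  ranked <- mrmr_rank(gfm$features, gfm$labels)
  list(X = gfm$features, y = gfm$labels, ranked = ranked,
       spec = classifier_spec("random_forest", seed = 32, ntree = 60))
}

test_that("run_ifs selects the global Youden argmax with smallest-size ties", {
  fx <- ifs_fixture()
  res <- run_ifs(fx$X, fx$y, fx$ranked, fx$spec, step = 10, width = 5,
                 folds = 5, seed = 33)
  all_sizes <- c(res$stage1$n_features, res$stage2$n_features)
  all_J <- c(res$stage1$J, res$stage2$J)
  best_J <- max(all_J)
  expect_equal(res$optimum_metrics$J, best_J, tolerance = 1e-12)
  # smallest size among the argmax ties
  expect_equal(res$optimum_size, min(all_sizes[all_J >= best_J - 1e-12]))
  # optimum beats (or equals) every stage-1 point
  expect_true(all(res$optimum_metrics$J >= res$stage1$J))
  # interval contains the stage-1 argmax
  best1 <- res$stage1$n_features[which.max(res$stage1$J)]
  expect_true(res$interval[1] <= best1 && best1 <= res$interval[2])
})

test_that("run_ifs curves equal an independent re-evaluation on the same folds", {
  fx <- ifs_fixture()
  res <- run_ifs(fx$X, fx$y, fx$ranked, fx$spec, step = 10, width = 3,
                 folds = 5, seed = 33)
  # exhaustive oracle: recompute each evaluated size from scratch
  folds <- res$fold_assignment
  for (row in sample(nrow(res$stage2), 3)) {
    sz <- res$stage2$n_features[row]
    cols <- fx$ranked$order[seq_len(sz)]
    cc <- cross_validate(fx$X[, cols, drop = FALSE], fx$y, fx$spec, folds)
    expect_equal(compute_metrics(cc)$J, res$stage2$J[row], tolerance = 1e-9)
  }
  # optimum is within 1e-9 of the max over all evaluated sizes
  expect_equal(res$optimum_metrics$J,
               max(c(res$stage1$J, res$stage2$J)), tolerance = 1e-9)
})

test_that("run_ifs is deterministic and honors an explicit interval", {
  fx <- ifs_fixture()
  r1 <- run_ifs(fx$X, fx$y, fx$ranked, fx$spec, step = 20, width = 2,
                folds = 5, seed = 44)
  r2 <- run_ifs(fx$X, fx$y, fx$ranked, fx$spec, step = 20, width = 2,
                folds = 5, seed = 44)
  expect_identical(r1$stage1, r2$stage1)
  expect_identical(r1$optimum_size, r2$optimum_size)

  r3 <- run_ifs(fx$X, fx$y, fx$ranked, fx$spec, step = 20, folds = 5,
                seed = 44, interval = c(5, 9))
  expect_identical(r3$stage2$n_features, 5:9)
})

test_that("run_ifs degenerates gracefully with a single feature", {
  gfm <- generate_feature_matrix(60, 1, 1, shift = 2, imbalance = 2, seed = 51)
  ranked <- mrmr_rank(gfm$features, gfm$labels)
  res <- run_ifs(gfm$features, gfm$labels, ranked,
                 classifier_spec("random_forest", seed = 52, ntree = 50),
                 step = 10, folds = 5, seed = 53)
  expect_identical(res$stage1$n_features, 1L)
  expect_identical(res$stage2$n_features, 1L)
  expect_identical(res$optimum_size, 1L)
})

test_that("the optimum classifier is the retrained optimum prefix model", {
  fx <- ifs_fixture()
  res <- run_ifs(fx$X, fx$y, fx$ranked, fx$spec, step = 10, width = 2,
                 folds = 5, seed = 60)
  expect_identical(res$optimum_classifier$feature_ids,
                   fx$ranked$feature_id[seq_len(res$optimum_size)])
  direct <- train(fx$spec,
                  fx$X[, fx$ranked$order[seq_len(res$optimum_size)], drop = FALSE],
                  fx$y)
  expect_identical(
    predict(res$optimum_classifier,
            fx$X[, fx$ranked$order[seq_len(res$optimum_size)], drop = FALSE]),
    predict(direct,
            fx$X[, fx$ranked$order[seq_len(res$optimum_size)], drop = FALSE]))
  expect_error(run_ifs(fx$X, fx$y, list(order = c(1L, 2L)), fx$spec,
                       folds = 5, seed = 1),
               class = "enrichIFS_domain_error")
})
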