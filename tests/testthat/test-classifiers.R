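test_that("vector_to_sequence chunks, pads and round-trips", {
  s <- vector_to_sequence(1:10, 5)
  expect_equal(dim(s), c(2, 5))
  expect_equal(as.vector(t(s)), 1:10)

  s2 <- vector_to_sequence(1:7, 3)
  expect_equal(dim(s2), c(3, 3))
  expect_equal(s2[3, ], c(7, 0, 0))
  expect_equal(as.vector(t(s2))[1:7], 1:7)   # trimming padding recovers x

  expect_equal(dim(vector_to_sequence(3.5, 1)), c(1, 1))
  expect_error(vector_to_sequence(numeric(0), 2), class = "enrichIFS_domain_error")
})

test_that("lstm_forward with zero parameters returns a zero hidden state", {
  p <- lstm_init(4, 3, seed = 1)
  for (nm in grep("^[WUb]_", names(p), value = TRUE)) p[[nm]] <- p[[nm]] * 0
  set.seed(2)
  h <- lstm_forward(p, vector_to_sequence(rnorm(9), 3))
  expect_equal(h, rep(0, 4))
})

test_that("lstm_forward matches a closed-form scalar evaluation", {
  # hidden_dim 1, chunk 1, T = 2: every gate is a scalar formula
  p <- lstm_init(1, 1, seed = 1)
  p$W_f[] <- 0.5; p$U_f[] <- 0.3; p$b_f[] <- 0.1
  p$W_i[] <- -0.4; p$U_i[] <- 0.2; p$b_i[] <- 0
  p$W_c[] <- 0.8; p$U_c[] <- -0.5; p$b_c[] <- 0.2
  p$W_o[] <- 0.6; p$U_o[] <- 0.1; p$b_o[] <- -0.3
  x <- c(1, -1)
  sig <- function(z) 1 / (1 + exp(-z))
  h <- 0; cc <- 0
  for (t in 1:2) {
    f <- sig(0.5 * x[t] + 0.3 * h + 0.1)
    i <- sig(-0.4 * x[t] + 0.2 * h + 0)
    g <- tanh(0.8 * x[t] - 0.5 * h + 0.2)
    o <- sig(0.6 * x[t] + 0.1 * h - 0.3)
    cc <- f * cc + i * g
    h <- o * tanh(cc)
  }
  expect_equal(lstm_forward(p, matrix(x, ncol = 1)), h, tolerance = 1e-12)
})

test_that("lstm_forward matches the naive per-gate reference on random params", {
  for (seed in 1:10) {
    p <- lstm_init(hidden_dim = 3, chunk_size = 4, seed = seed)
    set.seed(seed + 500)
    s <- vector_to_sequence(rnorm(15), 4)
    ref <- naive_lstm_forward(p, s)
    expect_equal(lstm_forward(p, s), ref$h, tolerance = 1e-10)
    # range and cell-state bound: f, i in (0,1), |tanh| < 1 => |c_t| <= t
    expect_true(all(abs(ref$h) < 1))
    for (t in seq_along(ref$c_hist)) {
      expect_true(all(abs(ref$c_hist[[t]]) <= t))
    }
  }
})

test_that("BPTT gradients agree with finite differences", {
  p <- lstm_init(2, 2, seed = 7)
  set.seed(8)
  X <- matrix(rnorm(12), 3, 4)
  ybin <- c(1, 0, 1)
  X_seq <- list(X[, 1:2], X[, 3:4])
  loss_of <- function(params) {
    fwd <- enrichIFS:::lstm_forward_batch(params, X_seq)
    logit <- drop(fwd$h_T %*% params$w_out) + params$b_out
    pr <- 1 / (1 + exp(-logit))
    -mean(ybin * log(pr) + (1 - ybin) * log(1 - pr))
  }
  fwd <- enrichIFS:::lstm_forward_batch(p, X_seq)
  logit <- drop(fwd$h_T %*% p$w_out) + p$b_out
  pr <- 1 / (1 + exp(-logit))
  dlogit <- matrix((pr - ybin) / 3, ncol = 1)
  updated <- enrichIFS:::lstm_backward_update(p, fwd, dlogit, lr = 1)
  eps <- 1e-6
  for (nm in c("W_c", "U_o", "b_f", "w_out")) {
    idx <- 1L   # first element of each parameter block
    analytic <- (p[[nm]][idx] - updated[[nm]][idx])   # lr = 1
    pp <- p; pp[[nm]][idx] <- pp[[nm]][idx] + eps
    pm <- p; pm[[nm]][idx] <- pm[[nm]][idx] - eps
    numeric_grad <- (loss_of(pp) - loss_of(pm)) / (2 * eps)
    expect_equal(analytic, numeric_grad, tolerance = 1e-5)
  }
})

test_that("both engines fit a separable toy set perfectly and deterministically", {
  sep <- make_separable()
  for (eng in c("lstm", "random_forest")) {
    spec <- classifier_spec(eng, seed = 11)
    clf <- train(spec, sep$X, sep$y)
    pred <- predict(clf, sep$X)
    expect_equal(mean(pred == sep$y$label), 1, info = eng)
    clf2 <- train(spec, sep$X, sep$y)
    expect_identical(predict(clf2, sep$X), pred)
    expect_identical(predict(clf, sep$X[1, , drop = FALSE]),
                     factor("positive", levels = c("negative", "positive")))
  }
})

test_that("training rejects degenerate labels and predict checks columns", {
  sep <- make_separable()
  yall <- gene_labels(rownames(sep$X), rep("positive", nrow(sep$X)))
  expect_error(train(classifier_spec("random_forest", seed = 1), sep$X, yall),
               class = "enrichIFS_domain_error")
  clf <- train(classifier_spec("random_forest", seed = 1), sep$X, sep$y)
  Xbad <- sep$X; colnames(Xbad) <- c("fA", "other")
  expect_error(predict(clf, Xbad), "other")
  expect_error(classifier_spec("lstm"), class = "enrichIFS_domain_error")
})

test_that("an LSTM logit of exactly zero is called positive", {
  sep <- make_separable()
  clf <- train(classifier_spec("lstm", seed = 3, epochs = 1), sep$X, sep$y)
  clf$fit$params$w_out[] <- 0
  clf$fit$params$b_out <- 0
  pred <- predict(clf, sep$X)
  expect_true(all(pred == "positive"))
})

test_that("both engines exceed Youden 0.8 on well-separated imbalanced data", {
  gfm <- generate_feature_matrix(n_samples = 200, n_features = 10,
                                 n_informative = 5, shift = 3,
                                 imbalance = 4.7, seed = 21)
  folds <- kfold_assign(200, k = 5, seed = 22, strata = gfm$labels$label)
  for (eng in c("lstm", "random_forest")) {
    cc <- cross_validate(gfm$features, gfm$labels,
                         classifier_spec(eng, seed = 23), folds)
    expect_gt(compute_metrics(cc)$J, 0.8, label = paste(eng, "Youden"))
  }
})
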