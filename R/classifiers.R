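# Binary classification engines: an LSTM recurrent network whose forward
# pass implements the standard gate equations, and a random-forest
# comparison engine.  A fixed-length feature vector is fed to the LSTM as a
# sequence of consecutive chunks (the last chunk zero-padded).

#' Classifier specification
#'
#' @param engine `"lstm"` or `"random_forest"`.
#' @param seed Integer seed; mandatory (both engines are stochastic).
#' @param ... Engine hyperparameters.  For `lstm`: `hidden_dim` (16),
#'   `chunk_size` (32), `epochs` (200), `learning_rate` (0.2),
#'   `class_weights` (`FALSE`; `TRUE` reweights the cross-entropy by inverse
#'   class frequency).  For `random_forest`: `ntree` (100), plus anything
#'   accepted by [randomForest::randomForest].
#' @return A `classifier_spec`.
#' @export
classifier_spec <- function(engine = c("lstm", "random_forest"), seed, ...) {
  engine <- match.arg(engine)
  if (missing(seed)) stop_domain("seed is mandatory for a stochastic engine")
  hp <- list(...)
  defaults <- switch(engine,
    lstm = list(hidden_dim = 16L, chunk_size = 32L, epochs = 200L,
                learning_rate = 0.2, class_weights = FALSE),
    random_forest = list(ntree = 100L))
  hp <- utils::modifyList(defaults, hp)
  structure(list(engine = engine, seed = as.integer(seed),
                 hyperparameters = hp),
            class = "classifier_spec")
}

#' Split a feature vector into a chunk sequence
#'
#' @param x Non-empty numeric vector of length d.
#' @param chunk_size Scalars per timestep (>= 1).
#' @return A `T x chunk_size` matrix of `T = ceiling(d / chunk_size)`
#'   consecutive chunks, the last zero-padded; concatenating the rows and
#'   trimming the padding recovers `x`.
#' @export
vector_to_sequence <- function(x, chunk_size) {
  if (length(x) == 0L) stop_domain("empty feature vector")
  if (chunk_size < 1L) stop_domain("chunk_size must be >= 1")
  T_ <- ceiling(length(x) / chunk_size)
  out <- numeric(T_ * chunk_size)
  out[seq_along(x)] <- x
  matrix(out, nrow = T_, ncol = chunk_size, byrow = TRUE)
}

#' Initialize LSTM parameters
#'
#' Input and recurrent weights are drawn uniformly in `(-r, r)` with
#' `r = 1/sqrt(hidden_dim + chunk_size)`; biases start at zero except the
#' forget-gate bias, which starts at 1 (the usual remember-by-default
#' initialization).
#'
#' @param hidden_dim Hidden-state size.
#' @param chunk_size Input scalars per timestep.
#' @param seed Integer seed.
#' @return An `lstm_params` list with input weights `W_f, W_i, W_c, W_o`
#'   (hidden x chunk), recurrent weights `U_f, U_i, U_c, U_o`
#'   (hidden x hidden), biases `b_f, b_i, b_c, b_o`, and readout `w_out`,
#'   `b_out`.
#' @export
lstm_init <- function(hidden_dim, chunk_size, seed) {
  with_seed(seed, {
    r <- 1 / sqrt(hidden_dim + chunk_size)
    rmat <- function(nr, nc) matrix(runif(nr * nc, -r, r), nr, nc)
    p <- list(hidden_dim = as.integer(hidden_dim),
              chunk_size = as.integer(chunk_size))
    for (g in c("f", "i", "c", "o")) {
      p[[paste0("W_", g)]] <- rmat(hidden_dim, chunk_size)
      p[[paste0("U_", g)]] <- rmat(hidden_dim, hidden_dim)
      p[[paste0("b_", g)]] <- if (g == "f") rep(1, hidden_dim) else rep(0, hidden_dim)
    }
    p$w_out <- matrix(runif(hidden_dim, -r, r), hidden_dim, 1)
    p$b_out <- 0
    structure(p, class = "lstm_params")
  })
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' LSTM forward pass over one chunk sequence
#'
#' Starting from zero hidden and cell states, applies for t = 1..T:
#' `f_t = sigmoid(W_f x_t + U_f h_{t-1} + b_f)`,
#' `i_t = sigmoid(W_i x_t + U_i h_{t-1} + b_i)`,
#' `c_t = f_t * c_{t-1} + i_t * tanh(W_c x_t + U_c h_{t-1} + b_c)`,
#' `o_t = sigmoid(W_o x_t + U_o h_{t-1} + b_o)`,
#' `h_t = o_t * tanh(c_t)` (all products element-wise), and returns `h_T`.
#'
#' @param params An `lstm_params`.
#' @param sequence A `T x chunk_size` matrix as from [vector_to_sequence()].
#' @return Numeric vector `h_T` of length `hidden_dim`; every component lies
#'   strictly inside (-1, 1).
#' @export
lstm_forward <- function(params, sequence) {
  if (!is.matrix(sequence)) sequence <- matrix(sequence, nrow = 1)
  if (ncol(sequence) != params$chunk_size) {
    stop_domain("sequence chunk length ", ncol(sequence),
                " does not match params chunk_size ", params$chunk_size)
  }
  H <- params$hidden_dim
  h <- numeric(H); cc <- numeric(H)
  for (t in seq_len(nrow(sequence))) {
    x <- sequence[t, ]
    f <- sigmoid(drop(params$W_f %*% x + params$U_f %*% h) + params$b_f)
    i <- sigmoid(drop(params$W_i %*% x + params$U_i %*% h) + params$b_i)
    g <- tanh(drop(params$W_c %*% x + params$U_c %*% h) + params$b_c)
    o <- sigmoid(drop(params$W_o %*% x + params$U_o %*% h) + params$b_o)
    cc <- f * cc + i * g
    h <- o * tanh(cc)
  }
  h
}

# Batched forward pass: X_seq is a list of T matrices (n x chunk_size).
# Returns gate/state caches for BPTT.
lstm_forward_batch <- function(params, X_seq) {
  n <- nrow(X_seq[[1L]]); H <- params$hidden_dim; T_ <- length(X_seq)
  h <- matrix(0, n, H); cc <- matrix(0, n, H)
  cache <- vector("list", T_)
  for (t in seq_len(T_)) {
    x <- X_seq[[t]]
    zf <- x %*% t(params$W_f) + h %*% t(params$U_f)
    zi <- x %*% t(params$W_i) + h %*% t(params$U_i)
    zg <- x %*% t(params$W_c) + h %*% t(params$U_c)
    zo <- x %*% t(params$W_o) + h %*% t(params$U_o)
    f <- sigmoid(sweep(zf, 2, params$b_f, "+"))
    i <- sigmoid(sweep(zi, 2, params$b_i, "+"))
    g <- tanh(sweep(zg, 2, params$b_c, "+"))
    o <- sigmoid(sweep(zo, 2, params$b_o, "+"))
    c_prev <- cc
    cc <- f * c_prev + i * g
    h <- o * tanh(cc)
    cache[[t]] <- list(f = f, i = i, g = g, o = o, c = cc, c_prev = c_prev,
                       h = h, x = x)
  }
  list(h_T = h, cache = cache)
}

# One full-batch gradient step; returns updated params. dlogit: n x 1
# gradient of the loss wrt the readout logit.
lstm_backward_update <- function(params, fwd, dlogit, lr) {
  cache <- fwd$cache; T_ <- length(cache)
  H <- params$hidden_dim
  grads <- list()
  for (nm in c("W_f", "W_i", "W_c", "W_o", "U_f", "U_i", "U_c", "U_o")) {
    grads[[nm]] <- params[[nm]] * 0
  }
  for (nm in c("b_f", "b_i", "b_c", "b_o")) grads[[nm]] <- numeric(H)

  grads$w_out <- t(fwd$h_T) %*% dlogit
  grads$b_out <- sum(dlogit)

  dh <- dlogit %*% t(params$w_out)      # n x H
  dc <- matrix(0, nrow(dh), H)
  for (t in rev(seq_len(T_))) {
    s <- cache[[t]]
    tc <- tanh(s$c)
    do_ <- dh * tc
    dc <- dc + dh * s$o * (1 - tc^2)
    dg <- dc * s$i
    di <- dc * s$g
    df <- dc * s$c_prev
    dc_prev <- dc * s$f
    # pre-activation gradients
    df_z <- df * s$f * (1 - s$f)
    di_z <- di * s$i * (1 - s$i)
    do_z <- do_ * s$o * (1 - s$o)
    dg_z <- dg * (1 - s$g^2)
    h_prev <- if (t > 1L) cache[[t - 1L]]$h else matrix(0, nrow(dh), H)
    grads$W_f <- grads$W_f + t(df_z) %*% s$x
    grads$W_i <- grads$W_i + t(di_z) %*% s$x
    grads$W_c <- grads$W_c + t(dg_z) %*% s$x
    grads$W_o <- grads$W_o + t(do_z) %*% s$x
    grads$U_f <- grads$U_f + t(df_z) %*% h_prev
    grads$U_i <- grads$U_i + t(di_z) %*% h_prev
    grads$U_c <- grads$U_c + t(dg_z) %*% h_prev
    grads$U_o <- grads$U_o + t(do_z) %*% h_prev
    grads$b_f <- grads$b_f + colSums(df_z)
    grads$b_i <- grads$b_i + colSums(di_z)
    grads$b_c <- grads$b_c + colSums(dg_z)
    grads$b_o <- grads$b_o + colSums(do_z)
    dh <- df_z %*% params$U_f + di_z %*% params$U_i +
          dg_z %*% params$U_c + do_z %*% params$U_o
    dc <- dc_prev
  }
  for (nm in names(grads)) params[[nm]] <- params[[nm]] - lr * grads[[nm]]
  params
}

#' Train a binary classifier
#'
#' The LSTM engine reshapes each feature vector into a chunk sequence,
#' standardizes features using training-set means/sds, and minimizes mean
#' cross-entropy of a sigmoid readout on the final hidden state by
#' full-batch gradient descent (backpropagation through time).  The
#' random-forest engine delegates to [randomForest::randomForest].  Both are
#' deterministic given the spec (including its seed).
#'
#' @param spec A `classifier_spec`.
#' @param X Numeric matrix (samples x features) with colnames.
#' @param y Labels: a `gene_labels` table aligned by rownames, or a vector
#'   of `"positive"` / `"negative"` of length `nrow(X)`.  Both classes must
#'   be present with at least 2 samples each.
#' @return A `trained_classifier`.
#' @export
train <- function(spec, X, y) {
  y <- align_labels(X, y)
  if (any(table(y) < 2L)) {
    stop_domain("need at least 2 samples of each class (got ",
                paste(table(y), collapse = "/"), ")")
  }
  X <- as.matrix(unclass(X))
  feature_ids <- colnames(X) %||% as.character(seq_len(ncol(X)))
  colnames(X) <- feature_ids
  fit <- switch(spec$engine,
    lstm = train_lstm(spec, X, y),
    random_forest = train_rf(spec, X, y))
  structure(list(spec = spec, fit = fit, feature_ids = feature_ids),
            class = "trained_classifier")
}

train_lstm <- function(spec, X, y) {
  hp <- spec$hyperparameters
  ybin <- as.numeric(y == "positive")
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu, "-"), 2, sdv, "/")
  chunk <- as.integer(hp$chunk_size)
  d <- ncol(Xs)
  T_ <- ceiling(d / chunk)
  pad <- T_ * chunk - d
  if (pad > 0) Xs <- cbind(Xs, matrix(0, nrow(Xs), pad))
  X_seq <- lapply(seq_len(T_), function(t) {
    Xs[, ((t - 1L) * chunk + 1L):(t * chunk), drop = FALSE]
  })
  w <- if (isTRUE(hp$class_weights)) {
    n <- length(ybin)
    ifelse(ybin == 1, n / (2 * sum(ybin)), n / (2 * sum(1 - ybin)))
  } else rep(1, length(ybin))

  params <- lstm_init(hp$hidden_dim, chunk, spec$seed)
  n <- nrow(Xs)
  for (epoch in seq_len(hp$epochs)) {
    fwd <- lstm_forward_batch(params, X_seq)
    logit <- drop(fwd$h_T %*% params$w_out) + params$b_out
    p <- sigmoid(logit)
    dlogit <- matrix(w * (p - ybin) / n, ncol = 1)
    params <- lstm_backward_update(params, fwd, dlogit, hp$learning_rate)
  }
  list(params = params, mu = mu, sd = sdv, chunk_size = chunk, n_features = d)
}

train_rf <- function(spec, X, y) {
  # randomForest draws from R's RNG, so a with_seed wrapper gives full
  # cross-process determinism (tree bootstraps and mtry draws included)
  args <- c(list(x = X, y = y), spec$hyperparameters)
  with_seed(spec$seed, do.call(randomForest::randomForest, args))
}

#' Predict class labels
#'
#' The LSTM thresholds the sigmoid of the readout logit at 0.5; a logit of
#' exactly 0 is called positive (documented tie rule).
#'
#' @param object A `trained_classifier`.
#' @param X Matrix whose columns match the classifier's `feature_ids`.
#' @param ... Unused.
#' @return Factor of labels (levels `negative`, `positive`), one per row.
#' @export
predict.trained_classifier <- function(object, X, ...) {
  X <- as.matrix(unclass(X))
  ids <- colnames(X) %||% as.character(seq_len(ncol(X)))
  if (!identical(ids, object$feature_ids)) {
    missing_f <- setdiff(object$feature_ids, ids)
    extra_f <- setdiff(ids, object$feature_ids)
    stop_domain("feature mismatch; missing: [",
                paste(utils::head(missing_f, 5), collapse = ", "),
                "], extra: [", paste(utils::head(extra_f, 5), collapse = ", "), "]")
  }
  if (object$spec$engine == "random_forest") {
    return(unname(predict(object$fit, X)))
  }
  fit <- object$fit
  Xs <- sweep(sweep(X, 2, fit$mu, "-"), 2, fit$sd, "/")
  T_ <- ceiling(fit$n_features / fit$chunk_size)
  pad <- T_ * fit$chunk_size - fit$n_features
  if (pad > 0) Xs <- cbind(Xs, matrix(0, nrow(Xs), pad))
  X_seq <- lapply(seq_len(T_), function(t) {
    Xs[, ((t - 1L) * fit$chunk_size + 1L):(t * fit$chunk_size), drop = FALSE]
  })
  fwd <- lstm_forward_batch(fit$params, X_seq)
  logit <- unname(drop(fwd$h_T %*% fit$params$w_out)) + fit$params$b_out
  factor(ifelse(logit >= 0, "positive", "negative"),
         levels = c("negative", "positive"))
}
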