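# Independent oracles and shared fixtures.  Each oracle re-derives the
# quantity by direct enumeration, never through the package's own code path.

# Hypergeometric upper tail by brute-force summation of the choose products.
brute_hyper_tail <- function(N, M, n, m) {
  ks <- m:n
  total <- 0
  for (k in ks) {
    if (k > M || (n - k) > (N - M)) next
    total <- total + choose(M, k) * choose(N - M, n - k)
  }
  total / choose(N, n)
}

# Plug-in mutual information straight off the contingency table.
naive_mi <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  mi <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      if (tab[i, j] == 0) next
      pij <- tab[i, j] / n
      mi <- mi + pij * log(pij / ((sum(tab[i, ]) / n) * (sum(tab[, j]) / n)))
    }
  }
  mi
}

# Exhaustive mRMR greedy: recomputes every pairwise MI at every step, no
# caching.  Uses the package's discretize() (the binning convention is part
# of the contract) but its own MI and its own greedy loop.
naive_mrmr_order <- function(X, y, n_bins = 4L) {
  disc <- apply(X, 2, function(col) suppressWarnings(enrichIFS::discretize(col, n_bins)))
  y <- as.integer(factor(y))
  nf <- ncol(X)
  relevance <- vapply(seq_len(nf), function(j) naive_mi(y, disc[, j]), numeric(1))
  selected <- integer(0)
  remaining <- seq_len(nf)
  while (length(remaining) > 0L) {
    score <- vapply(remaining, function(j) {
      red <- if (length(selected) == 0L) 0 else
        mean(vapply(selected, function(s) naive_mi(disc[, s], disc[, j]), numeric(1)))
      relevance[j] - red
    }, numeric(1))
    pick <- remaining[which.max(score)]
    selected <- c(selected, pick)
    remaining <- remaining[remaining != pick]
  }
  selected
}

# Scalar, gate-by-gate LSTM forward pass; also returns the cell-state
# trajectory for the |c_t| <= t bound.
naive_lstm_forward <- function(params, sequence) {
  H <- params$hidden_dim
  h <- rep(0, H); cc <- rep(0, H)
  c_hist <- list()
  sig <- function(z) 1 / (1 + exp(-z))
  for (t in seq_len(nrow(sequence))) {
    x <- sequence[t, ]
    f <- i <- g <- o <- numeric(H)
    for (u in seq_len(H)) {
      f[u] <- sig(sum(params$W_f[u, ] * x) + sum(params$U_f[u, ] * h) + params$b_f[u])
      i[u] <- sig(sum(params$W_i[u, ] * x) + sum(params$U_i[u, ] * h) + params$b_i[u])
      g[u] <- tanh(sum(params$W_c[u, ] * x) + sum(params$U_c[u, ] * h) + params$b_c[u])
      o[u] <- sig(sum(params$W_o[u, ] * x) + sum(params$U_o[u, ] * h) + params$b_o[u])
    }
    cc <- f * cc + i * g
    h <- o * tanh(cc)
    c_hist[[t]] <- cc
  }
  list(h = h, c_hist = c_hist)
}

# A small PPI fixture: star centre hub with 4 leaves plus a triangle and an
# isolated-from-the-star pair.
make_toy_ppi <- function() {
  ea <- c("hub", "hub", "hub", "hub", "t1", "t1", "t2", "p1")
  eb <- c("l1", "l2", "l3", "l4", "t2", "t3", "t3", "p2")
  enrichIFS::ppi_network(ea, eb, rep(0.9, length(ea)))
}

# Random toy instance for the enrichment oracle: graph + terms over a small
# universe.  Returns pieces ready for encode_genes().
random_enrichment_instance <- function(seed, n_nodes = 20L, n_terms = 6L) {
  set.seed(seed)
  genes <- sprintf("n%02d", seq_len(n_nodes))
  pairs <- combn(genes, 2)
  keep <- runif(ncol(pairs)) < 0.25
  ppi <- enrichIFS::ppi_network(pairs[1, keep], pairs[2, keep],
                                runif(sum(keep)))
  terms <- enrichIFS::term_collection(
    sprintf("T%02d", seq_len(n_terms)),
    sample(c("BP", "CC", "MF", "KEGG"), n_terms, replace = TRUE),
    lapply(seq_len(n_terms), function(i) sample(genes, sample(3:8, 1))))
  list(ppi = ppi, terms = terms, genes = genes)
}

# A linearly separable two-feature fixture (balanced classes).
make_separable <- function(n_per_class = 30L, gap = 6, seed = 99L) {
  set.seed(seed)
  X <- rbind(
    cbind(rnorm(n_per_class, gap), rnorm(n_per_class, gap)),
    cbind(rnorm(n_per_class, 0), rnorm(n_per_class, 0)))
  rownames(X) <- sprintf("s%03d", seq_len(2 * n_per_class))
  colnames(X) <- c("fA", "fB")
  y <- enrichIFS::gene_labels(rownames(X),
                              rep(c("positive", "negative"), each = n_per_class))
  list(X = X, y = y)
}
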