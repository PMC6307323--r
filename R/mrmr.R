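# Minimum-redundancy maximum-relevance feature ranking with plug-in mutual
# information on equal-frequency-discretized enrichment scores.

#' Equal-frequency discretization
#'
#' Bin boundaries are the empirical quantiles at i/n_bins (type-1, i.e.
#' order statistics), so for ties-free input the bins are balanced to within
#' one element.  Heavy ties collapse boundaries: a constant vector maps to a
#' single bin, and fewer distinct values than bins triggers a warning.
#'
#' @param values Finite numeric vector.
#' @param n_bins Number of bins (>= 2).
#' @return Integer vector of 0-based bin labels.
#' @export
discretize <- function(values, n_bins = 4L) {
  if (n_bins < 2L) stop_domain("n_bins must be >= 2")
  if (any(!is.finite(values))) stop_domain("values must be finite")
  n_distinct <- length(unique(values))
  if (n_distinct < n_bins) {
    warning("fewer distinct values (", n_distinct, ") than bins (", n_bins,
            "); bins collapsed", call. = FALSE)
  }
  breaks <- unique(quantile(values, probs = seq_len(n_bins - 1L) / n_bins,
                            type = 1, names = FALSE))
  findInterval(values, breaks, left.open = TRUE)
}

#' Plug-in mutual information between two discrete vectors
#'
#' Empirical MI in nats: the sum over occupied cells of the joint frequency
#' table of `p(a,b) * log(p(a,b) / (p(a) p(b)))`.
#'
#' @param a,b Vectors of equal length (>= 2) of discrete labels.
#' @return Non-negative MI in nats; symmetric in its arguments.
#' @export
mutual_information <- function(a, b) {
  if (length(a) != length(b)) stop_domain("length mismatch between a and b")
  if (length(a) < 2L) stop_domain("need at least 2 observations")
  joint <- table(a, b)
  n <- sum(joint)
  pj <- joint / n
  pa <- rowSums(pj); pb <- colSums(pj)
  occ <- pj > 0
  expected <- outer(pa, pb)
  max(0, sum(pj[occ] * log(pj[occ] / expected[occ])))
}

# MI from pre-tabulated integer codes (1-based), avoiding table() overhead
mi_codes <- function(a, b, na_, nb_) {
  joint <- tabulate((a - 1L) * nb_ + b, nbins = na_ * nb_)
  n <- sum(joint)
  pj <- joint / n
  pa <- rowSums(matrix(pj, nrow = na_, byrow = TRUE))
  pb <- colSums(matrix(pj, nrow = na_, byrow = TRUE))
  expected <- as.vector(t(outer(pa, pb)))  # matches (a,b) linear index order
  occ <- pj > 0
  max(0, sum(pj[occ] * log(pj[occ] / expected[occ])))
}

#' Rank features by the mRMR greedy criterion
#'
#' Features are first discretized into equal-frequency bins; the class label
#' is used as-is.  The first selected feature maximizes relevance
#' `D = I(class, f)`; each subsequent selection maximizes `D - R`, where `R`
#' is the mean MI between the candidate and the already-selected features
#' (zero while nothing is selected).  Redundancy sums are cached
#' incrementally, so each round costs one MI evaluation per remaining
#' feature.  Ties are broken toward the lowest column index.
#'
#' @param X Numeric matrix (samples x features), e.g. a `feature_matrix`.
#' @param y A `gene_labels` data frame aligned with `rownames(X)`, or a
#'   vector of labels of length `nrow(X)`.
#' @param n_bins Bins for feature discretization (default 4).
#' @param max_rank_depth Rank only the first `max_rank_depth` positions; the
#'   remaining features are appended in relevance order (then index order).
#'   `Inf` (default) ranks everything.
#' @return A `ranked_features` list: `order` (integer permutation of feature
#'   columns, selection order), `feature_id`, and `relevance` (MI with the
#'   class per feature, in original column order).
#' @export
mrmr_rank <- function(X, y, n_bins = 4L, max_rank_depth = Inf) {
  y <- align_labels(X, y)
  nf <- ncol(X)
  if (nf < 1L) stop_domain("need at least one feature")

  disc <- matrix(0L, nrow = nrow(X), ncol = nf)
  nbin <- integer(nf)
  for (j in seq_len(nf)) {
    d <- suppressWarnings(discretize(X[, j], n_bins)) + 1L
    disc[, j] <- d
    nbin[j] <- max(d)
  }
  ycode <- as.integer(factor(y))
  ny <- max(ycode)

  relevance <- vapply(seq_len(nf), function(j) {
    mi_codes(ycode, disc[, j], ny, nbin[j])
  }, numeric(1))

  depth <- min(nf, max_rank_depth)
  selected <- integer(0)
  remaining <- seq_len(nf)
  red_sum <- numeric(nf)

  for (round in seq_len(depth)) {
    score <- if (length(selected) == 0L) {
      relevance[remaining]
    } else {
      relevance[remaining] - red_sum[remaining] / length(selected)
    }
    pick <- remaining[which.max(score)]   # which.max: first max -> lowest index
    selected <- c(selected, pick)
    remaining <- remaining[remaining != pick]
    if (length(remaining) > 0L && length(selected) < depth) {
      for (j in remaining) {
        red_sum[j] <- red_sum[j] +
          mi_codes(disc[, pick], disc[, j], nbin[pick], nbin[j])
      }
    }
  }
  if (length(remaining) > 0L) {
    # unranked tail: relevance order, ties by index (deterministic)
    tail_ord <- remaining[order(-relevance[remaining], remaining)]
    selected <- c(selected, tail_ord)
  }

  structure(list(order = selected,
                 feature_id = colnames(X)[selected] %||% as.character(selected),
                 relevance = relevance),
            class = "ranked_features")
}

#' @export
print.ranked_features <- function(x, ...) {
  cat("ranked_features:", length(x$order), "features; top 5:",
      paste(utils::head(x$feature_id, 5), collapse = ", "), "\n")
  invisible(x)
}

#' Write a ranked feature list as TSV (rank, feature_id, relevance)
#' @param ranked A `ranked_features` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ranked_features <- function(ranked, path) {
  write.table(data.frame(rank = seq_along(ranked$order),
                         feature_id = ranked$feature_id,
                         relevance = ranked$relevance[ranked$order]),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Align a gene_labels table (or plain label vector) with the rows of X;
# returns a factor with levels negative, positive.
align_labels <- function(X, y) {
  if (inherits(y, "gene_labels") || (is.data.frame(y) && "gene_id" %in% names(y))) {
    if (is.null(rownames(X))) stop_domain("X must have gene rownames to align labels")
    idx <- match(rownames(X), y$gene_id)
    if (anyNA(idx)) {
      stop_domain("labels missing for gene(s): ",
                  paste(utils::head(rownames(X)[is.na(idx)], 5), collapse = ", "))
    }
    y <- y$label[idx]
  }
  if (length(y) != nrow(X)) stop_domain("labels misaligned with matrix rows")
  factor(as.character(y), levels = c("negative", "positive"))
}
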