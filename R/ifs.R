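# Two-step incremental feature selection: a coarse prefix scan of the mRMR
# list with a fixed step, then an exhaustive scan of an interval around the
# coarse optimum; the subset maximizing cross-validated Youden's index wins.

#' Stage-1 prefix sizes
#'
#' @param n_features Total feature count (>= 1).
#' @param step Scan step (default 10).
#' @return Sizes `step, 2*step, ...` up to `n_features`, with `n_features`
#'   itself appended when it is not a multiple of `step`.
#' @export
stage1_sizes <- function(n_features, step = 10L) {
  if (n_features < 1L) stop_domain("n_features must be >= 1")
  if (step < 1L) stop_domain("step must be >= 1")
  sizes <- if (step > n_features) integer(0) else
    seq.int(step, n_features, by = step)
  if (length(sizes) == 0L || sizes[length(sizes)] != n_features) {
    sizes <- c(sizes, n_features)
  }
  as.integer(sizes)
}

#' Stage-2 interval around the coarse optimum
#'
#' @param best_size Stage-1 Youden argmax size.
#' @param width Half-width of the interval (default 50).
#' @param n_features Total feature count (upper clip).
#' @return Integer vector `c(lo, hi)` with `lo = max(1, best_size - width)`
#'   and `hi = min(n_features, best_size + width)`.
#' @export
stage2_interval <- function(best_size, width = 50L, n_features) {
  if (best_size < 1L) stop_domain("best_size must be >= 1")
  c(max(1L, as.integer(best_size - width)),
    min(as.integer(n_features), as.integer(best_size + width)))
}

#' Run two-step incremental feature selection
#'
#' Stage 1 cross-validates the classifier on prefixes of the ranked feature
#' list at every [stage1_sizes()] size; stage 2 does the same for every size
#' in the interval around the stage-1 Youden argmax (or an explicit
#' `interval` override).  One fold assignment (stratified by class) is drawn
#' once and reused for every size, so the curves are comparable.  The
#' optimum is the global Youden argmax over all evaluated sizes, ties broken
#' toward the smallest size; the optimum classifier is retrained on the full
#' data with the optimum prefix.
#'
#' @param X Samples x features matrix (e.g. a `feature_matrix`).
#' @param y Labels (`gene_labels` table or vector).
#' @param ranked A `ranked_features` permutation of `X`'s columns.
#' @param spec A `classifier_spec`.
#' @param step Stage-1 step (default 10).
#' @param width Stage-2 half-width (default 50).
#' @param folds Number of CV folds (default 10).
#' @param seed Integer seed for the fold assignment.
#' @param interval Optional explicit `c(lo, hi)` stage-2 interval override.
#' @return An `ifs_result` list: `stage1` and `stage2` data frames
#'   (n_features, SN, SP, ACC, MCC, J), `interval`, `optimum_size`,
#'   `optimum_metrics`, `optimum_classifier`, and `fold_assignment`.
#' @export
run_ifs <- function(X, y, ranked, spec, step = 10L, width = 50L,
                    folds = 10L, seed, interval = NULL) {
  X <- as.matrix(unclass(X))
  nf <- ncol(X)
  if (!setequal(ranked$order, seq_len(nf))) {
    stop_domain("ranked list is not a permutation of X's features")
  }
  y <- align_labels(X, y)
  fold_assignment <- kfold_assign(nrow(X), k = folds, seed = seed, strata = y)

  cache <- new.env(parent = emptyenv())
  eval_size <- function(sz) {
    key <- as.character(sz)
    if (!is.null(cache[[key]])) return(cache[[key]])
    cols <- ranked$order[seq_len(sz)]
    cc <- cross_validate(X[, cols, drop = FALSE], y, spec, fold_assignment)
    rec <- compute_metrics(cc)
    cache[[key]] <- rec
    rec
  }
  curve_df <- function(sizes) {
    recs <- lapply(sizes, eval_size)
    data.frame(n_features = sizes,
               SN = vapply(recs, `[[`, numeric(1), "SN"),
               SP = vapply(recs, `[[`, numeric(1), "SP"),
               ACC = vapply(recs, `[[`, numeric(1), "ACC"),
               MCC = vapply(recs, `[[`, numeric(1), "MCC"),
               J = vapply(recs, `[[`, numeric(1), "J"))
  }

  s1_sizes <- stage1_sizes(nf, step)
  stage1 <- curve_df(s1_sizes)
  best1 <- s1_sizes[which.max(stage1$J)]   # first max -> smallest size
  if (is.null(interval)) interval <- stage2_interval(best1, width, nf)
  s2_sizes <- seq.int(interval[1L], interval[2L])
  stage2 <- curve_df(s2_sizes)

  all_sizes <- c(stage1$n_features, stage2$n_features)
  all_J <- c(stage1$J, stage2$J)
  ord <- order(-all_J, all_sizes)          # max J, ties -> smallest size
  optimum_size <- all_sizes[ord[1L]]
  optimum_metrics <- eval_size(optimum_size)

  opt_cols <- ranked$order[seq_len(optimum_size)]
  optimum_classifier <- train(spec, X[, opt_cols, drop = FALSE], y)

  structure(list(stage1 = stage1, interval = as.integer(interval),
                 stage2 = stage2, optimum_size = optimum_size,
                 optimum_metrics = optimum_metrics,
                 optimum_classifier = optimum_classifier,
                 fold_assignment = fold_assignment),
            class = "ifs_result")
}

#' @export
print.ifs_result <- function(x, ...) {
  cat("ifs_result: optimum", x$optimum_size, "features; ")
  print(x$optimum_metrics)
  invisible(x)
}

#' Write an IFS curve (stage-1 or stage-2 data frame) as TSV
#' @param curve Data frame with columns n_features, SN, SP, ACC, MCC, J.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ifs_curve <- function(curve, path) {
  write.table(curve, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
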