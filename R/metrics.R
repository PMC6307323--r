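# 10-fold cross-validation harness and the five performance measures
# (SN, SP, ACC, MCC, Youden's J) computed from pooled confusion counts.

#' Assign samples to cross-validation folds
#'
#' Random balanced partition: fold sizes differ by at most one.  With
#' `strata` given (the default path in this package: the class labels), the
#' balance holds within each stratum as well — the shuffled members of each
#' stratum are dealt cyclically onto folds, continuing one global counter
#' across strata so overall fold sizes stay balanced too.
#'
#' @param n Sample count (>= k).
#' @param k Number of folds (>= 2); default 10.
#' @param seed Integer seed; the assignment is deterministic given it.
#' @param strata Optional vector of length `n`; class labels to stratify by.
#' @return Integer vector of fold indices in `1..k`, one per sample.
#' @export
kfold_assign <- function(n, k = 10L, seed, strata = NULL) {
  if (k < 2L) stop_domain("k must be >= 2")
  if (n < k) stop_domain("n (", n, ") must be >= k (", k, ")")
  if (!is.null(strata) && length(strata) != n) {
    stop_domain("strata must have length n")
  }
  with_seed(seed, {
    fold <- integer(n)
    counter <- 0L
    groups <- if (is.null(strata)) list(seq_len(n)) else
      split(seq_len(n), strata, drop = TRUE)
    for (idx in groups) {
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- ((counter + seq_along(idx) - 1L) %% k) + 1L
      counter <- counter + length(idx)
    }
    structure(fold, seed = as.integer(seed), k = as.integer(k))
  })
}

#' Cross-validate a classifier, pooling held-out confusion counts
#'
#' For each fold, trains on the complement and predicts the held-out fold;
#' all held-out predictions are pooled into a single set of confusion
#' counts (so each model yields one SN/SP/ACC/MCC/J record).
#'
#' @param X Samples x features matrix.
#' @param y Labels (`gene_labels` table or vector; see [train()]).
#' @param spec A `classifier_spec`.
#' @param folds Integer fold assignment from [kfold_assign()].
#' @return A `confusion_counts` list: TP, TN, FP, FN.
#' @export
cross_validate <- function(X, y, spec, folds) {
  y <- align_labels(X, y)
  if (length(folds) != nrow(X)) stop_domain("folds must cover all rows")
  TP <- TN <- FP <- FN <- 0L
  for (f in sort(unique(folds))) {
    test_idx <- which(folds == f)
    train_idx <- which(folds != f)
    ytr <- y[train_idx]
    if (length(unique(ytr)) < 2L) {
      stop_domain("training complement of fold ", f, " contains one class only")
    }
    clf <- train(spec, X[train_idx, , drop = FALSE], ytr)
    pred <- predict(clf, X[test_idx, , drop = FALSE])
    truth <- y[test_idx]
    TP <- TP + sum(pred == "positive" & truth == "positive")
    TN <- TN + sum(pred == "negative" & truth == "negative")
    FP <- FP + sum(pred == "positive" & truth == "negative")
    FN <- FN + sum(pred == "negative" & truth == "positive")
  }
  confusion_counts(TP, TN, FP, FN)
}

#' Construct confusion counts
#' @param TP,TN,FP,FN Non-negative integer counts.
#' @return A `confusion_counts` list.
#' @export
confusion_counts <- function(TP, TN, FP, FN) {
  counts <- c(TP = TP, TN = TN, FP = FP, FN = FN)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_domain("confusion counts must be non-negative integers")
  }
  structure(as.list(counts), class = "confusion_counts")
}

#' Compute SN, SP, ACC, MCC and Youden's index from confusion counts
#'
#' SN = TP/(TP+FN); SP = TN/(TN+FP); ACC = (TP+TN)/total;
#' MCC = (TP TN - FP FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)), defined as 0
#' when any factor of the denominator is 0; J = SN + SP - 1.  Youden's J is
#' the model-selection criterion under class imbalance: unlike ACC it gives
#' the minority class equal weight.
#'
#' @param cc A `confusion_counts` (requires TP+FN > 0 and TN+FP > 0: both
#'   classes present in the truth).
#' @return A `metrics_record` list: SN, SP, ACC, MCC, J.
#' @export
compute_metrics <- function(cc) {
  TP <- cc$TP; TN <- cc$TN; FP <- cc$FP; FN <- cc$FN
  if (TP + FN == 0) stop_domain("no positive samples in truth")
  if (TN + FP == 0) stop_domain("no negative samples in truth")
  SN <- TP / (TP + FN)
  SP <- TN / (TN + FP)
  ACC <- (TP + TN) / (TP + TN + FP + FN)
  denom <- as.numeric(TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  MCC <- if (denom == 0) 0 else
    (as.numeric(TP) * TN - as.numeric(FP) * FN) / sqrt(denom)
  structure(list(SN = SN, SP = SP, ACC = ACC, MCC = MCC, J = SN + SP - 1),
            class = "metrics_record")
}

#' @export
print.metrics_record <- function(x, ...) {
  cat(sprintf("SN=%.3f SP=%.3f ACC=%.3f MCC=%.3f J=%.3f\n",
              x$SN, x$SP, x$ACC, x$MCC, x$J))
  invisible(x)
}

#' Reconstruct confusion counts from SN, SP and class sizes
#'
#' Inverts the metric definitions at a given precision: TP = round(SN * P),
#' TN = round(SP * N).  Useful for re-deriving ACC/MCC/J from published
#' sensitivity/specificity values and known class sizes.
#'
#' @param SN,SP Sensitivity and specificity.
#' @param n_positive,n_negative Class sizes.
#' @return A `confusion_counts`.
#' @export
confusion_from_rates <- function(SN, SP, n_positive, n_negative) {
  TP <- round(SN * n_positive)
  TN <- round(SP * n_negative)
  confusion_counts(TP, TN, FP = n_negative - TN, FN = n_positive - TP)
}
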