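# Post-hoc comparisons of ranked lists and optimum feature sets: top-k
# Jaccard curves and per-namespace tallies.

#' Jaccard coefficient of two feature sets
#' @param a,b Character vectors (treated as sets); not both empty.
#' @return `|a intersect b| / |a union b|`.
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- union(a, b)
  if (length(u) == 0L) stop_domain("both sets are empty")
  length(intersect(a, b)) / length(u)
}

#' Top-k Jaccard curve of two ranked feature lists
#'
#' For each k, the Jaccard coefficient of the two k-prefixes — how much the
#' top of one ranking agrees with the top of the other.
#'
#' @param listA,listB `ranked_features` objects (or character vectors of
#'   feature ids in rank order).
#' @param ks Prefix sizes; default `10, 20, ...` up to the shorter list.
#' @return A `jaccard_curve` data frame with columns `k` and `jaccard`.
#' @export
topk_jaccard_curve <- function(listA, listB, ks = NULL) {
  ida <- if (inherits(listA, "ranked_features")) listA$feature_id else as.character(listA)
  idb <- if (inherits(listB, "ranked_features")) listB$feature_id else as.character(listB)
  if (is.null(ks)) {
    kmax <- min(length(ida), length(idb))
    ks <- if (kmax < 10L) kmax else unique(c(seq.int(10L, kmax, by = 10L), kmax))
  }
  if (any(ks < 1L) || any(ks > length(ida)) || any(ks > length(idb))) {
    stop_domain("every k must lie within both list lengths")
  }
  j <- vapply(ks, function(k) jaccard(ida[seq_len(k)], idb[seq_len(k)]),
              numeric(1))
  structure(data.frame(k = as.integer(ks), jaccard = j),
            class = c("jaccard_curve", "data.frame"))
}

#' Tally feature ids by term namespace
#'
#' @param features Character vector of term/feature ids (all must exist in
#'   `terms`).
#' @param terms A `term_collection`.
#' @return Named integer vector with counts for BP, CC, MF and KEGG, summing
#'   to `length(unique(features))`.
#' @export
namespace_tally <- function(features, terms) {
  features <- unique(as.character(features))
  idx <- match(features, terms$term_id)
  if (anyNA(idx)) {
    stop_domain("unknown feature id(s): ",
                paste(utils::head(features[is.na(idx)], 5), collapse = ", "))
  }
  ns <- factor(terms$namespace[idx], levels = c("BP", "CC", "MF", "KEGG"))
  tab <- table(ns)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}
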