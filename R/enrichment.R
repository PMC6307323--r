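# Enrichment encoding: each gene becomes a vector of -log10 hypergeometric
# upper-tail p-values measuring the overlap between its PPI neighbor set and
# each GO/KEGG term's annotated gene set.

#' Enrichment encoding configuration
#'
#' @param universe_size_policy How the universe size N of the hypergeometric
#'   test is chosen: `"network_nodes"` (default; the number of nodes in the
#'   PPI network, self-consistent with the source of the neighbor sets),
#'   `"annotated_union"` (union of all term gene sets and network nodes), or
#'   `"explicit"` with `universe_size` set.
#' @param universe_size Explicit N (required when policy is `"explicit"`).
#' @param score_cap Maximum enrichment score; p-values underflowing to 0 are
#'   reported at the cap (default 300, i.e. p = 1e-300).
#' @param include_self Whether a gene belongs to its own neighbor set
#'   (default `FALSE`: the neighbor set holds only interacting partners).
#' @return An `enrichment_config` list.
#' @export
enrichment_config <- function(universe_size_policy = c("network_nodes",
                                                       "annotated_union",
                                                       "explicit"),
                              universe_size = NULL,
                              score_cap = 300,
                              include_self = FALSE) {
  universe_size_policy <- match.arg(universe_size_policy)
  if (score_cap <= 0) stop_domain("score_cap must be > 0")
  if (universe_size_policy == "explicit") {
    if (is.null(universe_size) || universe_size < 1) {
      stop_domain("explicit policy requires universe_size >= 1")
    }
  }
  structure(list(universe_size_policy = universe_size_policy,
                 universe_size = universe_size,
                 score_cap = score_cap,
                 include_self = isTRUE(include_self)),
            class = "enrichment_config")
}

#' PPI neighbor set of a gene
#'
#' @param ppi A `ppi_network`.
#' @param gene Gene identifier (may be absent from the network).
#' @param config An `enrichment_config`; `include_self` controls whether the
#'   gene itself is part of the set.
#' @return Character vector of neighbor gene ids (empty if the gene is
#'   isolated or absent).
#' @export
neighbor_set <- function(ppi, gene, config = enrichment_config()) {
  nb <- ppi$adjacency[[gene]]
  if (is.null(nb)) nb <- character(0)
  if (config$include_self) nb <- sort(unique(c(nb, gene)))
  nb
}

#' Hypergeometric upper-tail probability of an overlap
#'
#' The inclusive upper tail P(X >= m) where X is the overlap between a
#' neighbor set of size `n` and a term set of size `M` drawn from a universe
#' of `N` genes: sum over k = m..n of choose(M,k) choose(N-M,n-k) /
#' choose(N,n).  Computed via [stats::phyper], which is numerically stable
#' for universes well beyond 1e5.
#'
#' @param N Universe size.
#' @param M Term-set size (genes annotated to the term, within the universe).
#' @param n Neighbor-set size.
#' @param m Overlap size.
#' @return The tail probability, in (0, 1].
#' @export
hypergeom_tail_p <- function(N, M, n, m) {
  if (any(c(N, M, n, m) < 0) || m > min(n, M) || n > N || M > N) {
    stop_domain("hypergeometric bounds violated: need 0 <= m <= min(n, M), ",
                "n <= N, M <= N (got N=", N, ", M=", M, ", n=", n, ", m=", m, ")")
  }
  # P(X >= m) = 1 - P(X <= m - 1)
  phyper(m - 1, M, N - M, n, lower.tail = FALSE)
}

#' Convert a tail p-value into an enrichment score
#'
#' @param p P-value in (0, 1].  Values that underflowed to 0 are clamped to
#'   the cap with a warning.
#' @param config An `enrichment_config` supplying `score_cap`.
#' @return `-log10(p)`, capped at `config$score_cap`; `p = 1` gives 0.
#' @export
enrichment_score <- function(p, config = enrichment_config()) {
  out <- numeric(length(p))
  under <- p <= 0
  if (any(under)) {
    warning(sum(under), " p-value(s) underflowed to 0; reported at score_cap",
            call. = FALSE)
    out[under] <- config$score_cap
  }
  out[!under] <- pmin(-log10(p[!under]), config$score_cap)
  out
}

#' Encode genes as GO/KEGG enrichment-score vectors
#'
#' For every gene with a non-empty PPI neighbor set, computes one enrichment
#' score per term: `-log10` of the hypergeometric upper-tail probability of
#' the overlap between the gene's neighbor set and the term's gene set
#' (both intersected with the universe).  Genes with empty neighbor sets
#' carry no enrichment information and are discarded; their ids are recorded
#' in the `discarded` attribute of the result.
#'
#' Feature columns are ordered GO namespaces first (BP, CC, MF, each sorted
#' by term id) then KEGG (sorted by term id), and the order is fixed in the
#' matrix's colnames.
#'
#' @param genes Character vector of gene ids to encode.
#' @param ppi A `ppi_network` supplying neighbor sets (and, under the
#'   default universe policy, the universe).
#' @param terms A `term_collection`.
#' @param config An `enrichment_config`.
#' @return A `feature_matrix`: numeric genes x terms matrix with attributes
#'   `namespace` (per column), `discarded` (gene ids dropped) and `config`.
#' @export
encode_genes <- function(genes, ppi, terms, config = enrichment_config()) {
  if (length(terms) == 0L) stop_domain("term collection is empty")
  genes <- as.character(genes)

  universe <- switch(config$universe_size_policy,
    network_nodes = network_nodes(ppi),
    annotated_union = sort(unique(c(network_nodes(ppi),
                                    unlist(terms$genes, use.names = FALSE)))),
    explicit = NULL)
  if (is.null(universe)) {
    N <- as.numeric(config$universe_size)
    universe <- network_nodes(ppi)   # membership restriction still applies
  } else {
    N <- length(universe)
  }

  # fixed feature order: GO namespaces then KEGG, ids sorted within each
  ns_order <- c("BP", "CC", "MF", "KEGG")
  ord <- order(match(terms$namespace, ns_order), terms$term_id)
  term_id <- terms$term_id[ord]
  term_ns <- terms$namespace[ord]
  term_genes <- terms$genes[ord]

  # integer-index the universe for fast overlap counting
  idx <- seq_along(universe)
  names(idx) <- universe
  term_idx <- lapply(term_genes, function(g) unname(idx[g[g %in% universe]]))
  M <- lengths(term_idx)
  if (any(M > N)) stop_domain("term set larger than explicit universe size")

  nb_sets <- lapply(genes, function(g) neighbor_set(ppi, g, config))
  nb_sizes <- lengths(nb_sets)
  discarded <- genes[nb_sizes == 0L]
  keep <- nb_sizes > 0L
  if (!any(keep)) {
    stop_domain("all genes have empty neighbor sets; nothing to encode")
  }
  kept_genes <- genes[keep]
  if (any(nb_sizes[keep] > N)) {
    stop_domain("a neighbor set exceeds the universe size N")
  }

  scores <- matrix(0, nrow = length(kept_genes), ncol = length(term_id),
                   dimnames = list(kept_genes, term_id))
  kept_nb <- nb_sets[keep]
  in_nb <- logical(N)
  for (i in seq_along(kept_genes)) {
    nb <- unname(idx[kept_nb[[i]]])
    nb <- nb[!is.na(nb)]
    in_nb[nb] <- TRUE
    m <- vapply(term_idx, function(ti) sum(in_nb[ti]), numeric(1))
    in_nb[nb] <- FALSE
    n <- length(nb)
    p <- phyper(m - 1, M, N - M, n, lower.tail = FALSE)
    scores[i, ] <- enrichment_score(p, config)
  }

  structure(scores,
            class = c("feature_matrix", "matrix", "array"),
            namespace = term_ns,
            discarded = discarded,
            config = config)
}

#' Write a feature matrix as TSV with a JSON config sidecar
#' @param fm A `feature_matrix`.
#' @param path Output TSV path; the sidecar is written to `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- data.frame(gene_id = rownames(fm), as.data.frame(unclass(fm)),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- attr(fm, "config")
  meta <- list(namespace = attr(fm, "namespace"),
               discarded = attr(fm, "discarded"),
               config = list(universe_size_policy = cfg$universe_size_policy,
                             universe_size = cfg$universe_size,
                             score_cap = cfg$score_cap,
                             include_self = cfg$include_self))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#' @param path TSV path (the `.json` sidecar is read if present).
#' @return A `feature_matrix`.
#' @export
read_feature_matrix <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[-1L])
  rownames(m) <- df[[1L]]
  ns <- NULL; cfg <- enrichment_config(); disc <- character(0)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    ns <- meta$namespace
    disc <- meta$discarded %||% character(0)
    cfg <- enrichment_config(
      universe_size_policy = meta$config$universe_size_policy,
      universe_size = meta$config$universe_size,
      score_cap = meta$config$score_cap,
      include_self = meta$config$include_self)
  }
  structure(m, class = c("feature_matrix", "matrix", "array"),
            namespace = ns, discarded = disc, config = cfg)
}
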