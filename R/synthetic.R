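# Synthetic-data generators emulating the statistical structure the
# analysis assumes: a background PPI graph, term collections across four
# namespaces, imbalanced binary gene classes, and a planted signal in which
# positive-class genes acquire extra edges into the gene sets of a chosen
# subset of "informative" terms — so their neighbor sets are enriched for
# those terms, exactly the pathway the enrichment encoding measures.

#' Synthetic dataset configuration
#'
#' Defaults describe the benchmark conditions used throughout the package's
#' validation: a few hundred genes, a 300-term collection dominated by BP
#' (as real GO is), a sparse background interactome, ~4.7 widely expressed
#' genes per rarely expressed one, and 15 informative terms.
#'
#' @param n_genes Gene universe size (default 600).
#' @param n_terms Named counts per namespace (default BP 150, CC 50, MF 60,
#'   KEGG 40).
#' @param term_size_range Min/max genes per term (default c(10, 30)).
#' @param ppi_mean_degree Expected background degree (default 10).
#' @param n_informative Number of planted informative terms (default 15).
#' @param effect_strength Probability of an extra edge from each
#'   positive-class gene to each member of each informative term's gene set,
#'   in \[0, 1\] (default 0.5).
#' @param imbalance Positive:negative class ratio (default 4.7).
#' @param seed Integer seed (mandatory).
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_genes = 600L,
                             n_terms = c(BP = 150L, CC = 50L, MF = 60L, KEGG = 40L),
                             term_size_range = c(10L, 30L),
                             ppi_mean_degree = 10,
                             n_informative = 15L,
                             effect_strength = 0.5,
                             imbalance = 4.7,
                             seed) {
  if (missing(seed)) stop_domain("seed is mandatory")
  if (!all(c("BP", "CC", "MF", "KEGG") %in% names(n_terms))) {
    stop_domain("n_terms must name BP, CC, MF and KEGG counts")
  }
  if (n_informative > sum(n_terms)) {
    stop_domain("n_informative exceeds the total number of terms")
  }
  if (effect_strength < 0 || effect_strength > 1) {
    stop_domain("effect_strength must lie in [0, 1]")
  }
  if (n_genes < 1L || any(n_terms < 1L) || term_size_range[1L] < 1L ||
      term_size_range[2L] < term_size_range[1L]) {
    stop_domain("counts must be >= 1 and term_size_range non-degenerate")
  }
  if (term_size_range[2L] > n_genes) {
    stop_domain("term sizes cannot exceed n_genes")
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_terms = n_terms,
                 term_size_range = as.integer(term_size_range),
                 ppi_mean_degree = ppi_mean_degree,
                 n_informative = as.integer(n_informative),
                 effect_strength = effect_strength,
                 imbalance = imbalance,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic PPI network, term collection and gene labels
#'
#' The background interactome is an Erdős–Rényi graph with edge probability
#' `ppi_mean_degree / (n_genes - 1)`; edge confidences are uniform on
#' \[0.4, 1\].  Term gene sets are sampled uniformly from the universe with
#' sizes uniform in `term_size_range`.  Class labels follow the imbalance
#' ratio.  For each positive-class gene, an extra edge to each member of
#' each informative term's gene set is added with probability
#' `effect_strength`; at `effect_strength = 0` the construction is an exact
#' null.  Fully deterministic given the seed.
#'
#' @param config A `synthetic_config`.
#' @return List with `ppi` (`ppi_network`), `terms` (`term_collection`),
#'   `labels` (`gene_labels`) and `informative_terms` (character vector of
#'   the planted term ids).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    n <- config$n_genes
    genes <- sprintf("g%04d", seq_len(n))

    # class labels at the imbalance ratio
    n_pos <- round(n * config$imbalance / (config$imbalance + 1))
    pos_genes <- genes[seq_len(n_pos)]
    labels <- gene_labels(genes, rep(c("positive", "negative"),
                                     c(n_pos, n - n_pos)))

    # term collections: ids unique across namespaces
    ns_names <- c("BP", "CC", "MF", "KEGG")
    term_id <- character(0); term_ns <- character(0)
    for (ns in ns_names) {
      cnt <- config$n_terms[[ns]]
      term_id <- c(term_id, sprintf("%s%04d", ns, seq_len(cnt)))
      term_ns <- c(term_ns, rep(ns, cnt))
    }
    sizes <- sample(config$term_size_range[1L]:config$term_size_range[2L],
                    length(term_id), replace = TRUE)
    gene_sets <- lapply(sizes, function(s) sort(sample(genes, s)))
    terms <- term_collection(term_id, term_ns, gene_sets)

    informative <- sort(sample(term_id, config$n_informative))

    # Erdős–Rényi background
    p_edge <- min(1, config$ppi_mean_degree / (n - 1))
    pairs <- utils::combn(n, 2L)
    keep <- runif(ncol(pairs)) < p_edge
    ea <- genes[pairs[1L, keep]]
    eb <- genes[pairs[2L, keep]]

    # planted signal: positive genes gain edges into informative term sets
    if (config$effect_strength > 0 && config$n_informative > 0L) {
      inf_sets <- terms$genes[match(informative, terms$term_id)]
      for (g in pos_genes) {
        targets <- unlist(inf_sets, use.names = FALSE)
        hit <- targets[runif(length(targets)) < config$effect_strength]
        hit <- hit[hit != g]
        if (length(hit) > 0L) {
          ea <- c(ea, rep(g, length(hit)))
          eb <- c(eb, hit)
        }
      }
    }
    conf <- runif(length(ea), 0.4, 1)
    ppi <- suppressWarnings(ppi_network(ea, eb, conf))

    list(ppi = ppi, terms = terms, labels = labels,
         informative_terms = informative)
  })
}

#' Generate a feature matrix with planted informative columns
#'
#' A direct generator for unit-testing the ranking and selection stages in
#' isolation.  Null features are folded-normal, `|N(0, 1)|` — non-negative
#' and right-skewed, resembling -log10 p-value scores; the first
#' `n_informative` columns are shifted upward by `shift` in the positive
#' class.  Deterministic given the seed.
#'
#' @param n_samples Number of rows.
#' @param n_features Number of columns (>= n_informative).
#' @param n_informative Number of shifted columns (these are columns
#'   `1..n_informative`, named in the `informative` attribute).
#' @param shift Upward mean shift (in null SD units, the folded-normal SD
#'   being ~0.6) applied to informative features of positive samples.
#' @param imbalance Positive:negative ratio (default 4.7).
#' @param seed Integer seed.
#' @return List with `features` (`feature_matrix` with an `informative`
#'   attribute) and `labels` (`gene_labels`).
#' @export
generate_feature_matrix <- function(n_samples, n_features, n_informative,
                                    shift, imbalance = 4.7, seed) {
  if (n_informative > n_features) {
    stop_domain("n_informative must be <= n_features")
  }
  if (n_samples < 2L || n_features < 1L || n_informative < 0L) {
    stop_domain("invalid counts")
  }
  with_seed(seed, {
    ids <- sprintf("s%04d", seq_len(n_samples))
    n_pos <- round(n_samples * imbalance / (imbalance + 1))
    labels <- gene_labels(ids, rep(c("positive", "negative"),
                                   c(n_pos, n_samples - n_pos)))
    X <- matrix(abs(rnorm(n_samples * n_features)), n_samples, n_features,
                dimnames = list(ids, sprintf("f%04d", seq_len(n_features))))
    if (n_informative > 0L && shift != 0) {
      X[seq_len(n_pos), seq_len(n_informative)] <-
        X[seq_len(n_pos), seq_len(n_informative)] + shift
    }
    fm <- structure(X, class = c("feature_matrix", "matrix", "array"),
                    informative = colnames(X)[seq_len(n_informative)])
    list(features = fm, labels = labels)
  })
}
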