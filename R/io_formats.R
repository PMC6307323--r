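# Readers/writers for the plain-text formats the pipeline touches, plus the
# FPKM-threshold labeling rule that defines the two gene classes.

#' Read a genes-by-samples expression table
#'
#' Parses a TSV whose header row holds sample identifiers and whose first
#' column holds gene identifiers; all remaining cells must be finite,
#' non-negative FPKM values.
#'
#' @param path Path to a tab-separated file.
#' @return An `expression_table`: a numeric matrix (genes x samples) with
#'   gene ids as rownames and sample ids as colnames.
#' @export
read_expression_table <- function(path) {
  if (!file.exists(path)) stop_format("file not found: ", path)
  df <- tryCatch(
    read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
               colClasses = "character", stringsAsFactors = FALSE),
    error = function(e) stop_format("cannot parse expression TSV: ", conditionMessage(e))
  )
  if (nrow(df) == 0L || ncol(df) < 2L) {
    stop_format("expression table is empty or has no sample columns")
  }
  gene_ids <- df[[1L]]
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup) > 0L) {
    stop_format("duplicate gene id(s): ", paste(unique(dup), collapse = ", "))
  }
  sample_ids <- colnames(df)[-1L]
  if (anyDuplicated(sample_ids)) stop_format("duplicate sample ids in header")
  vals <- suppressWarnings(vapply(df[-1L], as.numeric, numeric(nrow(df))))
  vals <- matrix(vals, nrow = nrow(df),
                 dimnames = list(gene_ids, sample_ids))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop_format("non-numeric or missing value at gene '", gene_ids[bad[1L]],
                "', sample '", sample_ids[bad[2L]], "'")
  }
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop_format("expression values must be finite and >= 0")
  }
  structure(vals, class = c("expression_table", "matrix", "array"))
}

#' Write an expression table as TSV
#' @param expr An `expression_table` (or genes x samples numeric matrix).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), as.data.frame(unclass(expr)),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Label genes as widely or rarely expressed by an FPKM threshold
#'
#' A gene is labeled `positive` (widely expressed) iff its FPKM exceeds
#' `threshold` in every sample and `negative` (rarely expressed) iff its FPKM
#' is below `threshold` in every sample.  Both inequalities are strict, so a
#' gene exactly at the threshold in any sample, or above it in some samples
#' and below in others, matches neither class and is omitted from the output.
#'
#' @param expr An `expression_table`.
#' @param threshold Positive FPKM cutoff (default 1).
#' @return A `gene_labels` data frame with columns `gene_id` and `label`
#'   (factor, levels `negative`, `positive`).
#' @export
label_genes_by_expression <- function(expr, threshold = 1) {
  if (is.null(dim(expr)) || nrow(expr) == 0L || ncol(expr) == 0L) {
    stop_domain("expression table is empty")
  }
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    stop_domain("threshold must be a single positive number")
  }
  pos <- rowSums(expr > threshold) == ncol(expr)
  neg <- rowSums(expr < threshold) == ncol(expr)
  gene_labels(
    gene_id = c(rownames(expr)[pos], rownames(expr)[neg]),
    label = rep(c("positive", "negative"), c(sum(pos), sum(neg)))
  )
}

#' Construct a gene label table
#' @param gene_id Character vector of unique gene ids.
#' @param label Character/factor vector with values `positive` / `negative`.
#' @return A `gene_labels` data frame.
#' @export
gene_labels <- function(gene_id, label) {
  gene_id <- as.character(gene_id)
  if (anyDuplicated(gene_id)) {
    stop_format("duplicate gene id(s) in label table: ",
                paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "))
  }
  label <- as.character(label)
  if (!all(label %in% c("positive", "negative"))) {
    stop_format("labels must be 'positive' or 'negative'")
  }
  structure(
    data.frame(gene_id = gene_id,
               label = factor(label, levels = c("negative", "positive"))),
    class = c("gene_labels", "data.frame")
  )
}

#' Read a gene label TSV (columns gene_id, label)
#' @param path Path to a TSV with header `gene_id`, `label`.
#' @return A `gene_labels` data frame.
#' @export
read_gene_labels <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("gene_id", "label") %in% colnames(df))) {
    stop_format("label TSV must have columns gene_id, label")
  }
  gene_labels(df$gene_id, df$label)
}

#' Write a gene label table as TSV
#' @param labels A `gene_labels` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_labels <- function(labels, path) {
  write.table(data.frame(gene_id = labels$gene_id,
                         label = as.character(labels$label)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read term collections from GMT files
#'
#' Standard GMT: one term per line, tab-separated `term_id`, description,
#' then member gene ids.  Terms with no genes are dropped with a warning.
#' Several files can be merged, each contributing one namespace.
#'
#' @param paths Character vector of GMT file paths.
#' @param namespaces Namespace per file, each one of `"BP"`, `"CC"`, `"MF"`,
#'   `"KEGG"` (recycled to `length(paths)` if length 1).
#' @return A `term_collection`: list with `term_id`, `namespace` (both
#'   character vectors) and `genes` (list of character vectors), aligned.
#' @export
read_gmt <- function(paths, namespaces) {
  if (length(namespaces) == 1L) namespaces <- rep(namespaces, length(paths))
  if (length(namespaces) != length(paths)) {
    stop_format("namespaces must have length 1 or length(paths)")
  }
  ids <- character(0); ns <- character(0); genes <- list()
  for (i in seq_along(paths)) {
    lines <- readLines(paths[i], warn = FALSE)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      fields <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
      if (length(fields) < 2L) stop_format("malformed GMT line: ", substr(ln, 1, 60))
      members <- unique(fields[-(1:2)])
      members <- members[nzchar(members)]
      if (length(members) == 0L) {
        warning("dropping term '", fields[1L], "': empty gene set", call. = FALSE)
        next
      }
      ids <- c(ids, fields[1L])
      ns <- c(ns, namespaces[i])
      genes <- c(genes, list(members))
    }
  }
  term_collection(ids, ns, genes)
}

#' Construct a term collection
#' @param term_id Unique term identifiers.
#' @param namespace One of `BP`, `CC`, `MF`, `KEGG` per term.
#' @param genes List of non-empty character vectors of member gene ids.
#' @return A `term_collection`.
#' @export
term_collection <- function(term_id, namespace, genes) {
  term_id <- as.character(term_id)
  if (anyDuplicated(term_id)) {
    stop_format("duplicate term id(s): ",
                paste(unique(term_id[duplicated(term_id)]), collapse = ", "))
  }
  namespace <- as.character(namespace)
  if (!all(namespace %in% c("BP", "CC", "MF", "KEGG"))) {
    stop_format("namespace must be one of BP, CC, MF, KEGG")
  }
  if (length(genes) != length(term_id) || length(namespace) != length(term_id)) {
    stop_format("term_id, namespace and genes must be aligned")
  }
  if (any(lengths(genes) == 0L)) stop_format("every term gene set must be non-empty")
  structure(list(term_id = term_id, namespace = namespace,
                 genes = lapply(genes, as.character)),
            class = "term_collection")
}

#' @export
length.term_collection <- function(x) length(x$term_id)

#' @export
print.term_collection <- function(x, ...) {
  cat("term_collection:", length(x), "terms (",
      paste(names(table(x$namespace)), table(x$namespace),
            sep = "=", collapse = ", "),
      "); median set size", stats::median(lengths(x$genes)), "\n")
  invisible(x)
}

#' Write a term collection to a GMT file
#' @param terms A `term_collection`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(terms, path) {
  lines <- vapply(seq_along(terms$term_id), function(i) {
    paste(c(terms$term_id[i], terms$namespace[i], terms$genes[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a protein-protein interaction edge list
#'
#' Expects a TSV with three columns: gene_a, gene_b, score.  Scores are
#' either already in \[0, 1\] (`scale = "unit"`) or in the STRING 0-1000
#' dialect (`scale = "string_1000"`, divided by 1000).  Self-loops are
#' dropped with a warning; duplicate (unordered) pairs are collapsed keeping
#' the maximum confidence; edges below `min_confidence` are removed.
#'
#' @param path Path to the edge TSV (header row expected).
#' @param min_confidence Minimum confidence kept, in \[0, 1\] (default 0:
#'   keep all edges).
#' @param scale `"unit"` or `"string_1000"`.
#' @return A `ppi_network`.
#' @export
read_ppi_edges <- function(path, min_confidence = 0, scale = c("unit", "string_1000")) {
  scale <- match.arg(scale)
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop_format("edge TSV needs 3 columns: gene_a, gene_b, score")
  score <- as.numeric(df[[3L]])
  if (anyNA(score)) stop_format("non-numeric confidence score")
  if (any(score < 0)) stop_format("negative confidence score")
  if (scale == "string_1000") score <- score / 1000
  if (any(score > 1)) stop_format("confidence > 1 after normalization; check 'scale'")
  ppi_network(df[[1L]], df[[2L]], score, min_confidence = min_confidence)
}

#' Construct a PPI network from edge vectors
#'
#' @param gene_a,gene_b Character vectors of endpoints.
#' @param confidence Numeric confidence in \[0, 1\] per edge.
#' @param min_confidence Drop edges strictly below this confidence.
#' @return A `ppi_network`: list with `edges` (data frame gene_a, gene_b,
#'   confidence; gene_a < gene_b lexicographically) and `adjacency` (named
#'   list mapping each node to its neighbor set).
#' @export
ppi_network <- function(gene_a, gene_b, confidence, min_confidence = 0) {
  gene_a <- as.character(gene_a); gene_b <- as.character(gene_b)
  confidence <- as.numeric(confidence)
  if (length(gene_a) != length(gene_b) || length(gene_a) != length(confidence)) {
    stop_format("gene_a, gene_b and confidence must be aligned")
  }
  if (any(confidence < 0 | confidence > 1)) {
    stop_format("confidence must lie in [0, 1]")
  }
  loops <- gene_a == gene_b
  if (any(loops)) {
    warning("dropping ", sum(loops), " self-loop(s)", call. = FALSE)
    gene_a <- gene_a[!loops]; gene_b <- gene_b[!loops]
    confidence <- confidence[!loops]
  }
  # canonical unordered pair, collapse duplicates keeping max confidence
  lo <- pmin(gene_a, gene_b); hi <- pmax(gene_a, gene_b)
  key <- paste(lo, hi, sep = "\r")
  if (anyDuplicated(key)) {
    confidence <- vapply(split(confidence, key), max, numeric(1))
    pair <- strsplit(names(confidence), "\r", fixed = TRUE)
    lo <- vapply(pair, `[`, character(1), 1L)
    hi <- vapply(pair, `[`, character(1), 2L)
  }
  keep <- confidence >= min_confidence
  edges <- data.frame(gene_a = lo[keep], gene_b = hi[keep],
                      confidence = unname(confidence[keep]),
                      stringsAsFactors = FALSE)
  o <- order(edges$gene_a, edges$gene_b)
  edges <- edges[o, , drop = FALSE]
  rownames(edges) <- NULL
  adjacency <- build_adjacency(edges)
  structure(list(edges = edges, adjacency = adjacency), class = "ppi_network")
}

build_adjacency <- function(edges) {
  nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  adj <- c(split(edges$gene_b, factor(edges$gene_a, levels = nodes)),
           split(edges$gene_a, factor(edges$gene_b, levels = nodes)))
  adj <- tapply(unlist(adj, use.names = FALSE),
                rep(names(adj), lengths(adj)), function(v) sort(unique(v)),
                simplify = FALSE)
  out <- vector("list", length(nodes)); names(out) <- nodes
  out[names(adj)] <- adj
  out
}

#' Network node set
#' @param ppi A `ppi_network`.
#' @return Sorted character vector of node ids.
#' @export
network_nodes <- function(ppi) names(ppi$adjacency)

#' @export
print.ppi_network <- function(x, ...) {
  cat("ppi_network:", length(x$adjacency), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Convert a PPI network to an igraph graph
#' @param ppi A `ppi_network`.
#' @return An undirected weighted [igraph::graph] with a `confidence` edge
#'   attribute.
#' @export
as_igraph <- function(ppi) {
  igraph::graph_from_data_frame(ppi$edges, directed = FALSE)
}

#' Write a PPI network edge list as TSV (unit-scale confidences)
#' @param ppi A `ppi_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ppi_edges <- function(ppi, path) {
  write.table(ppi$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
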