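# Pipeline orchestration: label -> encode -> rank -> ifs -> evaluate ->
# compare, writing every intermediate artifact plus a run manifest.

#' Run the full classification pipeline
#'
#' Executes the chain on either synthetic inputs (when `config$synthetic`
#' is given) or files on disk: gene labeling (from an expression table or a
#' label TSV), enrichment encoding against the PPI network and term
#' collection, mRMR ranking, two-step incremental feature selection with
#' cross-validation, and a namespace tally of the optimum feature set.
#' Every artifact is written under `config$outdir` and listed, with an md5
#' checksum, in `manifest.json`.  A single global seed derives per-stage
#' seeds by fixed offsets, so one integer reproduces the whole run.
#'
#' @param config A named list (or path to a JSON file holding one) with
#'   entries:
#'   \describe{
#'     \item{outdir}{Output directory (created if needed).}
#'     \item{seed}{Global integer seed.}
#'     \item{synthetic}{Optional list of [synthetic_config()] arguments
#'       (minus `seed`); when present, inputs are generated.}
#'     \item{expression, labels, ppi, gmt, gmt_namespaces}{Input paths when
#'       `synthetic` is absent: either `expression` (TSV, labeled at
#'       `fpkm_threshold`, default 1) or `labels` (TSV), plus `ppi` and
#'       `gmt` (vector) with `gmt_namespaces`.}
#'     \item{min_confidence, ppi_scale}{Edge-filter options for `ppi`.}
#'     \item{score_cap, include_self, universe_size_policy, universe_size}{
#'       [enrichment_config()] options.}
#'     \item{n_bins}{mRMR discretization bins (default 4).}
#'     \item{engine, engine_params}{Classifier engine (default
#'       `"random_forest"`) and hyperparameters.}
#'     \item{step, width, folds, interval}{IFS controls (defaults 10, 50,
#'       10, NULL).}
#'   }
#' @return The manifest, invisibly: a list of artifact paths, checksums,
#'   seeds, package version and the optimum summary.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (is.null(config$outdir)) stop_domain("config$outdir is required")
  if (is.null(config$seed)) stop_domain("config$seed is required")
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  artifacts <- character(0)
  add <- function(path) { artifacts <<- c(artifacts, path); path }
  log_msg <- function(...) message("[enrichIFS] ", ...)

  # --- stage: inputs -------------------------------------------------------
  if (!is.null(config$synthetic)) {
    log_msg("simulate: generating synthetic dataset")
    syn_args <- config$synthetic
    syn_args$seed <- derive_seed(seed, 1L)
    ds <- generate_dataset(do.call(synthetic_config, syn_args))
    ppi <- ds$ppi; terms <- ds$terms; labels <- ds$labels
    write_ppi_edges(ppi, add(file.path(outdir, "ppi.tsv")))
    write_gmt(terms, add(file.path(outdir, "terms.gmt")))
    write_gene_labels(labels, add(file.path(outdir, "labels.tsv")))
    jsonlite::write_json(list(informative_terms = ds$informative_terms),
                         add(file.path(outdir, "synthetic_truth.json")))
  } else {
    for (key in c("ppi", "gmt")) {
      if (is.null(config[[key]])) stop_domain("config$", key, " is required")
      if (!all(file.exists(config[[key]]))) {
        stop_domain("input path does not exist: ",
                    paste(config[[key]][!file.exists(config[[key]])], collapse = ", "))
      }
    }
    if (is.null(config$labels) && is.null(config$expression)) {
      stop_domain("either config$labels or config$expression is required")
    }
    src <- config$labels %||% config$expression
    if (!file.exists(src)) stop_domain("input path does not exist: ", src)
    log_msg("load: reading inputs")
    ppi <- read_ppi_edges(config$ppi,
                          min_confidence = config$min_confidence %||% 0,
                          scale = config$ppi_scale %||% "unit")
    terms <- read_gmt(config$gmt, config$gmt_namespaces %||% "BP")
    labels <- if (!is.null(config$labels)) {
      read_gene_labels(config$labels)
    } else {
      log_msg("label: FPKM thresholding")
      label_genes_by_expression(read_expression_table(config$expression),
                                threshold = config$fpkm_threshold %||% 1)
    }
    write_gene_labels(labels, add(file.path(outdir, "labels.tsv")))
  }

  # --- stage: encode -------------------------------------------------------
  log_msg("encode: ", nrow(labels), " genes x ", length(terms), " terms")
  enc_cfg <- enrichment_config(
    universe_size_policy = config$universe_size_policy %||% "network_nodes",
    universe_size = config$universe_size,
    score_cap = config$score_cap %||% 300,
    include_self = config$include_self %||% FALSE)
  fm <- encode_genes(labels$gene_id, ppi, terms, enc_cfg)
  write_feature_matrix(fm, add(file.path(outdir, "feature_matrix.tsv")))
  labels_used <- labels[labels$gene_id %in% rownames(fm), , drop = FALSE]

  # --- stage: rank ---------------------------------------------------------
  log_msg("rank: mRMR over ", ncol(fm), " features")
  ranked <- mrmr_rank(fm, labels_used, n_bins = config$n_bins %||% 4L)
  write_ranked_features(ranked, add(file.path(outdir, "ranked.tsv")))

  # --- stage: ifs ----------------------------------------------------------
  spec <- do.call(classifier_spec,
                  c(list(engine = config$engine %||% "random_forest",
                         seed = derive_seed(seed, 2L)),
                    config$engine_params %||% list()))
  log_msg("ifs: two-step scan (engine ", spec$engine, ")")
  ifs <- run_ifs(fm, labels_used, ranked, spec,
                 step = config$step %||% 10L,
                 width = config$width %||% 50L,
                 folds = config$folds %||% 10L,
                 seed = derive_seed(seed, 3L),
                 interval = config$interval)
  write_ifs_curve(ifs$stage1, add(file.path(outdir, "stage1.tsv")))
  write_ifs_curve(ifs$stage2, add(file.path(outdir, "stage2.tsv")))
  opt <- ifs$optimum_metrics
  jsonlite::write_json(
    list(optimum_size = ifs$optimum_size, interval = ifs$interval,
         metrics = list(SN = opt$SN, SP = opt$SP, ACC = opt$ACC,
                        MCC = opt$MCC, J = opt$J)),
    add(file.path(outdir, "optimum.json")), auto_unbox = TRUE, digits = NA)

  # --- stage: compare ------------------------------------------------------
  opt_features <- ranked$feature_id[seq_len(ifs$optimum_size)]
  tally <- namespace_tally(opt_features, terms)
  write.table(data.frame(namespace = names(tally), count = tally),
              add(file.path(outdir, "namespace_tally.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # --- manifest ------------------------------------------------------------
  manifest <- list(
    package = "enrichIFS",
    version = as.character(packageVersion("enrichIFS")),
    seed = seed,
    stage_seeds = list(simulate = derive_seed(seed, 1L),
                       classifier = derive_seed(seed, 2L),
                       folds = derive_seed(seed, 3L)),
    optimum = list(size = ifs$optimum_size, J = opt$J),
    artifacts = lapply(artifacts, function(p) {
      list(path = basename(p), md5 = unname(tools::md5sum(p)))
    }))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  log_msg("done: optimum ", ifs$optimum_size, " features, J = ",
          formatC(opt$J, digits = 3, format = "f"))
  invisible(manifest)
}
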