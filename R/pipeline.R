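#' Pipeline configuration
#'
#' Collects every stage parameter with the reference-study values as
#' defaults. Unknown keys are rejected.
#'
#' @param ... overrides of the defaults listed below.
#' @return a \code{pipeline_config} list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    max_age = 60,
    normalization = "quantile",
    loess_span = 0.4,
    rank_invariant_threshold = 0.05,
    collapse_arm = TRUE,
    t_variant = "pooled",
    p_max = 0.05,
    q_max = 0.05,
    denominator = "per_symbol",
    e_floor = 0,
    min_band = "75-80",
    min_coverage = 0.8,
    cluster = TRUE,
    k_range = 2:6,
    n_restarts = 5,
    roc_band = "100",
    nb_folds = 5,
    seed = 17L)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  defaults[names(over)] <- over
  structure(defaults, class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes the fixed stage sequence: hyper-matrix assembly, age exclusion,
#' preprocessing (background correction, masking, normalization, rescaling,
#' replicate averaging), per-symbol differential testing, tumor/control
#' ratio construction, k-means clustering with Calinski-Harabasz selection,
#' the co-deregulation frequency scan, and ROC / naive-Bayes evaluation of
#' the most extreme band's markers. Identical inputs and config give
#' identical outputs.
#'
#' @param series list of \code{\link{series_table}}s.
#' @param metadata sample metadata data.frame (needs sample_id, age_years,
#'   diagnosis1).
#' @param annotation optional chromosome annotation (symbol, chromosome,
#'   cytoband) for the chromosomal summaries.
#' @param config a \code{\link{pipeline_config}}.
#' @return a run bundle: list with hypermatrix, exclusion report, naturals,
#'   de (test table), de_selected, ratios, clusters (or NULL), codereg,
#'   chrom (or NULL), roc (list per marker), nb (or NULL), manifest.
#' @export
run_pipeline <- function(series, metadata, annotation = NULL,
                         config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  hm <- assemble_hypermatrix(series, collapse_arm = config$collapse_arm)
  excl <- exclude_by_age(hm, metadata, max_age = config$max_age)
  hm <- excl$hypermatrix

  pre <- preprocess_hypermatrix(hm, method = config$normalization,
                                span = config$loess_span,
                                ri_threshold = config$rank_invariant_threshold)
  validate_stages(pre)
  naturals <- pre$values
  is_tumor <- metadata$diagnosis1[match(pre$samples,
                                        metadata$sample_id)] == "NEOPLASM"

  de <- t_test_per_symbol(naturals, is_tumor, variant = config$t_variant)
  de_selected <- select_de(de, p_max = config$p_max, q_max = config$q_max)
  ratios <- tumor_to_control_ratio(naturals, is_tumor)

  # Downstream stages work on the differentially expressed symbols only,
  # and cohort-level co-deregulation claims are restricted to symbols
  # measured in at least min_coverage of the tumor samples (the same filter
  # that feeds clustering): a symbol private to one platform cannot be
  # deregulated across the whole cohort. Low-coverage DE symbols are kept
  # aside in `codereg_low_coverage`.
  de_ratios <- ratios[rownames(ratios) %in% de_selected, , drop = FALSE]
  covered <- rowMeans(is.finite(de_ratios)) >= config$min_coverage
  scan_ratios <- de_ratios[covered, , drop = FALSE]

  clusters <- NULL
  if (isTRUE(config$cluster) &&
      nrow(scan_ratios) >= max(config$k_range) + 1) {
    sel <- select_k(scan_ratios, k_range = config$k_range,
                    seed = derive_seed(config$seed, "kmeans"),
                    n_restarts = config$n_restarts)
    clusters <- sel$models[[as.character(sel$k_star)]]
    clusters$ch_scores <- sel$ch_scores
  }

  codereg <- scan_codereg(scan_ratios, clusters,
                          min_band = config$min_band,
                          denominator = config$denominator,
                          e_floor = config$e_floor)
  codereg_low <- scan_codereg(de_ratios[!covered, , drop = FALSE], NULL,
                              min_band = "below",
                              denominator = config$denominator,
                              e_floor = config$e_floor)

  chrom <- if (!is.null(annotation))
    chrom_summaries(ratios, annotation, "chromosome") else NULL

  markers <- codereg$symbol[codereg$band == config$roc_band]
  roc <- nb <- NULL
  if (length(markers)) {
    roc <- lapply(stats::setNames(markers, markers), function(sym)
      roc_auc(naturals[sym, ], is_tumor))
    feats <- prepare_for_clustering(naturals[markers, , drop = FALSE],
                                    min_coverage = 0)
    lab <- ifelse(is_tumor[colnames(naturals) %in% colnames(feats)],
                  "tumor", "control")
    cls <- table(lab)
    if (length(cls) == 2 && all(cls >= config$nb_folds))
      nb <- naive_bayes_cv(feats, lab, folds = config$nb_folds,
                           seed = derive_seed(config$seed, "nb"))
  }

  manifest <- list(
    config = unclass(config),
    config_hash = config_hash(config),
    seed = config$seed,
    n_series = length(series),
    n_samples_raw = length(unlist(lapply(series, `[[`, "sample_ids"))),
    n_samples_excluded = length(excl$report$removed),
    n_symbols = nrow(naturals),
    n_samples = ncol(naturals),
    n_tested = sum(de$tested),
    n_de_selected = length(de_selected),
    n_codereg = nrow(codereg),
    k_star = if (is.null(clusters)) NA else clusters$k)

  list(hypermatrix = hm, exclusion = excl$report, preprocessed = pre,
       naturals = naturals, is_tumor = is_tumor, de = de,
       de_selected = de_selected, ratios = ratios, clusters = clusters,
       codereg = codereg, codereg_low_coverage = codereg_low,
       chrom = chrom, roc = roc, nb = nb, manifest = manifest)
}

#' Generate a synthetic study and run the pipeline on it
#'
#' @param syn_config a \code{\link{synthetic_config}}.
#' @param config a \code{\link{pipeline_config}}.
#' @param annotate also generate a synthetic chromosome annotation.
#' @return list with \code{sim} (the generated study) and \code{run} (the
#'   pipeline bundle).
#' @export
run_synthetic_study <- function(syn_config = synthetic_config(),
                                config = pipeline_config(),
                                annotate = FALSE) {
  sim <- generate_multiseries(syn_config)
  ann <- if (annotate)
    generate_annotation(sort(unique(unlist(lapply(sim$series,
                                                  `[[`, "feature_symbols")))),
                        seed = derive_seed(syn_config$seed, "annotation"))
  else NULL
  run <- run_pipeline(sim$series, sim$metadata, annotation = ann,
                      config = config)
  list(sim = sim, run = run)
}

#' Write the pipeline bundle to a directory
#'
#' Serialises the stage outputs as plain text: hyper-matrix and naturals as
#' TSV (literal NaN), the differential table and co-deregulation report as
#' TSV, and the manifest as JSON.
#'
#' @param bundle result of \code{\link{run_pipeline}}.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    write_hypermatrix(bundle$naturals, file.path(dir, "naturals.tsv")),
    write_hypermatrix(bundle$ratios, file.path(dir, "ratios.tsv")))
  utils::write.table(bundle$de, file.path(dir, "de_table.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_codereg_report(bundle$codereg, file.path(dir, "codereg.tsv"))
  if (!is.null(bundle$clusters)) {
    utils::write.table(
      data.frame(symbol = names(bundle$clusters$assignments),
                 cluster = bundle$clusters$assignments),
      file.path(dir, "clusters.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(c(paths, file.path(dir, c("de_table.tsv", "codereg.tsv",
                                      "manifest.json"))))
}

config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = NA), tf)
  unname(tools::md5sum(tf))
}
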