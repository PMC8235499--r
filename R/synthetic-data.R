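#' Configuration for the multi-series synthetic generator
#'
#' Defines the statistical structure of a simulated multi-series miRNA
#' microarray study: several series measuring partially overlapping miRNA
#' universes (block-diagonal missingness once assembled), series-level
#' multiplicative batch effects, optional background channels, occasional
#' non-positive intensities, planted globally deregulated miRNAs, and
#' grade-ordered expression signatures.
#'
#' Defaults describe the reference study conditions used throughout the test
#' suite: 3 series, 110 shared + 30 private features per series (200 symbols
#' in total), 40 tumor and 20 control samples, five markers planted
#' down-regulated in every tumor at a 2.0 log2-unit shift, two up-regulated
#' markers at partial penetrance, per-cell noise SD 0.5 and per-series batch
#' SD 0.25 on the log2 scale.
#'
#' @param n_series number of microarray series.
#' @param features_per_series number of features measured by each series.
#' @param shared_features number of features common to all series; the
#'   remaining \code{features_per_series - shared_features} features of each
#'   series are private to it.
#' @param n_tumor,n_control total tumor / control sample counts (distributed
#'   round-robin across series so every series contains both classes).
#' @param planted_down_100 character vector of shared feature symbols shifted
#'   down by \code{planted_shift} log2 units in every tumor sample.
#' @param planted_up_partial named numeric vector: names are shared feature
#'   symbols, values are penetrance fractions in (0, 1]; each feature is
#'   shifted up in a seeded random subset of \code{ceiling(pen * n_tumor)}
#'   tumors.
#' @param planted_shift magnitude of planted shifts, log2 units.
#' @param grade_ordered_features shared features given monotone grade means
#'   following the order control < IV < I < II < III.
#' @param grade_step log2 increment between successive grade categories for
#'   grade-ordered features.
#' @param batch_scale_sd SD of the per-series multiplicative batch effect on
#'   the log2 scale (0 disables batch effects).
#' @param noise_sd per-cell log2-scale noise SD.
#' @param background_fraction mean background/foreground intensity ratio in
#'   [0, 1); 0 omits the background channel.
#' @param negative_fraction fraction of intensity cells flipped to negative
#'   values, exercising the non-positive masking stage.
#' @param n_decoys_over60 number of extra control samples aged over 60 years,
#'   exercising the cohort age-exclusion rule.
#' @param missing_block if TRUE each series only measures its own feature set
#'   (diagonal block missingness); if FALSE every series measures the full
#'   union.
#' @param seed integer seed; identical configurations produce bit-identical
#'   output.
#' @return a validated \code{synthetic_config} list.
#' @export
synthetic_config <- function(n_series = 3L,
                             features_per_series = 140L,
                             shared_features = 110L,
                             n_tumor = 40L,
                             n_control = 20L,
                             planted_down_100 = c("MIR149", "MIR214", "MIR574",
                                                  "MIR595", "MIR765"),
                             planted_up_partial = c(MIR376B = 0.85,
                                                    MIR372 = 0.78),
                             planted_shift = 2.0,
                             grade_ordered_features = c("MIR1307", "MIR3613"),
                             grade_step = 0.8,
                             batch_scale_sd = 0.25,
                             noise_sd = 0.5,
                             background_fraction = 0,
                             negative_fraction = 0.002,
                             n_decoys_over60 = 3L,
                             missing_block = TRUE,
                             seed = 1L) {
  cfg <- list(n_series = as.integer(n_series),
              features_per_series = as.integer(features_per_series),
              shared_features = as.integer(shared_features),
              n_tumor = as.integer(n_tumor),
              n_control = as.integer(n_control),
              planted_down_100 = as.character(planted_down_100),
              planted_up_partial = planted_up_partial,
              planted_shift = planted_shift,
              grade_ordered_features = as.character(grade_ordered_features),
              grade_step = grade_step,
              batch_scale_sd = batch_scale_sd,
              noise_sd = noise_sd,
              background_fraction = background_fraction,
              negative_fraction = negative_fraction,
              n_decoys_over60 = as.integer(n_decoys_over60),
              missing_block = isTRUE(missing_block),
              seed = as.integer(seed))
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  if (cfg$shared_features > cfg$features_per_series)
    stop("invalid config: shared_features (", cfg$shared_features,
         ") exceeds features_per_series (", cfg$features_per_series, ")")
  if (cfg$n_series < 1L || cfg$n_tumor < 2L || cfg$n_control < 2L)
    stop("invalid config: need >= 1 series and >= 2 samples per class")
  if (cfg$batch_scale_sd < 0 || cfg$noise_sd < 0)
    stop("invalid config: batch_scale_sd and noise_sd must be non-negative")
  if (cfg$background_fraction < 0 || cfg$background_fraction >= 1)
    stop("invalid config: background_fraction must be in [0, 1)")
  pens <- unname(cfg$planted_up_partial)
  if (length(pens) && (any(pens <= 0) || any(pens > 1)))
    stop("invalid config: penetrance fractions must lie in (0, 1]")
  planted <- c(cfg$planted_down_100, names(cfg$planted_up_partial),
               cfg$grade_ordered_features)
  n_named <- length(unique(planted))
  if (n_named > cfg$shared_features)
    stop("invalid config: ", n_named, " planted features exceed the ",
         cfg$shared_features, " shared features")
  invisible(cfg)
}

# Shared feature names: planted symbols first, filler MIR9xxx after, so every
# planted feature is observable in all series.
synthetic_feature_universe <- function(cfg) {
  named <- unique(c(cfg$planted_down_100, names(cfg$planted_up_partial),
                    cfg$grade_ordered_features))
  n_fill <- cfg$shared_features - length(named)
  shared <- c(named, sprintf("MIR9%03d", seq_len(n_fill)))
  n_priv <- cfg$features_per_series - cfg$shared_features
  private <- lapply(seq_len(cfg$n_series), function(s)
    sprintf("MIR8%d%03d", s, seq_len(n_priv)))
  list(shared = shared, private = private,
       universe = c(shared, unlist(private)))
}

GRADE_ORDER <- c("CONTROL", "IV", "I", "II", "III")

#' Generate a multi-series synthetic miRNA study
#'
#' Draws per-feature baseline log2 intensities (normal, mean 8, SD 1.5 --
#' typical microarray magnitudes), applies planted tumor shifts, per-series
#' multiplicative batch factors and cell-level noise, exponentiates to the
#' intensity scale, optionally adds a background channel and flips a small
#' fraction of cells negative. Sample metadata carries gender, age (with a
#' configurable number of over-60 decoys), diagnosis at three granularities,
#' grade, sampling and developmental status. Every planted effect is recorded
#' in the returned ground truth.
#'
#' @param config a \code{\link{synthetic_config}}.
#' @return list with elements \code{series} (list of series tables as used by
#'   \code{\link{assemble_hypermatrix}}), \code{metadata} (data.frame) and
#'   \code{truth} (ground-truth list).
#' @export
generate_multiseries <- function(config = synthetic_config()) {
  validate_synthetic_config(config)
  set.seed(config$seed)
  feats <- synthetic_feature_universe(config)
  universe <- feats$universe
  baseline <- stats::rnorm(length(universe), mean = 8, sd = 1.5)
  names(baseline) <- universe

  n_total <- config$n_tumor + config$n_control + config$n_decoys_over60
  sample_ids <- sprintf("S%03d", seq_len(n_total))
  is_tumor <- c(rep(TRUE, config$n_tumor),
                rep(FALSE, config$n_control + config$n_decoys_over60))
  is_decoy <- c(rep(FALSE, config$n_tumor + config$n_control),
                rep(TRUE, config$n_decoys_over60))
  series_of <- rep_len(seq_len(config$n_series), n_total)

  meta <- synthetic_metadata(config, sample_ids, is_tumor, is_decoy,
                             paste0("SER", series_of))

  # planted per-tumor shift matrix on the log2 scale
  tumor_ids <- sample_ids[is_tumor]
  shift <- matrix(0, length(universe), n_total,
                  dimnames = list(universe, sample_ids))
  for (f in config$planted_down_100)
    shift[f, tumor_ids] <- -config$planted_shift
  up_affected <- list()
  for (f in names(config$planted_up_partial)) {
    pen <- config$planted_up_partial[[f]]
    n_hit <- ceiling(pen * config$n_tumor)
    hit <- sample(tumor_ids, n_hit)
    shift[f, hit] <- config$planted_shift
    up_affected[[f]] <- sort(hit)
  }
  grade_of <- meta$grade
  names(grade_of) <- meta$sample_id
  for (f in config$grade_ordered_features) {
    lev <- match(grade_of[sample_ids], GRADE_ORDER) - 1L
    lev[is.na(lev)] <- 0L
    shift[f, ] <- shift[f, ] + config$grade_step * lev
  }

  batch_log2 <- stats::rnorm(config$n_series, 0, config$batch_scale_sd)
  names(batch_log2) <- paste0("SER", seq_len(config$n_series))

  series <- vector("list", config$n_series)
  for (s in seq_len(config$n_series)) {
    sid <- paste0("SER", s)
    f_s <- if (config$missing_block)
      c(feats$shared, feats$private[[s]]) else universe
    cols <- sample_ids[series_of == s]
    log2v <- baseline[f_s] + shift[f_s, cols, drop = FALSE] +
      batch_log2[s] +
      matrix(stats::rnorm(length(f_s) * length(cols), 0, config$noise_sd),
             length(f_s), length(cols))
    fg <- 2 ^ log2v
    if (config$negative_fraction > 0) {
      n_neg <- round(config$negative_fraction * length(fg))
      if (n_neg > 0) {
        idx <- sample(length(fg), n_neg)
        fg[idx] <- -abs(fg[idx])
      }
    }
    bg <- NULL
    if (config$background_fraction > 0)
      bg <- config$background_fraction * abs(fg) *
        2 ^ matrix(stats::rnorm(length(fg), 0, 0.1), nrow(fg), ncol(fg))
    dimnames(fg) <- list(f_s, cols)
    if (!is.null(bg)) dimnames(bg) <- dimnames(fg)
    series[[s]] <- series_table(series_id = sid,
                                platform_id = paste0("PLT", s),
                                feature_symbols = f_s,
                                sample_ids = cols,
                                foreground = fg,
                                background = bg)
  }

  planted <- data.frame(
    symbol = c(config$planted_down_100, names(config$planted_up_partial)),
    direction = c(rep("down", length(config$planted_down_100)),
                  rep("up", length(config$planted_up_partial))),
    penetrance = c(rep(1.0, length(config$planted_down_100)),
                   unname(config$planted_up_partial)),
    shift = c(rep(-config$planted_shift, length(config$planted_down_100)),
              rep(config$planted_shift, length(config$planted_up_partial))),
    stringsAsFactors = FALSE)
  planted$n_affected <- ifelse(planted$direction == "down", config$n_tumor,
                               vapply(up_affected[planted$symbol],
                                      length, 0L)[seq_len(nrow(planted))])
  planted$affected <- ifelse(planted$direction == "down",
                             paste(tumor_ids, collapse = ";"),
                             vapply(planted$symbol, function(f)
                               if (is.null(up_affected[[f]])) ""
                               else paste(up_affected[[f]], collapse = ";"),
                               ""))

  truth <- list(planted = planted,
                baseline_log2 = baseline,
                batch_log2 = batch_log2,
                series_features = stats::setNames(
                  lapply(series, function(s) s$feature_symbols),
                  vapply(series, function(s) s$series_id, "")),
                grade_ordered = config$grade_ordered_features,
                grade_order = GRADE_ORDER,
                decoy_ids = sample_ids[is_decoy],
                tumor_ids = tumor_ids,
                control_ids = sample_ids[!is_tumor & !is_decoy],
                config = unclass(config))

  list(series = series, metadata = meta, truth = truth)
}

synthetic_metadata <- function(cfg, sample_ids, is_tumor, is_decoy, series) {
  n <- length(sample_ids)
  entity <- data.frame(
    diagnosis3 = c("MEDULLOBLASTOMA", "ASTROCYTOMA", "EPENDYMOMA", "ATRT",
                   "GLIOBLASTOMA", "GERMINOMA", "RETINOBLASTOMA"),
    diagnosis2 = c("MALIGNANCY", "BENIGN", "BENIGN", "MALIGNANCY",
                   "MALIGNANCY", "MALIGNANCY", "MALIGNANCY"),
    stringsAsFactors = FALSE)
  pick <- sample(nrow(entity), n, replace = TRUE)
  diagnosis3 <- ifelse(is_tumor, entity$diagnosis3[pick], "CONTROL")
  diagnosis2 <- ifelse(is_tumor, entity$diagnosis2[pick], "CONTROL")
  diagnosis1 <- ifelse(is_tumor, "NEOPLASM", "CONTROL")
  # grade frequencies follow the reference cohort proportions (53/18/12/92)
  grade <- ifelse(is_tumor,
                  sample(c("I", "II", "III", "IV"), n, replace = TRUE,
                         prob = c(53, 18, 12, 92)),
                  "CONTROL")
  age <- round(stats::runif(n, 0, 27), 2)
  age[is_decoy] <- round(stats::runif(sum(is_decoy), 61, 80), 2)
  dev_status <- cut(age, c(-Inf, 0.08, 1, 12, 17, Inf),
                    labels = c("NEONATE", "INFANT", "CHILD", "ADOLESCENT",
                               "ADULT"))
  data.frame(sample_id = sample_ids,
             series_id = series,
             gender = sample(c("FEMALE", "MALE", "NA"), n, replace = TRUE,
                             prob = c(0.35, 0.45, 0.2)),
             age_years = age,
             gestational_age_years = age + 0.75,
             sampling = sample(c("VIVUS", "POST-MORTEM"), n, replace = TRUE),
             diagnosis1 = diagnosis1,
             diagnosis2 = diagnosis2,
             diagnosis3 = diagnosis3,
             grade = grade,
             developmental_status = as.character(dev_status),
             outcome = sample(c("ALIVE", "DECEASED", "NA"), n,
                              replace = TRUE, prob = c(0.5, 0.2, 0.3)),
             stringsAsFactors = FALSE)
}

#' Deterministic synthetic chromosome / cytoband annotation
#'
#' Assigns each feature one chromosome (1-22, X, Y) and one cytoband label,
#' reproducibly under the seed. Purely synthetic: it supports chromosomal
#' summary testing, not biological lookup.
#'
#' @param feature_ids unique feature symbols.
#' @param seed integer seed.
#' @return data.frame with columns symbol, chromosome, cytoband.
#' @export
generate_annotation <- function(feature_ids, seed = 1L) {
  dup <- unique(feature_ids[duplicated(feature_ids)])
  if (length(dup))
    stop("duplicate feature ids: ", paste(dup, collapse = ", "))
  set.seed(as.integer(seed))
  chroms <- c(as.character(1:22), "X", "Y")
  chr <- sample(chroms, length(feature_ids), replace = TRUE)
  band <- paste0(chr, sample(c("p", "q"), length(feature_ids), TRUE),
                 sample(11:36, length(feature_ids), TRUE), ".",
                 sample(1:3, length(feature_ids), TRUE))
  data.frame(symbol = feature_ids, chromosome = chr, cytoband = band,
             stringsAsFactors = FALSE)
}

#' Write synthetic series tables, metadata and ground truth to disk
#'
#' Series tables are tab-delimited (feature column plus one column per
#' sample; background channels as parallel *_BKG columns), metadata is CSV,
#' ground truth is JSON.
#'
#' @param sim result of \code{\link{generate_multiseries}}.
#' @param dir output directory, created if needed.
#' @return invisibly, the paths written.
#' @export
write_synthetic_study <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (s in sim$series) {
    df <- data.frame(feature = s$feature_symbols, s$foreground,
                     check.names = FALSE, stringsAsFactors = FALSE)
    if (!is.null(s$background)) {
      bg <- s$background
      colnames(bg) <- paste0(colnames(bg), "_BKG")
      df <- cbind(df, bg)
    }
    p <- file.path(dir, paste0(s$series_id, ".tsv"))
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  mp <- file.path(dir, "metadata.csv")
  utils::write.csv(sim$metadata, mp, row.names = FALSE)
  tp <- file.path(dir, "ground_truth.json")
  truth <- sim$truth
  truth$baseline_log2 <- as.list(truth$baseline_log2)
  jsonlite::write_json(truth, tp, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, mp, tp))
}
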