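#' Construct a single-series expression table
#'
#' @param series_id,platform_id identifiers.
#' @param feature_symbols raw feature symbols, one per foreground row.
#' @param sample_ids sample identifiers, unique within the series.
#' @param foreground features x samples matrix of intensities.
#' @param background optional matrix of the same shape (background channel).
#' @return a \code{series_table} list.
#' @export
series_table <- function(series_id, platform_id = NA_character_,
                         feature_symbols, sample_ids, foreground,
                         background = NULL) {
  foreground <- as.matrix(foreground)
  if (nrow(foreground) != length(feature_symbols) ||
      ncol(foreground) != length(sample_ids))
    stop("series ", series_id, ": foreground shape ",
         nrow(foreground), "x", ncol(foreground),
         " does not match ", length(feature_symbols), " features x ",
         length(sample_ids), " samples")
  if (anyDuplicated(sample_ids))
    stop("series ", series_id, ": duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (!is.null(background)) {
    background <- as.matrix(background)
    if (!all(dim(background) == dim(foreground)))
      stop("series ", series_id, ": background shape differs from foreground")
  }
  structure(list(series_id = series_id, platform_id = platform_id,
                 feature_symbols = as.character(feature_symbols),
                 sample_ids = as.character(sample_ids),
                 foreground = foreground, background = background),
            class = "series_table")
}

#' Canonicalize miRNA symbols
#'
#' Maps heterogeneous platform spellings onto one canonical symbol per mature
#' miRNA family: the species prefix ("hsa-") is stripped, "miR"/"mir" maps to
#' "MIR", "let" to "MIRLET", hyphens are removed and the result is
#' upper-cased, so "hsa-miR-149" becomes "MIR149". Under the default arm
#' policy the -5p/-3p arm tag is stripped from the canonical symbol and
#' recorded separately ("hsa-miR-376b-3p" -> MIR376B, arm "3p"). Symbols that
#' do not look like miRNA names are not silently dropped: they come back with
#' \code{mapped = FALSE} and an NA canonical symbol.
#'
#' @param raw character vector of raw symbols.
#' @param collapse_arm strip the -5p/-3p suffix from the canonical symbol
#'   (default TRUE); the arm is recorded either way.
#' @return data.frame with columns raw, canonical, arm, mapped.
#' @export
canonicalize_symbols <- function(raw, collapse_arm = TRUE) {
  raw <- as.character(raw)
  if (any(!nzchar(trimws(raw))))
    stop("empty symbol at position ",
         paste(which(!nzchar(trimws(raw))), collapse = ", "))
  s <- trimws(raw)
  low <- sub("^hsa-", "", tolower(s))
  arm <- rep(NA_character_, length(s))
  has_arm <- grepl("-(3p|5p)$", low)
  arm[has_arm] <- sub("^.*-(3p|5p)$", "\\1", low[has_arm])
  core <- if (collapse_arm) sub("-(3p|5p)$", "", low) else low
  mapped <- grepl("^(mir|let)[-0-9a-z]", core)
  canon <- sub("^let", "mirlet", core)
  canon <- toupper(gsub("-", "", canon))
  canon[!mapped] <- NA_character_
  data.frame(raw = s, canonical = canon, arm = arm, mapped = mapped,
             stringsAsFactors = FALSE)
}

#' @rdname canonicalize_symbols
#' @export
canonicalize_symbol <- function(raw, collapse_arm = TRUE) {
  canonicalize_symbols(raw, collapse_arm)$canonical
}

#' Assemble multiple series into a sparse hyper-matrix
#'
#' Stacks all series into one features x samples matrix: the row universe is
#' the union of canonical symbols across series, each series occupies its own
#' block of sample columns, and a cell is NaN iff the sample's series did not
#' measure that symbol (block-diagonal missingness for disjoint platforms).
#' Within-series duplicate occurrences of a symbol are kept as distinct rows
#' (occurrence 1 of a symbol aligns across series, occurrence 2 forms a
#' second row, ...) until \code{\link{average_replicates}} collapses them.
#' Symbols that fail canonicalization are excluded from the matrix and listed
#' in the \code{unmapped} report.
#'
#' @param series list of \code{\link{series_table}} objects.
#' @param collapse_arm arm policy passed to \code{\link{canonicalize_symbols}}.
#' @return a \code{hypermatrix}: list with \code{values} (matrix, NaN for
#'   missing), \code{background} (matrix or NULL), \code{symbols},
#'   \code{samples}, \code{series_of_sample}, \code{series_has_background},
#'   \code{unmapped}, \code{stage}.
#' @export
assemble_hypermatrix <- function(series, collapse_arm = TRUE) {
  stopifnot(length(series) >= 1)
  all_samples <- unlist(lapply(series, function(s) s$sample_ids))
  if (anyDuplicated(all_samples))
    stop("sample id collision across series: ",
         paste(unique(all_samples[duplicated(all_samples)]), collapse = ", "))

  canon <- lapply(series, function(s)
    canonicalize_symbols(s$feature_symbols, collapse_arm))
  unmapped <- do.call(rbind, lapply(seq_along(series), function(i) {
    bad <- canon[[i]][!canon[[i]]$mapped, , drop = FALSE]
    if (nrow(bad)) cbind(series_id = series[[i]]$series_id, bad) else NULL
  }))

  # row key = canonical symbol + within-series occurrence index
  keys <- lapply(canon, function(cc) {
    ok <- cc$mapped
    k <- rep(NA_character_, nrow(cc))
    occ <- stats::ave(seq_len(sum(ok)), cc$canonical[ok], FUN = seq_along)
    k[ok] <- paste0(cc$canonical[ok], "\r", occ)
    k
  })
  universe <- unique(unlist(lapply(keys, function(k) k[!is.na(k)])))
  symbols <- sub("\r.*$", "", universe)

  n_samp <- length(all_samples)
  values <- matrix(NA_real_, length(universe), n_samp,
                   dimnames = list(symbols, all_samples))
  any_bg <- any(vapply(series, function(s) !is.null(s$background), TRUE))
  background <- if (any_bg) values else NULL
  series_of <- character(n_samp)
  names(series_of) <- all_samples
  has_bg <- logical(0)

  for (i in seq_along(series)) {
    s <- series[[i]]
    ok <- !is.na(keys[[i]])
    ridx <- match(keys[[i]][ok], universe)
    values[ridx, s$sample_ids] <- s$foreground[ok, , drop = FALSE]
    if (!is.null(s$background) && any_bg)
      background[ridx, s$sample_ids] <- s$background[ok, , drop = FALSE]
    series_of[s$sample_ids] <- s$series_id
    has_bg[s$series_id] <- !is.null(s$background)
  }

  structure(list(values = values, background = background,
                 symbols = symbols, samples = all_samples,
                 series_of_sample = series_of,
                 series_has_background = has_bg,
                 unmapped = unmapped, stage = "raw", notes = list()),
            class = "hypermatrix")
}

#' @export
print.hypermatrix <- function(x, ...) {
  cat("hypermatrix:", nrow(x$values), "feature rows x", ncol(x$values),
      "samples,", length(unique(x$series_of_sample)), "series\n")
  cat("  stage:", paste(x$stage, collapse = " -> "), "\n")
  cat("  missing cells:", sum(is.na(x$values)), "of", length(x$values), "\n")
  invisible(x)
}

#' @export
dim.hypermatrix <- function(x) dim(x$values)

#' Exclude samples above an age cutoff
#'
#' Drops samples whose metadata age exceeds \code{max_age} years from the
#' hyper-matrix columns. Samples with missing age are retained and flagged.
#'
#' @param hm a \code{hypermatrix}.
#' @param meta data.frame with columns \code{sample_id} and \code{age_years}.
#' @param max_age cutoff in years (default 60).
#' @return list with the filtered \code{hypermatrix} and a \code{report}
#'   (removed ids, retained-with-missing-age ids).
#' @export
exclude_by_age <- function(hm, meta, max_age = 60) {
  stopifnot(inherits(hm, "hypermatrix"))
  missing <- setdiff(hm$samples, meta$sample_id)
  if (length(missing))
    stop("metadata missing for sample(s): ", paste(missing, collapse = ", "))
  age <- meta$age_years[match(hm$samples, meta$sample_id)]
  drop <- !is.na(age) & age > max_age
  removed <- hm$samples[drop]
  flagged <- hm$samples[is.na(age)]
  keep <- hm$samples[!drop]
  hm$values <- hm$values[, keep, drop = FALSE]
  if (!is.null(hm$background))
    hm$background <- hm$background[, keep, drop = FALSE]
  hm$samples <- keep
  hm$series_of_sample <- hm$series_of_sample[keep]
  list(hypermatrix = hm,
       report = list(removed = removed, missing_age_retained = flagged))
}

#' Read a tab-delimited series table
#'
#' Expects a first column of feature symbols and one column per sample;
#' columns named \code{<sample>_BKG} are interpreted as the background
#' channel of \code{<sample>}.
#'
#' @param path file path.
#' @param series_id,platform_id identifiers (default: file stem).
#' @return a \code{\link{series_table}}.
#' @export
read_series_table <- function(path, series_id = NULL,
                              platform_id = NA_character_) {
  if (is.null(series_id))
    series_id <- sub("\\.[^.]*$", "", basename(path))
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  feats <- as.character(df[[1]])
  rest <- as.matrix(df[, -1, drop = FALSE])
  bkg_cols <- grepl("_BKG$", colnames(rest))
  fg <- rest[, !bkg_cols, drop = FALSE]
  bg <- NULL
  if (any(bkg_cols)) {
    bg <- rest[, bkg_cols, drop = FALSE]
    colnames(bg) <- sub("_BKG$", "", colnames(bg))
    bg <- bg[, colnames(fg), drop = FALSE]
  }
  series_table(series_id, platform_id, feats, colnames(fg), fg, bg)
}

#' Write a hyper-matrix as TSV with literal NaN tokens
#'
#' @param hm a \code{hypermatrix} (or plain matrix).
#' @param path output path.
#' @export
write_hypermatrix <- function(hm, path) {
  m <- if (inherits(hm, "hypermatrix")) hm$values else hm
  df <- data.frame(feature = rownames(m), m, check.names = FALSE)
  df[] <- lapply(df, function(col)
    if (is.numeric(col)) ifelse(is.na(col), "NaN", format(col, digits = 12))
    else col)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
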