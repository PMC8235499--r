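#' Half-up rounding
#'
#' Standard commercial rounding (0.005 rounds up), used for the reported
#' frequency percentages; base R's \code{round} rounds half to even.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 2).
#' @return rounded vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10 ^ digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

BAND_LEVELS <- c("100", "90-99", "80-89", "75-80", "below")

#' Assign a frequency percentage to its co-deregulation band
#'
#' Bands: exactly 100 -> "100"; [90, 100) -> "90-99"; [80, 90) -> "80-89";
#' [75, 80) -> "75-80"; anything lower -> "below". Boundaries are half-open.
#'
#' @param f_pct percentage(s) in [0, 100].
#' @return ordered factor with levels 100 > 90-99 > 80-89 > 75-80 > below.
#' @export
band_assign <- function(f_pct) {
  if (any(!is.finite(f_pct)) || any(f_pct < 0 | f_pct > 100))
    stop("f_pct outside [0, 100]")
  band <- ifelse(f_pct == 100, "100",
          ifelse(f_pct >= 90, "90-99",
          ifelse(f_pct >= 80, "80-89",
          ifelse(f_pct >= 75, "75-80", "below"))))
  factor(band, levels = BAND_LEVELS, ordered = TRUE)
}

#' Per-symbol deregulation frequency
#'
#' Counts the tumor samples in which a symbol's log2 ratio is positive
#' (up-regulated) or negative (down-regulated); a ratio of exactly zero
#' counts toward neither. The percentage denominator is either the number of
#' non-missing tumor values for the symbol (default, appropriate when
#' platform coverage differs across series) or a fixed cohort total.
#'
#' @param e_row numeric vector of log2 ratios for one symbol across tumor
#'   samples (at least one finite value).
#' @param denominator "per_symbol" (non-missing count) or a positive number
#'   (fixed cohort total).
#' @param e_floor optional magnitude floor: only |E| > e_floor counts as
#'   deregulated (default 0, i.e. sign only).
#' @return list with f_up, f_down, n_zero, n_missing, denominator,
#'   f_pct_up, f_pct_down, direction ("up", "down" or "ambiguous").
#' @export
deregulation_frequency <- function(e_row, denominator = "per_symbol",
                                   e_floor = 0) {
  fin <- is.finite(e_row)
  if (!any(fin)) stop("all-missing ratio row")
  f_up <- sum(e_row[fin] > e_floor)
  f_down <- sum(e_row[fin] < -e_floor)
  n_zero <- sum(fin) - f_up - f_down
  denom <- if (identical(denominator, "per_symbol")) sum(fin)
           else as.numeric(denominator)
  if (!is.finite(denom) || denom <= 0) stop("invalid denominator")
  direction <- if (f_up > f_down) "up" else if (f_down > f_up) "down"
               else "ambiguous"
  list(f_up = f_up, f_down = f_down, n_zero = n_zero,
       n_missing = sum(!fin), denominator = denom,
       f_pct_up = round_half_up(100 * f_up / denom),
       f_pct_down = round_half_up(100 * f_down / denom),
       direction = direction)
}

#' Scan for co-deregulated miRNAs across tumor samples
#'
#' The core frequency statistic: every symbol of the ratio matrix is counted
#' for the tumor samples it is up- or down-regulated in, expressed as a
#' percentage of the denominator, assigned a band and reported together with
#' its k-means cluster and mean expression. Records below \code{min_band}
#' are excluded, and the output is sorted by cluster, then f ascending.
#'
#' @param E log2 ratio matrix (symbols x tumor samples) from
#'   \code{\link{tumor_to_control_ratio}}.
#' @param clusters optional \code{cluster_model} over (a superset of) the
#'   same symbols; cluster ids are NA for symbols without an assignment.
#' @param min_band least extreme band to keep (default "75-80"; use "below"
#'   to keep everything).
#' @param denominator see \code{\link{deregulation_frequency}}.
#' @param e_floor see \code{\link{deregulation_frequency}}.
#' @return data.frame of co-deregulation records (symbol, direction, f,
#'   f_pct, denominator, band, kmeans_cluster, mean_expression) with a
#'   per-(cluster, direction, band) census in attribute \code{summary}.
#' @export
scan_codereg <- function(E, clusters = NULL, min_band = "75-80",
                         denominator = "per_symbol", e_floor = 0) {
  E <- as.matrix(E)
  min_band <- match.arg(min_band, BAND_LEVELS)
  if (nrow(E) == 0)
    return(empty_codereg())
  assign_of <- if (is.null(clusters)) NULL else clusters$assignments
  rows <- lapply(rownames(E), function(sym) {
    e <- E[sym, ]
    if (!any(is.finite(e))) return(NULL)
    fr <- deregulation_frequency(e, denominator, e_floor)
    f <- max(fr$f_up, fr$f_down)
    f_pct <- max(fr$f_pct_up, fr$f_pct_down)
    data.frame(symbol = sym, direction = fr$direction, f = f,
               f_pct = f_pct, denominator = fr$denominator,
               band = as.character(band_assign(min(f_pct, 100))),
               kmeans_cluster = if (is.null(assign_of)) NA_integer_
                 else unname(assign_of[sym]),
               mean_expression = mean(e[is.finite(e)]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty_codereg())
  out$band <- factor(out$band, levels = BAND_LEVELS, ordered = TRUE)
  keep <- out$band <= factor(min_band, levels = BAND_LEVELS, ordered = TRUE)
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$kmeans_cluster, out$f, out$symbol), , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out)) {
    cl <- ifelse(is.na(out$kmeans_cluster), "none",
                 as.character(out$kmeans_cluster))
    census <- stats::aggregate(list(n = seq_len(nrow(out))),
                               by = list(cluster = cl,
                                         direction = out$direction,
                                         band = out$band), FUN = length)
  } else census <- NULL
  attr(out, "summary") <- census
  out
}

empty_codereg <- function() {
  out <- data.frame(symbol = character(0), direction = character(0),
                    f = integer(0), f_pct = numeric(0),
                    denominator = numeric(0),
                    band = factor(character(0), levels = BAND_LEVELS,
                                  ordered = TRUE),
                    kmeans_cluster = integer(0),
                    mean_expression = numeric(0), stringsAsFactors = FALSE)
  attr(out, "summary") <- NULL
  out
}

#' Write a co-deregulation report as TSV
#'
#' @param records result of \code{\link{scan_codereg}}.
#' @param path output path.
#' @export
write_codereg_report <- function(records, path) {
  df <- data.frame(Inv = seq_len(nrow(records)),
                   miRNA = records$symbol,
                   Pattern = ifelse(records$direction == "up",
                                    "Up-regulated", "Down-regulated"),
                   f = records$f,
                   `f (%)` = sprintf("%.2f", records$f_pct),
                   `K-Means Cluster` = records$kmeans_cluster,
                   `Mean Expression` = signif(records$mean_expression, 7),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Chromosomal and cytoband expression summaries
#'
#' NaN-ignoring mean log2 ratio per chromosome or cytoband over the
#' annotated symbols, plus a location x sample mean matrix for heat-map
#' export; unannotated symbols are reported separately.
#'
#' @param E log2 ratio matrix (symbols x tumor samples).
#' @param ann annotation data.frame with columns symbol, chromosome,
#'   cytoband (see \code{\link{generate_annotation}}).
#' @param level "chromosome" or "cytoband".
#' @return list with \code{summary} (location, n_symbols, mean_expression;
#'   sorted by mean descending), \code{heatmap} (location x sample matrix)
#'   and \code{unannotated}.
#' @export
chrom_summaries <- function(E, ann, level = c("chromosome", "cytoband")) {
  level <- match.arg(level)
  E <- as.matrix(E)
  loc_of <- ann[[level]][match(rownames(E), ann$symbol)]
  unann <- rownames(E)[is.na(loc_of)]
  keep <- !is.na(loc_of)
  if (!any(keep)) stop("no annotated symbols")
  Ek <- E[keep, , drop = FALSE]
  loc <- loc_of[keep]
  locs <- unique(loc)
  summary <- data.frame(
    location = locs,
    n_symbols = as.integer(table(loc)[locs]),
    mean_expression = vapply(locs, function(l) {
      v <- Ek[loc == l, , drop = FALSE]
      mean(v[is.finite(v)])
    }, 0),
    row.names = NULL, stringsAsFactors = FALSE)
  summary <- summary[order(-summary$mean_expression), ]
  rownames(summary) <- NULL
  heatmap <- t(vapply(locs, function(l)
    colMeans(Ek[loc == l, , drop = FALSE], na.rm = TRUE),
    numeric(ncol(Ek))))
  rownames(heatmap) <- locs
  list(summary = summary, heatmap = heatmap, unannotated = unann)
}
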