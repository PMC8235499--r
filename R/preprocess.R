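#' Multiplicative background correction
#'
#' Subtracts the log2 background estimate from the log2 foreground estimate
#' cellwise: \code{log2(fg) - log2(bg)} wherever both channels are positive;
#' cells with a non-positive channel become NaN. When \code{bg} is NULL the
#' data are taken as already background corrected and pass through as
#' \code{log2(fg)} with the attribute \code{assumed_corrected = TRUE}.
#'
#' @param fg foreground intensity matrix (entries >= 0 or NaN).
#' @param bg background matrix of the same shape, or NULL.
#' @return log2-scale matrix with attribute \code{assumed_corrected}.
#' @export
background_correct_mbc <- function(fg, bg = NULL) {
  fg <- as.matrix(fg)
  if (is.null(bg)) {
    out <- ifelse(!is.na(fg) & fg > 0, log2(pmax(fg, .Machine$double.xmin)),
                  NA_real_)
    dim(out) <- dim(fg); dimnames(out) <- dimnames(fg)
    attr(out, "assumed_corrected") <- TRUE
    return(out)
  }
  bg <- as.matrix(bg)
  if (!all(dim(fg) == dim(bg)))
    stop("foreground and background shapes differ: ",
         paste(dim(fg), collapse = "x"), " vs ",
         paste(dim(bg), collapse = "x"))
  ok <- !is.na(fg) & !is.na(bg) & fg > 0 & bg > 0
  out <- matrix(NA_real_, nrow(fg), ncol(fg), dimnames = dimnames(fg))
  out[ok] <- log2(fg[ok]) - log2(bg[ok])
  attr(out, "assumed_corrected") <- FALSE
  out
}

#' Mask negative values as missing
#'
#' Replaces entries below zero with NaN (zeros are kept: low intensities may
#' still be biologically informative). Existing NaN cells are preserved. The
#' number of newly masked cells is attached as attribute \code{n_masked}.
#'
#' @param m numeric matrix.
#' @return masked matrix with attribute \code{n_masked}.
#' @export
mask_nonpositive <- function(m) {
  m <- as.matrix(m)
  neg <- !is.na(m) & m < 0
  m[neg] <- NA_real_
  attr(m, "n_masked") <- sum(neg)
  m
}

#' Normalize sample columns
#'
#' Three schemes, all NaN-aware and column-order preserving:
#' \describe{
#'   \item{quantile}{columns mapped onto the mean quantile profile
#'     (delegated to \code{\link[limma]{normalizeQuantiles}}, which computes
#'     ranks over non-missing entries and interpolates the target profile to
#'     each column's non-missing count).}
#'   \item{loess}{each column MA-adjusted against the row-median
#'     pseudo-reference by local regression with the given span.}
#'   \item{rank_invariant}{per column, features whose rank against the
#'     pseudo-reference changes by at most \code{ri_threshold} of the feature
#'     count form the invariant set; a lowess curve through that set maps the
#'     column onto the reference scale.}
#' }
#' Columns with fewer than two finite values are left unchanged with a
#' warning.
#'
#' @param m numeric matrix (features x samples) with NaN for missing.
#' @param method one of "quantile", "loess", "rank_invariant".
#' @param span loess span (default 0.4).
#' @param ri_threshold rank-invariance tolerance as a fraction of the feature
#'   count (default 0.05).
#' @return normalized matrix.
#' @export
normalize_expression <- function(m,
                                 method = c("quantile", "loess",
                                            "rank_invariant"),
                                 span = 0.4, ri_threshold = 0.05) {
  method <- match.arg(method)
  m <- as.matrix(m)
  if (ncol(m) < 2) stop("need at least 2 columns to normalize")
  n_finite <- colSums(!is.na(m))
  thin <- n_finite < 2
  if (any(thin))
    warning("column(s) with < 2 finite values left unchanged: ",
            paste(colnames(m)[thin], collapse = ", "))
  work <- m[, !thin, drop = FALSE]
  out <- switch(method,
                quantile = limma::normalizeQuantiles(work, ties = TRUE),
                loess = normalize_loess_ref(work, span),
                rank_invariant = normalize_rank_invariant(work, ri_threshold))
  m[, !thin] <- out
  m
}

# MA-loess of each column against the row-median pseudo-reference.
normalize_loess_ref <- function(m, span) {
  ref <- apply(m, 1, stats::median, na.rm = TRUE)
  out <- m
  for (j in seq_len(ncol(m))) {
    ok <- !is.na(m[, j]) & !is.na(ref)
    if (sum(ok) < 10) next
    A <- (m[ok, j] + ref[ok]) / 2
    M <- m[ok, j] - ref[ok]
    fit <- stats::lowess(A, M, f = span)
    bias <- stats::approx(fit$x, fit$y, xout = A, rule = 2, ties = mean)$y
    out[ok, j] <- m[ok, j] - bias
  }
  out
}

# Rank-invariant scaling of each column onto the pseudo-reference scale.
normalize_rank_invariant <- function(m, threshold) {
  ref <- apply(m, 1, stats::median, na.rm = TRUE)
  out <- m
  for (j in seq_len(ncol(m))) {
    ok <- !is.na(m[, j]) & !is.na(ref)
    x <- m[ok, j]; r <- ref[ok]
    n <- length(x)
    if (n < 10) next
    inv <- abs(rank(x) - rank(r)) <= threshold * n
    if (sum(inv) < 5) {
      warning("column ", j, ": invariant set too small, left unchanged")
      next
    }
    fit <- stats::lowess(x[inv], r[inv], f = 2 / 3)
    out[ok, j] <- stats::approx(fit$x, fit$y, xout = x, rule = 2,
                                ties = mean)$y
  }
  out
}

#' Compare normalization schemes
#'
#' Scores each scheme (plus the raw input, "none") by two criteria, lower
#' being better: the mean pairwise Kolmogorov-Smirnov distance between
#' column distributions, and the variance of column medians pooled between
#' series (plain variance if no series map is given). Methods are ranked by
#' mean KS distance.
#'
#' @param m matrix to normalize.
#' @param series optional series id per column for the pooled variance.
#' @param methods schemes to evaluate.
#' @inheritParams normalize_expression
#' @return data.frame with columns method, mean_ks, median_var, rank.
#' @export
compare_normalizations <- function(m, series = NULL,
                                   methods = c("quantile", "loess",
                                               "rank_invariant"),
                                   span = 0.4, ri_threshold = 0.05) {
  eval_one <- function(x) {
    cols <- lapply(seq_len(ncol(x)), function(j) x[!is.na(x[, j]), j])
    pairs <- utils::combn(ncol(x), 2)
    ks <- apply(pairs, 2, function(p) {
      a <- cols[[p[1]]]; b <- cols[[p[2]]]
      if (!length(a) || !length(b)) return(NA_real_)
      suppressWarnings(stats::ks.test(a, b)$statistic)
    })
    med <- vapply(cols, stats::median, 0)
    mv <- if (is.null(series)) stats::var(med) else {
      grp <- split(med, series)
      mean(vapply(grp[lengths(grp) > 1], stats::var, 0))
    }
    c(mean_ks = mean(ks, na.rm = TRUE), median_var = mv)
  }
  res <- rbind(none = eval_one(m),
               t(vapply(methods, function(meth)
                 eval_one(suppressWarnings(normalize_expression(
                   m, meth, span = span, ri_threshold = ri_threshold))),
                 c(mean_ks = 0, median_var = 0))))
  out <- data.frame(method = rownames(res), res, row.names = NULL)
  out$rank <- rank(out$mean_ks, ties.method = "min")
  out[order(out$rank), ]
}

#' Global-mean rescaling
#'
#' Divides every cell by the global mean over non-missing cells, the
#' algebraic equivalent of forming the log2 ratio against the global mean and
#' exponentiating back. After rescaling, the non-missing mean is 1 (to 1e-9)
#' and the operation is idempotent.
#'
#' @param m numeric matrix.
#' @return rescaled matrix with attribute \code{global_mean}.
#' @export
global_mean_rescale <- function(m) {
  m <- as.matrix(m)
  gm <- mean(m, na.rm = TRUE)
  if (!is.finite(gm) || gm <= 0)
    stop("global mean of non-missing entries is not positive: ", gm)
  out <- m / gm
  attr(out, "global_mean") <- gm
  out
}

#' Average within-symbol replicate rows
#'
#' Collapses rows sharing a canonical symbol to their NaN-ignoring mean per
#' sample; a cell is NaN iff all contributing cells are NaN. Output rows are
#' in first-occurrence order of the symbols.
#'
#' @param m numeric matrix.
#' @param symbol_of_row symbol per row (default: rownames).
#' @return matrix with one row per symbol.
#' @export
average_replicates <- function(m, symbol_of_row = rownames(m)) {
  m <- as.matrix(m)
  if (is.null(symbol_of_row) || length(symbol_of_row) != nrow(m))
    stop("every row must be mapped to a canonical symbol")
  sym <- factor(symbol_of_row, levels = unique(symbol_of_row))
  vals <- m; vals[is.na(vals)] <- 0
  sums <- rowsum(vals, sym)
  counts <- rowsum((!is.na(m)) * 1, sym)
  out <- sums / counts
  out[counts == 0] <- NA_real_
  rownames(out) <- levels(sym)
  out
}

#' Run the full preprocessing chain on a hyper-matrix
#'
#' Fixed stage order: multiplicative background correction, negative-value
#' masking, normalization, global-mean rescaling, replicate averaging. Each
#' stage appends its provenance tag; \code{\link{validate_stages}} checks the
#' sequence.
#'
#' @param hm a \code{hypermatrix} from \code{\link{assemble_hypermatrix}}.
#' @param method normalization scheme.
#' @inheritParams normalize_expression
#' @return the \code{hypermatrix} with processed \code{values} (one row per
#'   symbol) and stage tags
#'   \code{raw, mbc, masked, normalized, rescaled, averaged}.
#' @export
preprocess_hypermatrix <- function(hm, method = "quantile", span = 0.4,
                                   ri_threshold = 0.05) {
  stopifnot(inherits(hm, "hypermatrix"))
  if (!identical(hm$stage[length(hm$stage)], "raw"))
    stop("preprocess_hypermatrix expects a raw hypermatrix; got stage ",
         paste(hm$stage, collapse = " -> "))
  v <- hm$values
  assumed <- character(0)
  if (is.null(hm$background)) {
    v <- background_correct_mbc(v, NULL)
    assumed <- unique(hm$series_of_sample)
  } else {
    out <- matrix(NA_real_, nrow(v), ncol(v), dimnames = dimnames(v))
    for (sid in unique(hm$series_of_sample)) {
      cols <- names(hm$series_of_sample)[hm$series_of_sample == sid]
      if (isTRUE(hm$series_has_background[sid])) {
        out[, cols] <- background_correct_mbc(v[, cols, drop = FALSE],
                                              hm$background[, cols,
                                                            drop = FALSE])
      } else {
        out[, cols] <- background_correct_mbc(v[, cols, drop = FALSE], NULL)
        assumed <- c(assumed, sid)
      }
    }
    v <- out
  }
  hm$notes$assumed_background_corrected <- assumed
  hm$stage <- c(hm$stage, "mbc")

  v <- mask_nonpositive(v)
  hm$notes$n_masked <- attr(v, "n_masked")
  hm$stage <- c(hm$stage, "masked")

  v <- normalize_expression(v, method, span = span,
                            ri_threshold = ri_threshold)
  hm$notes$normalization <- method
  hm$stage <- c(hm$stage, "normalized")

  v <- global_mean_rescale(v)
  hm$notes$global_mean <- attr(v, "global_mean")
  hm$stage <- c(hm$stage, "rescaled")

  v <- average_replicates(v, hm$symbols)
  hm$stage <- c(hm$stage, "averaged")

  hm$values <- v
  hm$background <- NULL
  hm$symbols <- rownames(v)
  hm
}

#' Validate the preprocessing stage sequence of a hyper-matrix
#'
#' @param hm a \code{hypermatrix}.
#' @return TRUE invisibly; error if tags are out of order.
#' @export
validate_stages <- function(hm) {
  full <- c("raw", "mbc", "masked", "normalized", "rescaled", "averaged")
  if (!identical(hm$stage, full[seq_along(hm$stage)]))
    stop("stage sequence out of order: ", paste(hm$stage, collapse = " -> "))
  invisible(TRUE)
}
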