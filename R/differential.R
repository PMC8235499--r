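#' Per-symbol two-sample t-tests (tumor vs control)
#'
#' Vectorised row-wise two-sample t statistics with two-tailed p-values,
#' ignoring missing cells. The pooled-variance form is the default; Welch is
#' available. Symbols with fewer than two finite values in either group are
#' reported untested (\code{tested = FALSE}). Degenerate symbols (zero
#' variance in both groups) get p = 1 when the group means are equal and
#' p = 0 otherwise, flagged in the \code{flag} column. Benjamini-Hochberg
#' q-values are attached over the tested symbols.
#'
#' @param m numeric matrix (symbols x samples), e.g. preprocessed naturals.
#' @param is_tumor logical per column, TRUE for tumor samples.
#' @param variant "pooled" (default) or "welch".
#' @return data.frame with one row per symbol: t, p, q, group sizes used,
#'   group means, tested, flag.
#' @export
t_test_per_symbol <- function(m, is_tumor, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  m <- as.matrix(m)
  stopifnot(length(is_tumor) == ncol(m), is.logical(is_tumor))
  if (is.null(rownames(m))) rownames(m) <- paste0("row", seq_len(nrow(m)))
  x <- m[, is_tumor, drop = FALSE]
  y <- m[, !is_tumor, drop = FALSE]
  nx <- rowSums(!is.na(x)); ny <- rowSums(!is.na(y))
  mx <- rowMeans(x, na.rm = TRUE); my <- rowMeans(y, na.rm = TRUE)
  vx <- apply(x, 1, stats::var, na.rm = TRUE)
  vy <- apply(y, 1, stats::var, na.rm = TRUE)
  tested <- nx >= 2 & ny >= 2

  tstat <- p <- rep(NA_real_, nrow(m))
  flag <- rep("", nrow(m))
  if (variant == "pooled") {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  } else {
    se <- sqrt(vx / nx + vy / ny)
    df <- (vx / nx + vy / ny) ^ 2 /
      ((vx / nx) ^ 2 / (nx - 1) + (vy / ny) ^ 2 / (ny - 1))
  }
  ok <- tested & !is.na(se) & se > 0
  tstat[ok] <- (mx[ok] - my[ok]) / se[ok]
  p[ok] <- 2 * stats::pt(abs(tstat[ok]), df[ok], lower.tail = FALSE)
  degen <- tested & !ok
  if (any(degen)) {
    eq <- degen & abs(mx - my) < .Machine$double.eps ^ 0.5
    tstat[eq] <- 0; p[eq] <- 1
    tstat[degen & !eq] <- sign(mx - my)[degen & !eq] * Inf
    p[degen & !eq] <- 0
    flag[degen] <- "degenerate"
  }
  flag[!tested] <- "untested"

  q <- rep(NA_real_, nrow(m))
  q[tested] <- fdr_adjust(p[tested])
  data.frame(symbol = rownames(m), t = tstat, p = p, q = q,
             n_tumor_used = nx, n_control_used = ny,
             mean_tumor = mx, mean_control = my,
             tested = tested, flag = flag,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Wraps \code{stats::p.adjust(method = "BH")} after validating the input;
#' order of the input is preserved and monotonicity is enforced by the
#' step-up construction.
#'
#' @param p numeric vector of p-values in [0, 1] (NA allowed, passed through).
#' @return adjusted q-values in the input order.
#' @export
fdr_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values outside [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Select differentially expressed symbols
#'
#' @param res result of \code{\link{t_test_per_symbol}}.
#' @param p_max raw p-value threshold (default 0.05).
#' @param q_max BH q-value threshold (default 0.05). The realized FDR bound
#'   of any given dataset is a property of that dataset; it is configured
#'   here, never hard-coded.
#' @return character vector of selected symbols, sorted by p.
#' @export
select_de <- function(res, p_max = 0.05, q_max = 0.05) {
  sel <- res[res$tested & !is.na(res$p) & res$p < p_max &
               !is.na(res$q) & res$q < q_max, ]
  sel$symbol[order(sel$p)]
}

#' Log2 tumor/control-mean ratio matrix
#'
#' For each symbol, forms the NaN-ignoring mean over control samples and
#' the log2 ratio of every tumor sample against it. Cells with a
#' non-positive numerator or denominator are NaN and counted in the
#' \code{report} attribute; symbols with no finite control value give an
#' all-NaN row, listed in \code{report$no_control}.
#'
#' @param m numeric matrix of naturals (symbols x samples).
#' @param is_tumor logical per column.
#' @return matrix of log2 ratios (symbols x tumor samples) with attribute
#'   \code{report}.
#' @export
tumor_to_control_ratio <- function(m, is_tumor) {
  m <- as.matrix(m)
  stopifnot(length(is_tumor) == ncol(m))
  tum <- m[, is_tumor, drop = FALSE]
  ctl <- m[, !is_tumor, drop = FALSE]
  if (ncol(ctl) < 1) stop("at least one control sample required")
  cbar <- rowMeans(ctl, na.rm = TRUE)
  no_control <- !is.finite(cbar)
  E <- suppressWarnings(log2(sweep(tum, 1, cbar, "/")))
  bad <- !is.na(tum) & (tum <= 0 | rep(cbar <= 0 | no_control, ncol(tum)))
  E[!is.finite(E)] <- NA_real_
  n_nonpos <- sum(bad & !is.na(tum))
  attr(E, "report") <- list(n_nonpositive = n_nonpos,
                            no_control = rownames(m)[no_control])
  E
}
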