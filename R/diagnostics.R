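#' ROC curve and AUC for a single marker
#'
#' AUC via the Mann-Whitney U identity (ties counted one half), with the ROC
#' curve evaluated at every score threshold; the trapezoidal area of the
#' returned curve equals the rank AUC to numerical precision. The
#' orientation is chosen automatically so that AUC >= 0.5 and recorded
#' (\code{low_predicts_tumor = TRUE} for markers whose low values indicate
#' tumors, i.e. down-regulated markers). The p-value against AUC = 0.5 comes
#' from the normal-approximation Mann-Whitney test with tie correction.
#'
#' @param scores numeric score per sample (NA dropped pairwise with labels).
#' @param is_tumor logical per sample; both classes must be non-empty.
#' @return \code{roc_result}: list with auc (oriented, >= 0.5), auc_raw
#'   (probability a tumor sample scores higher than a control, before
#'   orientation), p, curve (data.frame fpr, tpr, threshold),
#'   low_predicts_tumor, n_tumor, n_control.
#' @export
roc_auc <- function(scores, is_tumor) {
  ok <- !is.na(scores) & !is.na(is_tumor)
  scores <- scores[ok]; is_tumor <- as.logical(is_tumor[ok])
  n1 <- sum(is_tumor); n0 <- sum(!is_tumor)
  if (n1 == 0 || n0 == 0) stop("both classes must be non-empty")

  auc_of <- function(s) {
    r <- rank(s)
    (sum(r[is_tumor]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  a <- auc_of(scores)
  flip <- a < 0.5
  s <- if (flip) -scores else scores
  auc <- if (flip) 1 - a else a

  # curve over all thresholds of the oriented score (predict tumor if s >= t)
  thr <- sort(unique(s), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(s[is_tumor] >= t) / n1, 0)
  fpr <- vapply(thr, function(t) sum(s[!is_tumor] >= t) / n0, 0)
  curve <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                      tpr = c(0, tpr))
  if (curve$fpr[nrow(curve)] != 1 || curve$tpr[nrow(curve)] != 1)
    curve <- rbind(curve, data.frame(threshold = -Inf, fpr = 1, tpr = 1))

  p <- if (length(unique(s)) == 1) 1 else
    suppressWarnings(stats::wilcox.test(s[is_tumor], s[!is_tumor],
                                        exact = FALSE,
                                        correct = FALSE)$p.value)
  structure(list(auc = auc, auc_raw = a, p = p, curve = curve,
                 low_predicts_tumor = flip, n_tumor = n1, n_control = n0),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f (p = %.3g), %d tumors vs %d controls%s\n",
              x$auc, x$p, x$n_tumor, x$n_control,
              if (x$low_predicts_tumor) ", low score predicts tumor" else ""))
  invisible(x)
}

#' Trapezoidal area under a ROC curve
#'
#' @param curve data.frame with columns fpr, tpr (monotone).
#' @return the trapezoidal area.
#' @export
trapezoid_auc <- function(curve) {
  sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) +
                           utils::tail(curve$tpr, -1)) / 2)
}

# Gaussian class-conditional naive Bayes (maximum a posteriori rule).
# Variances below `floor` are floored and flagged.
gaussian_nb_fit <- function(x, y, var_floor = 1e-9) {
  y <- factor(y)
  fit <- list(classes = levels(y), var_floor = var_floor,
              priors = as.numeric(table(y)) / length(y), flagged = FALSE)
  fit$mu <- vapply(levels(y), function(cl)
    colMeans(x[y == cl, , drop = FALSE]), numeric(ncol(x)))
  v <- vapply(levels(y), function(cl)
    apply(x[y == cl, , drop = FALSE], 2, stats::var), numeric(ncol(x)))
  if (any(v < var_floor, na.rm = TRUE) || anyNA(v)) fit$flagged <- TRUE
  v[is.na(v) | v < var_floor] <- var_floor
  fit$var <- v
  dim(fit$mu) <- dim(fit$var) <- c(ncol(x), length(levels(y)))
  fit
}

gaussian_nb_predict <- function(fit, x) {
  ll <- vapply(seq_along(fit$classes), function(j) {
    rowSums(stats::dnorm(x, rep(fit$mu[, j], each = nrow(x)),
                         rep(sqrt(fit$var[, j]), each = nrow(x)),
                         log = TRUE)) + log(fit$priors[j])
  }, numeric(nrow(x)))
  if (is.null(dim(ll))) dim(ll) <- c(nrow(x), length(fit$classes))
  fit$classes[max.col(ll, ties.method = "first")]
}

#' Cross-validated Gaussian naive Bayes classification
#'
#' Stratified k-fold cross-validation of a Gaussian class-conditional naive
#' Bayes classifier (maximum a posteriori decision rule; within-class
#' variances floored at 1e-9 and flagged). Deterministic under the seed.
#'
#' @param features matrix, symbols x samples (complete; impute first if
#'   needed).
#' @param labels class label per sample (e.g. tumor/control).
#' @param folds number of CV folds (default 5); each class needs at least
#'   \code{folds} samples.
#' @param seed integer seed for the fold shuffle.
#' @return \code{nbayes_report}: folds, seed, per-fold accuracy, mean
#'   accuracy, confusion matrix, class priors, fold assignment,
#'   variance_floored flag.
#' @export
naive_bayes_cv <- function(features, labels, folds = 5, seed = 1L) {
  x <- t(as.matrix(features))       # samples x features
  y <- factor(labels)
  if (any(table(y) < folds))
    stop("each class needs at least ", folds, " samples")
  set.seed(as.integer(seed))
  fold_of <- integer(nrow(x))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold_of[idx] <- rep_len(seq_len(folds), length(idx))
  }
  pred <- character(nrow(x))
  flagged <- FALSE
  acc <- numeric(folds)
  for (f in seq_len(folds)) {
    test <- fold_of == f
    fit <- gaussian_nb_fit(x[!test, , drop = FALSE], y[!test])
    flagged <- flagged || fit$flagged
    pred[test] <- gaussian_nb_predict(fit, x[test, , drop = FALSE])
    acc[f] <- mean(pred[test] == as.character(y[test]))
  }
  cm <- table(truth = y, predicted = factor(pred, levels = levels(y)))
  structure(list(folds = folds, seed = as.integer(seed),
                 fold_accuracy = acc, mean_accuracy = mean(acc),
                 confusion = cm,
                 priors = as.numeric(table(y)) / length(y),
                 fold_of = fold_of, variance_floored = flagged),
            class = "nbayes_report")
}

#' @export
print.nbayes_report <- function(x, ...) {
  cat(sprintf("naive Bayes %d-fold CV: mean accuracy %.3f\n",
              x$folds, x$mean_accuracy))
  print(x$confusion)
  invisible(x)
}

#' Association statistics for a contingency table
#'
#' Pearson chi-square test of independence (continuity correction off by
#' default); for 2x2 tables additionally the odds ratio OR = ad/bc, relative
#' risk RR = [a/(a+b)] / [c/(c+d)] and absolute risk difference
#' AR = a/(a+b) - c/(c+d). A zero cell triggers the Haldane-Anscombe +0.5
#' correction for the OR (flagged); RR and AR are computed from the raw
#' counts.
#'
#' @param tab matrix of non-negative counts (r x c; OR/RR/AR only for 2x2).
#' @param correct apply Yates continuity correction (default FALSE).
#' @return list with chisq, df, p and, for 2x2, odds_ratio, relative_risk,
#'   absolute_risk, haldane_corrected.
#' @export
cohort_association <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("counts must be non-negative")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  out <- list(chisq = unname(ct$statistic), df = unname(ct$parameter),
              p = ct$p.value)
  if (all(dim(tab) == 2)) {
    a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
    haldane <- any(tab == 0)
    if (haldane) {
      out$odds_ratio <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
    } else {
      out$odds_ratio <- (a * d) / (b * c)
    }
    out$relative_risk <- (a / (a + b)) / (c / (c + d))
    out$absolute_risk <- a / (a + b) - c / (c + d)
    out$haldane_corrected <- haldane
  }
  out
}
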