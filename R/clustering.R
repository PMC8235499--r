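#' Prepare a matrix with missing values for clustering
#'
#' K-means needs complete vectors. Rows (features) covered in less than
#' \code{min_coverage} of the columns are dropped -- under block-diagonal
#' missingness these are the features private to a subset of series, whose
#' profiles are not comparable across the full sample set -- and the
#' remaining NaN cells are imputed by the row median.
#'
#' @param m numeric matrix with NaN.
#' @param min_coverage minimum non-missing fraction per row (default 0.8).
#' @return complete matrix; dropped rows recorded in attribute
#'   \code{dropped_rows}.
#' @export
prepare_for_clustering <- function(m, min_coverage = 0.8) {
  m <- as.matrix(m)
  cov <- rowMeans(!is.na(m))
  keep_row <- cov >= min_coverage & cov > 0
  x <- m[keep_row, , drop = FALSE]
  med <- apply(x, 1, stats::median, na.rm = TRUE)
  idx <- which(is.na(x), arr.ind = TRUE)
  if (nrow(idx)) x[idx] <- med[idx[, 1]]
  attr(x, "dropped_rows") <- rownames(m)[!keep_row]
  x
}

# squared Euclidean distances between rows of x and rows of centers
.dist2 <- function(x, centers) {
  outer(rowSums(x ^ 2), rep(1, nrow(centers))) +
    outer(rep(1, nrow(x)), rowSums(centers ^ 2)) - 2 * x %*% t(centers)
}

# k-means++ seeding
.kmeanspp <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- .dist2(x, centers[1, , drop = FALSE])[, 1]
  for (i in seq_len(k)[-1]) {
    prob <- pmax(d2, 0)
    if (sum(prob) <= 0) prob <- rep(1, n)
    centers[i, ] <- x[sample.int(n, 1, prob = prob), ]
    d2 <- pmin(d2, .dist2(x, centers[i, , drop = FALSE])[, 1])
  }
  centers
}

#' K-means clustering with k-means++ seeding
#'
#' Lloyd's algorithm under the squared-Euclidean distance, k-means++
#' initialisation, up to \code{n_iterations} update steps per restart and the
#' best of \code{n_restarts} restarts by within-cluster sum of squares
#' (WCSS). The WCSS trace of the winning restart is returned and checked to
#' be non-increasing; empty clusters are repaired by reseeding on the point
#' farthest from its center. Deterministic under \code{seed}.
#'
#' @param m complete numeric matrix (rows are clustered) or a matrix with
#'   NaN, which is first passed through \code{\link{prepare_for_clustering}}.
#' @param k number of clusters (2 <= k <= number of distinct rows).
#' @param n_iterations Lloyd iteration cap per restart (default 100).
#' @param n_restarts independent restarts (default 10).
#' @param seed integer seed.
#' @return a \code{cluster_model}: list with k, assignments (named integer),
#'   centroids, sorted_centroids (each centroid's values sorted decreasing),
#'   wcss, wcss_trace, seed, n_restarts.
#' @export
kmeans_cluster <- function(m, k, n_iterations = 100, n_restarts = 10,
                           seed = 1L) {
  x <- if (anyNA(m)) prepare_for_clustering(m) else as.matrix(m)
  if (k < 2) stop("k must be at least 2")
  if (nrow(unique(x)) < k)
    stop("k = ", k, " exceeds the number of distinct rows (",
         nrow(unique(x)), ")")
  set.seed(as.integer(seed))
  best <- NULL
  for (r in seq_len(n_restarts)) {
    centers <- .kmeanspp(x, k)
    trace <- numeric(0)
    assign_old <- rep(0L, nrow(x))
    for (it in seq_len(n_iterations)) {
      d2 <- .dist2(x, centers)
      assign_new <- max.col(-d2, ties.method = "first")
      # repair empty clusters with the globally farthest point
      for (cl in which(tabulate(assign_new, k) == 0)) {
        far <- which.max(d2[cbind(seq_len(nrow(x)), assign_new)])
        assign_new[far] <- cl
        centers[cl, ] <- x[far, ]
        d2 <- .dist2(x, centers)
        assign_new <- max.col(-d2, ties.method = "first")
        assign_new[far] <- cl
      }
      wcss <- sum(d2[cbind(seq_len(nrow(x)), assign_new)])
      trace <- c(trace, wcss)
      if (identical(assign_new, assign_old)) break
      assign_old <- assign_new
      centers <- t(vapply(seq_len(k), function(cl)
        colMeans(x[assign_new == cl, , drop = FALSE]), numeric(ncol(x))))
    }
    if (any(diff(trace) > 1e-8 * max(trace[1], 1)))
      stop("internal error: WCSS increased across Lloyd iterations")
    if (is.null(best) || trace[length(trace)] < best$wcss)
      best <- list(assignments = assign_new, centers = centers,
                   wcss = trace[length(trace)], trace = trace)
  }
  names(best$assignments) <- rownames(x)
  colnames(best$centers) <- colnames(x)
  sorted <- t(apply(best$centers, 1, sort, decreasing = TRUE))
  structure(list(k = k, assignments = best$assignments,
                 centroids = best$centers, sorted_centroids = sorted,
                 wcss = best$wcss, wcss_trace = best$trace,
                 seed = as.integer(seed), n_restarts = n_restarts,
                 data = x),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("k-means model: k =", x$k, ", WCSS =", signif(x$wcss, 6), "\n")
  print(table(cluster = x$assignments))
  invisible(x)
}

#' Calinski-Harabasz score of a clustering
#'
#' CH = [B / (k - 1)] / [W / (n - k)], where B is the between-cluster and W
#' the within-cluster sum of squares about the global and cluster centroids.
#' Perfect separation (W = 0) returns Inf with attribute
#' \code{perfect_separation}.
#'
#' @param m complete numeric matrix.
#' @param assignments integer cluster label per row (>= 2 non-empty
#'   clusters).
#' @return the CH score.
#' @export
calinski_harabasz <- function(m, assignments) {
  x <- as.matrix(m)
  cl <- as.integer(factor(assignments))
  k <- length(unique(cl))
  n <- nrow(x)
  if (k < 2) stop("Calinski-Harabasz requires at least 2 clusters")
  g <- colMeans(x)
  W <- 0; B <- 0
  for (c in unique(cl)) {
    xc <- x[cl == c, , drop = FALSE]
    mc <- colMeans(xc)
    W <- W + sum(sweep(xc, 2, mc) ^ 2)
    B <- B + nrow(xc) * sum((mc - g) ^ 2)
  }
  if (W <= .Machine$double.eps * sum(x ^ 2)) {
    out <- Inf
    attr(out, "perfect_separation") <- TRUE
    return(out)
  }
  (B / (k - 1)) / (W / (n - k))
}

#' Select the number of clusters by the Calinski-Harabasz criterion
#'
#' Runs \code{\link{kmeans_cluster}} for every candidate k and returns the
#' argmax of the CH score together with the full score table.
#'
#' @param m matrix to cluster.
#' @param k_range candidate k values (default 2:10).
#' @param seed integer seed (fanned out per k).
#' @param ... passed to \code{\link{kmeans_cluster}}.
#' @return list with \code{k_star}, \code{ch_scores} (named numeric) and
#'   \code{models} (one \code{cluster_model} per candidate).
#' @export
select_k <- function(m, k_range = 2:10, seed = 1L, ...) {
  x <- if (anyNA(m)) prepare_for_clustering(m) else as.matrix(m)
  k_range <- k_range[k_range <= nrow(unique(x))]
  if (!length(k_range)) stop("no feasible k in k_range")
  models <- lapply(k_range, function(k)
    kmeans_cluster(x, k, seed = derive_seed(seed, k), ...))
  ch <- vapply(models, function(mod)
    as.numeric(calinski_harabasz(x, mod$assignments)), 0)
  names(ch) <- k_range
  names(models) <- k_range
  list(k_star = k_range[which.max(ch)], ch_scores = ch, models = models)
}

#' Agglomerative hierarchical clustering with Euclidean distance
#'
#' Wraps \code{stats::hclust} on the Euclidean distance matrix; all-missing
#' rows are excluded with a warning, remaining NaN are imputed as in
#' \code{\link{prepare_for_clustering}}. Sub-clusters are extracted by tree
#' cut with \code{\link{cut_subclusters}}.
#'
#' @param m numeric matrix (rows clustered).
#' @param linkage one of "average" (default), "single", "complete", "ward".
#' @return list with \code{hclust} (merge tree), \code{order} and
#'   \code{labels}.
#' @export
hierarchical_cluster <- function(m, linkage = c("average", "single",
                                                "complete", "ward")) {
  linkage <- match.arg(linkage)
  x <- as.matrix(m)
  if (nrow(x) < 2) stop("need at least 2 rows")
  all_na <- rowSums(!is.na(x)) == 0
  if (any(all_na)) {
    warning("excluding all-missing row(s): ",
            paste(rownames(x)[all_na], collapse = ", "))
    x <- x[!all_na, , drop = FALSE]
  }
  if (anyNA(x)) x <- prepare_for_clustering(x, min_coverage = 0)
  hc <- stats::hclust(stats::dist(x),
                      method = if (linkage == "ward") "ward.D2" else linkage)
  list(hclust = hc, order = hc$order, labels = hc$labels)
}

#' @param model result of \code{\link{hierarchical_cluster}}.
#' @param k number of sub-clusters (or use \code{h} for a height cut).
#' @param h cut height.
#' @rdname hierarchical_cluster
#' @export
cut_subclusters <- function(model, k = NULL, h = NULL) {
  stats::cutree(model$hclust, k = k, h = h)
}

#' Export a hierarchical tree as Newick
#'
#' @param model result of \code{\link{hierarchical_cluster}}.
#' @param path optional output file; otherwise the Newick string is returned.
#' @rdname hierarchical_cluster
#' @export
as_newick <- function(model, path = NULL) {
  if (!requireNamespace("ape", quietly = TRUE))
    stop("Newick export requires the 'ape' package")
  phy <- ape::as.phylo(model$hclust)
  if (is.null(path)) ape::write.tree(phy)
  else { ape::write.tree(phy, file = path); invisible(path) }
}

#' Collapse sample columns to category means (descriptive profiles)
#'
#' Columns are grouped by a metadata variable (diagnosis2, diagnosis3 or
#' grade) and collapsed to NaN-ignoring category means; the result feeds
#' descriptive (group-mean) k-means.
#'
#' @param m numeric matrix (symbols x samples).
#' @param meta metadata data.frame with a \code{sample_id} column.
#' @param variable metadata column to group by.
#' @return matrix of symbols x categories.
#' @export
group_mean_profiles <- function(m, meta,
                                variable = c("diagnosis2", "diagnosis3",
                                             "grade")) {
  variable <- match.arg(variable)
  m <- as.matrix(m)
  cat_of <- meta[[variable]][match(colnames(m), meta$sample_id)]
  if (anyNA(cat_of))
    stop("metadata missing for sample(s): ",
         paste(colnames(m)[is.na(cat_of)], collapse = ", "))
  cats <- unique(cat_of)
  out <- vapply(cats, function(cc)
    rowMeans(m[, cat_of == cc, drop = FALSE], na.rm = TRUE),
    numeric(nrow(m)))
  out[!is.finite(out)] <- NA_real_
  colnames(out) <- cats
  rownames(out) <- rownames(m)
  out
}

#' Detect ordered expression patterns across categories
#'
#' For each cluster, the per-sample cluster profile (mean over member
#' symbols) is grouped by a categorical variable; category means and SDs,
#' one-way ANOVA across categories and Bonferroni-adjusted pairwise t-tests
#' are reported. The monotone flag is TRUE when the category means are
#' strictly ordered (matching one of the candidate orders, if given) and the
#' ANOVA p-value is below \code{alpha}. Categories with fewer than two
#' samples are excluded from the ANOVA and noted.
#'
#' @param m numeric matrix (symbols x samples).
#' @param assignments cluster label per symbol (named by symbol).
#' @param categories category per sample (aligned with columns of \code{m}).
#' @param candidate_orders optional list of character vectors of category
#'   names; the realized order must match one of them.
#' @param alpha ANOVA significance level (default 0.05).
#' @return list of per-cluster \code{pattern_result}s: category_stats,
#'   anova_p, pairwise (Bonferroni-adjusted p matrix), order, monotone,
#'   excluded_categories.
#' @export
detect_ordered_pattern <- function(m, assignments, categories,
                                   candidate_orders = NULL, alpha = 0.05) {
  m <- as.matrix(m)
  stopifnot(length(categories) == ncol(m))
  categories <- as.character(categories)
  if (length(unique(categories)) < 3)
    stop("need at least 3 categories")
  syms <- intersect(rownames(m), names(assignments))
  out <- list()
  for (cl in sort(unique(assignments[syms]))) {
    members <- syms[assignments[syms] == cl]
    profile <- colMeans(m[members, , drop = FALSE], na.rm = TRUE)
    ok <- is.finite(profile)
    vals <- profile[ok]; cats <- categories[ok]
    tab <- table(cats)
    excluded <- names(tab)[tab < 2]
    usable <- !(cats %in% excluded)
    stats_df <- data.frame(
      category = names(tab),
      n = as.integer(tab),
      mean = vapply(names(tab), function(cc) mean(vals[cats == cc]), 0),
      sd = vapply(names(tab), function(cc) stats::sd(vals[cats == cc]), 0),
      row.names = NULL, stringsAsFactors = FALSE)
    anova_p <- NA_real_
    pairwise <- NULL
    if (length(unique(cats[usable])) >= 2) {
      fit <- stats::aov(v ~ g, data = data.frame(v = vals[usable],
                                                 g = factor(cats[usable])))
      anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
      pw <- stats::pairwise.t.test(vals[usable], factor(cats[usable]),
                                   p.adjust.method = "bonferroni",
                                   pool.sd = TRUE)
      pairwise <- pw$p.value
    }
    ord <- stats_df$category[order(stats_df$mean)]
    strict <- !any(duplicated(stats_df$mean))
    order_ok <- if (is.null(candidate_orders)) strict else
      strict && any(vapply(candidate_orders, function(co)
        identical(as.character(co), ord), TRUE))
    res <- list(cluster = cl, category_stats = stats_df, anova_p = anova_p,
                pairwise = pairwise, order = ord,
                monotone = isTRUE(order_ok) && !is.na(anova_p) &&
                  anova_p < alpha,
                excluded_categories = excluded)
    class(res) <- "pattern_result"
    out[[as.character(cl)]] <- res
  }
  out
}

# deterministic per-stage seed derivation from one master seed
derive_seed <- function(seed, salt) {
  s <- sum(utf8ToInt(paste0(seed, ":", salt)) *
             seq_along(utf8ToInt(paste0(seed, ":", salt))))
  as.integer((as.numeric(seed) * 2654435761 + s * 97 + 11) %% 2147483647)
}
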