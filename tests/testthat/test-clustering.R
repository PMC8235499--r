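make_blobs <- function(k, n_per = 15, dim = 4, sep = 10, sd = 1,
                       seed = 1) {
  set.seed(seed)
  centers <- matrix(stats::rnorm(k * dim), k) * sep
  x <- do.call(rbind, lapply(seq_len(k), function(i)
    sweep(matrix(stats::rnorm(n_per * dim, sd = sd), n_per), 2,
          centers[i, ], "+")))
  rownames(x) <- paste0("R", seq_len(nrow(x)))
  attr(x, "truth") <- rep(seq_len(k), each = n_per)
  x
}

test_that("k-means recovers two well-separated clouds", {
  x <- make_blobs(2, seed = 50)
  mod <- kmeans_cluster(x, 2, seed = 1)
  truth <- attr(x, "truth")
  expect_equal(length(unique(mod$assignments[truth == 1])), 1L)
  expect_equal(length(unique(mod$assignments[truth == 2])), 1L)
  expect_false(mod$assignments[1] == mod$assignments[30])
})

test_that("degenerate inputs and infeasible k are rejected", {
  same <- matrix(1, 5, 3)
  expect_error(kmeans_cluster(same, 2), "distinct rows")
  expect_error(kmeans_cluster(make_blobs(2), 1), "at least 2")
})

test_that("k-means attains the exhaustive-enumeration WCSS at tiny n", {
  set.seed(51)
  for (rep in 1:5) {
    x <- matrix(stats::rnorm(24), 12, 2)
    mod <- kmeans_cluster(x, 2, n_restarts = 20, seed = rep)
    expect_equal(mod$wcss, oracle_best_wcss_k2(x), tolerance = 1e-8)
  }
})

test_that("the WCSS trace is non-increasing and the fit deterministic", {
  x <- make_blobs(3, sep = 3, seed = 52)
  mod <- kmeans_cluster(x, 3, seed = 7)
  expect_true(all(diff(mod$wcss_trace) <= 1e-8))
  expect_identical(mod$assignments,
                   kmeans_cluster(x, 3, seed = 7)$assignments)
  # matches stats::kmeans at its many-restart optimum
  ref <- stats::kmeans(x, 3, nstart = 25, iter.max = 100,
                       algorithm = "Lloyd")
  expect_equal(mod$wcss, ref$tot.withinss, tolerance = 1e-6)
})

test_that("sorted centroids are the centroid values in decreasing order", {
  x <- make_blobs(2, seed = 53)
  mod <- kmeans_cluster(x, 2, seed = 2)
  for (i in 1:2)
    expect_equal(mod$sorted_centroids[i, ],
                 sort(mod$centroids[i, ], decreasing = TRUE),
                 ignore_attr = TRUE)
})

test_that("Calinski-Harabasz matches a hand computation on 8 points", {
  x <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1),
             c(10, 10), c(11, 10), c(10, 11), c(11, 11))
  cl <- rep(1:2, each = 4)
  g <- colMeans(x)
  W <- sum(sweep(x[1:4, ], 2, colMeans(x[1:4, ])) ^ 2) +
       sum(sweep(x[5:8, ], 2, colMeans(x[5:8, ])) ^ 2)
  B <- 4 * sum((colMeans(x[1:4, ]) - g) ^ 2) +
       4 * sum((colMeans(x[5:8, ]) - g) ^ 2)
  expect_equal(calinski_harabasz(x, cl), (B / 1) / (W / 6))
  # zero within-scatter: perfect separation
  y <- rbind(c(0, 0), c(0, 0), c(5, 5), c(5, 5))
  ch <- calinski_harabasz(y, c(1, 1, 2, 2))
  expect_true(is.infinite(ch))
  expect_true(attr(ch, "perfect_separation"))
  expect_error(calinski_harabasz(x, rep(1, 8)), "2 clusters")
})

test_that("random assignments on structureless data score near one", {
  set.seed(54)
  scores <- replicate(40, {
    x <- matrix(stats::rnorm(60 * 3), 60, 3)
    calinski_harabasz(x, sample(1:3, 60, replace = TRUE))
  })
  expect_gt(mean(scores), 0.6)
  expect_lt(mean(scores), 1.6)
})

test_that("CH selection returns the planted number of clusters", {
  for (k in 2:4) {
    x <- make_blobs(k, seed = 60 + k)
    sel <- select_k(x, k_range = 2:6, seed = 5)
    expect_equal(sel$k_star, k)
    expect_named(sel$ch_scores, as.character(2:6))
  }
})

test_that("hierarchical clustering merges nearest pairs first", {
  x <- rbind(A = c(0, 0), B = c(1, 0), C = c(6, 0))
  hc <- hierarchical_cluster(x)$hclust
  expect_equal(sort(hc$merge[1, ]), c(-2, -1))   # A,B first
  # duplicate rows merge at height zero
  y <- rbind(a = c(1, 1), b = c(1, 1), c = c(4, 4))
  expect_equal(hierarchical_cluster(y)$hclust$height[1], 0)
})

test_that("average-linkage heights match the brute-force agglomerator", {
  set.seed(55)
  for (rep in 1:5) {
    x <- matrix(stats::rnorm(12), 6, 2)
    hc <- hierarchical_cluster(x, "average")$hclust
    expect_equal(hc$height, oracle_average_linkage_heights(x),
                 tolerance = 1e-10)
    expect_true(all(diff(hc$height) >= -1e-12))
  }
})

test_that("all-missing rows are excluded with a warning; cuts and newick work", {
  x <- rbind(A = c(1, 2), B = c(NA, NA), C = c(5, 6), D = c(1.1, 2.2))
  expect_warning(mod <- hierarchical_cluster(x), "B")
  cut <- cut_subclusters(mod, k = 2)
  expect_equal(cut[["A"]], cut[["D"]])
  expect_false(cut[["A"]] == cut[["C"]])
  skip_if_not_installed("ape")
  nwk <- as_newick(mod)
  expect_match(nwk, "^\\(")
  expect_match(nwk, "A")
})

test_that("group-mean profiles equal the scalar group means", {
  set.seed(56)
  m <- rand_mat(15, 12, na_frac = 0.2)
  meta <- data.frame(sample_id = colnames(m),
                     diagnosis2 = sample(c("MALIGNANCY", "BENIGN",
                                           "CONTROL"), 12, replace = TRUE))
  got <- group_mean_profiles(m, meta, "diagnosis2")
  want <- oracle_group_means(m, meta$diagnosis2)
  expect_equal(got[, colnames(want)], want)
  # single-sample category passes through; equal columns collapse equal
  meta2 <- data.frame(sample_id = colnames(m)[1:3],
                      grade = c("I", "I", "II"))
  m2 <- m[, 1:3]
  got2 <- group_mean_profiles(m2, meta2, "grade")
  expect_equal(got2[, "II"], m2[, 3], ignore_attr = TRUE)
  expect_error(group_mean_profiles(m, meta, "country"))
})

test_that("ordered grade patterns are detected when planted", {
  set.seed(57)
  order_wanted <- c("CONTROL", "IV", "I", "II", "III")
  means <- c(CONTROL = 0, IV = 1, I = 2, II = 3, III = 4)
  cats <- rep(order_wanted, each = 8)
  m <- matrix(rep(means[cats], each = 10), 10, 40,
              dimnames = list(paste0("F", 1:10), paste0("s", 1:40)))
  m <- m + stats::rnorm(length(m), 0, 0.05)
  assign <- stats::setNames(rep(1L, 10), rownames(m))
  res <- detect_ordered_pattern(m, assign, cats,
                                candidate_orders = list(order_wanted))
  expect_true(res[["1"]]$monotone)
  expect_equal(res[["1"]]$order, order_wanted)
  expect_lt(res[["1"]]$anova_p, 0.05)
  expect_true(all(res[["1"]]$pairwise >= 0, na.rm = TRUE))
})

test_that("flat categories do not raise the monotone flag", {
  set.seed(58)
  cats <- rep(c("CONTROL", "I", "II", "III"), each = 6)
  m <- matrix(stats::rnorm(5 * 24, 0, 0.1), 5, 24,
              dimnames = list(paste0("F", 1:5), paste0("s", 1:24)))
  assign <- stats::setNames(rep(1L, 5), rownames(m))
  res <- detect_ordered_pattern(m, assign, cats,
                                candidate_orders =
                                  list(c("CONTROL", "I", "II", "III")))
  expect_false(res[["1"]]$monotone)
  expect_gt(res[["1"]]$anova_p, 0.05)
})

test_that("thin categories are excluded from the ANOVA but reported", {
  cats <- c(rep("A", 5), rep("B", 5), "C")
  m <- matrix(stats::rnorm(33), 3, 11,
              dimnames = list(paste0("F", 1:3), paste0("s", 1:11)))
  assign <- stats::setNames(rep(1L, 3), rownames(m))
  res <- detect_ordered_pattern(m, assign, cats)
  expect_equal(res[["1"]]$excluded_categories, "C")
  expect_false("C" %in% rownames(res[["1"]]$pairwise))
})
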