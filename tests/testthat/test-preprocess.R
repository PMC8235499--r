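test_that("multiplicative background correction is log2(fg) - log2(bg)", {
  expect_equal(background_correct_mbc(matrix(1024), matrix(4))[1, 1], 8)
  expect_equal(background_correct_mbc(matrix(7), matrix(7))[1, 1], 0)
  set.seed(1)
  fg <- matrix(runif(20, 1, 100), 5, 4)
  bg <- matrix(runif(20, 1, 10), 5, 4)
  got <- background_correct_mbc(fg, bg)
  want <- matrix(NA_real_, 5, 4)
  for (i in 1:5) for (j in 1:4) want[i, j] <- log2(fg[i, j] / bg[i, j])
  expect_equal(unname(got), want, ignore_attr = TRUE)
})

test_that("non-positive channels become NaN; missing background flagged", {
  got <- background_correct_mbc(matrix(c(-1, 8, 0, 16), 2, 2),
                                matrix(c(2, 2, 2, -3), 2, 2))
  expect_equal(is.na(got), matrix(c(TRUE, FALSE, TRUE, TRUE), 2, 2))
  expect_false(attr(got, "assumed_corrected"))
  nobg <- background_correct_mbc(matrix(c(8, -2), 1, 2))
  expect_true(attr(nobg, "assumed_corrected"))
  expect_equal(nobg[1, 1], 3)
  expect_true(is.na(nobg[1, 2]))
  expect_error(background_correct_mbc(matrix(1, 2, 2), matrix(1, 3, 2)),
               "shape")
})

test_that("masking replaces negatives only and counts them", {
  got <- mask_nonpositive(matrix(c(-1, 0, 2), 1))
  expect_equal(as.vector(got), c(NA, 0, 2))
  expect_equal(attr(got, "n_masked"), 1L)
  pos <- matrix(runif(12), 3, 4)
  expect_equal(unname(mask_nonpositive(pos)), pos, ignore_attr = TRUE)
  k <- matrix(c(-1, -2, -3, 1, NA, 2), 2, 3)
  expect_equal(attr(mask_nonpositive(k), "n_masked"), 3L)
})

test_that("quantile normalization maps columns to the mean quantile profile", {
  m <- cbind(c(1, 2, 3), c(4, 5, 6))
  got <- normalize_expression(m, "quantile")
  expect_equal(unname(got), cbind(c(2.5, 3.5, 4.5), c(2.5, 3.5, 4.5)))
  # identical columns are a fixed point for every method
  same <- matrix(rep(stats::rnorm(30, 8, 2), 3), 30, 3)
  for (meth in c("quantile", "loess", "rank_invariant"))
    expect_equal(unname(normalize_expression(same, meth)), unname(same),
                 tolerance = 1e-6)
})

test_that("quantile agrees with the sort/average/unsort oracle", {
  set.seed(42)
  for (rep in 1:100) {
    m <- rand_mat(sample(4:9, 1), sample(3:5, 1))
    expect_equal(unname(normalize_expression(m, "quantile")),
                 unname(oracle_quantile(m)), tolerance = 1e-12)
  }
})

test_that("post-quantile complete columns share their sorted values", {
  set.seed(7)
  m <- rand_mat(50, 6)
  q <- normalize_expression(m, "quantile")
  s1 <- sort(q[, 1])
  for (j in 2:6) expect_equal(sort(q[, j]), s1, ignore_attr = TRUE)
})

test_that("quantile is equivariant under column permutation", {
  set.seed(8)
  m <- rand_mat(30, 5)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(normalize_expression(m, "quantile")[, perm],
               normalize_expression(m[, perm], "quantile"))
})

test_that("loess and rank-invariant remove a planted column offset", {
  set.seed(9)
  base <- stats::rnorm(200, 8, 1.5)
  m <- cbind(a = base + stats::rnorm(200, 0, 0.05),
             b = base + 2 + stats::rnorm(200, 0, 0.05),
             c = base + stats::rnorm(200, 0, 0.05))
  for (meth in c("loess", "rank_invariant")) {
    n <- normalize_expression(m, meth)
    offset_before <- abs(median(m[, "b"]) - median(m[, "a"]))
    offset_after <- abs(median(n[, "b"]) - median(n[, "a"]))
    expect_lt(offset_after, offset_before / 4)
  }
})

test_that("missing cells stay missing and thin columns are left alone", {
  set.seed(10)
  m <- rand_mat(20, 4, na_frac = 0.2)
  for (meth in c("quantile", "loess", "rank_invariant"))
    expect_equal(is.na(suppressWarnings(normalize_expression(m, meth))),
                 is.na(m))
  thin <- cbind(a = c(1, 2, 3, 4), b = c(5, NA, NA, NA))
  expect_warning(out <- normalize_expression(thin, "quantile"), "unchanged")
  expect_equal(out[, "b"], thin[, "b"])
  expect_error(normalize_expression(m, "zscore"))
})

test_that("the normalization comparison ranks quantile over raw batches", {
  set.seed(11)
  base <- matrix(stats::rnorm(100 * 6, 8, 1.5), 100, 6)
  batched <- base + rep(c(0, 0, 3, 3, -2, -2), each = 100)
  rep1 <- compare_normalizations(batched)
  expect_lt(rep1$mean_ks[rep1$method == "quantile"],
            rep1$mean_ks[rep1$method == "none"])
  expect_equal(rep1$rank[rep1$method == "quantile"], 1L)
  # post-quantile complete matrix: all-column KS distance is 0
  q <- normalize_expression(batched, "quantile")
  rep2 <- compare_normalizations(q)
  expect_equal(rep2$mean_ks[rep2$method == "none"], 0, tolerance = 1e-12)
  # deterministic given its input
  expect_identical(compare_normalizations(batched),
                   compare_normalizations(batched))
})

test_that("global-mean rescaling fixes the mean at one", {
  expect_equal(unname(global_mean_rescale(matrix(c(3, 3, 3, 3), 2))),
               matrix(1, 2, 2), ignore_attr = TRUE)
  expect_equal(as.vector(global_mean_rescale(matrix(c(1, 3), 1))),
               c(0.5, 1.5))
  set.seed(12)
  m <- rand_mat(30, 5, na_frac = 0.1) + 2
  r <- global_mean_rescale(m)
  expect_equal(mean(r, na.rm = TRUE), 1, tolerance = 1e-9)
  # idempotent, and identical to the log2-then-exponentiate form
  expect_equal(unname(global_mean_rescale(r)), unname(r),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(unname(r), unname(2 ^ (log2(m / mean(m, na.rm = TRUE)))),
               ignore_attr = TRUE)
  expect_error(global_mean_rescale(matrix(c(-5, 1), 1)), "positive")
})

test_that("replicate averaging takes NaN-ignoring within-symbol means", {
  m <- rbind(c(2, 4), c(4, NA))
  got <- average_replicates(m, c("M1", "M1"))
  expect_equal(unname(got["M1", ]), c(3, 4))
  # no duplicates: identity
  m2 <- rand_mat(5, 3)
  expect_equal(unname(average_replicates(m2, rownames(m2))), unname(m2))
  # random replicate groups against the scalar oracle
  set.seed(13)
  for (rep in 1:20) {
    m3 <- rand_mat(12, 4, na_frac = 0.3)
    groups <- sample(paste0("G", 1:5), 12, replace = TRUE)
    got3 <- average_replicates(m3, groups)
    want <- t(oracle_group_means(t(m3), groups))
    expect_equal(got3[rownames(want), ], want[, colnames(got3)])
  }
})

test_that("the preprocessing chain runs in the fixed stage order", {
  sim <- generate_multiseries(synthetic_config(
    seed = 21, n_tumor = 8, n_control = 6, features_per_series = 30,
    shared_features = 20, background_fraction = 0.2))
  hm <- assemble_hypermatrix(sim$series)
  pre <- preprocess_hypermatrix(hm)
  expect_identical(pre$stage, c("raw", "mbc", "masked", "normalized",
                                "rescaled", "averaged"))
  expect_true(validate_stages(pre))
  expect_equal(mean(pre$values, na.rm = TRUE), 1, tolerance = 1e-9)
  expect_false(anyDuplicated(rownames(pre$values)) > 0)
  # re-running on an already processed object is refused
  expect_error(preprocess_hypermatrix(pre), "raw")
  broken <- pre
  broken$stage <- c("raw", "normalized", "mbc")
  expect_error(validate_stages(broken), "order")
})
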