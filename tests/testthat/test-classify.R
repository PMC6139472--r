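make_null_features <- function(n, p, seed, mean = 0, sd = 1) {
  withr::with_seed(seed, matrix(rnorm(n * p, mean, sd), n, p))
}
balanced_labels <- function(n) factor(rep(c("CTRL", "PP"), each = n / 2))

test_that("a group-separated edge is ranked first across seeds", {
  for (seed in 1:5) {
    x <- make_null_features(24, 20, seed)
    labels <- balanced_labels(24)
    x[labels == "PP", 7] <- x[labels == "PP", 7] + 3
    expect_equal(rank_features(x, labels)$order[1], 7)
  }
})

test_that("ranking matches stats::t.test and breaks ties by edge index", {
  x <- make_null_features(16, 6, seed = 2)
  labels <- balanced_labels(16)
  rk <- rank_features(x, labels)
  for (j in 1:6)
    expect_equal(rk$statistic[j],
                 unname(t.test(x[labels == "CTRL", j],
                               x[labels == "PP", j])$statistic))
  xt <- cbind(x[, 1], x[, 1], x[, 3])    # columns 1 and 2 identical
  rkt <- rank_features(xt, labels)
  expect_lt(which(rkt$order == 1), which(rkt$order == 2))
})

test_that("zero-variance separated edges go to the top and are flagged", {
  x <- make_null_features(12, 5, seed = 3)
  labels <- balanced_labels(12)
  x[, 4] <- ifelse(labels == "CTRL", 1, 2)   # no within-group variance
  rk <- rank_features(x, labels)
  expect_equal(rk$order[1], 4)
  expect_equal(rk$degenerate, 4L)
  # no variance and no difference -> statistic 0, not NaN
  x[, 4] <- 1
  expect_equal(rank_features(x, labels)$statistic[4], 0)
})

test_that("the ranking statistic is centered at zero under label shuffles", {
  x <- make_null_features(20, 8, seed = 4)
  labels <- balanced_labels(20)
  stats <- withr::with_seed(9, replicate(200, {
    rank_features(x, labels[sample.int(20)])$statistic
  }))
  expect_lt(max(abs(rowMeans(stats))), 0.35)  # ~3 SE of a t at these sizes
})

test_that("LOOCV is exact on separated clusters and guards its inputs", {
  x <- make_null_features(16, 4, seed = 5)
  labels <- balanced_labels(16)
  x[, 2] <- ifelse(labels == "CTRL", -3, 3) + x[, 2] * 0.1
  rk <- rank_features(x, labels)
  expect_equal(rk$order[1], 2)
  expect_equal(loocv_accuracy(x, labels, rk, 1), 1)
  expect_equal(loocv_accuracy(x, labels, rk, 4), 1)
  expect_error(loocv_accuracy(x, labels, rk, 0), "between")
  expect_error(loocv_accuracy(x, labels, rk, 5), "between")
  expect_error(loocv_accuracy(x[1:3, ], labels[c(1, 2, 9)], rk, 1),
               "at least 2")
})

test_that("a subject duplicated into both classes caps accuracy at one half", {
  base <- make_null_features(6, 4, seed = 6)
  x <- rbind(base, base)                  # each row appears in both classes
  labels <- factor(rep(c("CTRL", "PP"), each = 6))
  rk <- rank_features(x, labels)
  for (k in c(1, 4))
    expect_lte(loocv_accuracy(x, labels, rk, k), 0.5)
})

test_that("null LOOCV accuracy sits at the majority-class proportion", {
  x <- make_null_features(200, 10, seed = 7)
  labels <- balanced_labels(200)
  acc <- loocv_accuracy(x, labels, rank_features(x, labels), 5)
  se <- sqrt(0.5 * 0.5 / 200)
  expect_lt(abs(acc - 0.5), 3 * se)
})

test_that("the incremental curve has one value per feature count", {
  x <- make_null_features(12, 6, seed = 8)   # 4-node cohort: 6 edges
  labels <- balanced_labels(12)
  rk <- rank_features(x, labels)
  acc <- incremental_curve(x, labels, ranking = rk)
  expect_length(acc, 6)
  expect_true(all(acc >= 0 & acc <= 1))
  # consistency with the non-incremental all-feature analysis
  expect_equal(unname(acc[6]), loocv_accuracy(x, labels, rk, 6))
  # invariance to subject ordering
  perm <- withr::with_seed(1, sample.int(12))
  acc_p <- incremental_curve(x[perm, ], labels[perm],
                             ranking = rank_features(x[perm, ], labels[perm]))
  expect_equal(unname(acc_p), unname(acc))
})

test_that("duplicating a separating feature preserves separability", {
  x <- make_null_features(16, 3, seed = 9)
  labels <- balanced_labels(16)
  x[, 1] <- ifelse(labels == "CTRL", -2, 2)
  rk <- rank_features(x, labels)
  expect_equal(loocv_accuracy(x, labels, rk, 3), 1)
  xdup <- cbind(x, x[, 1])
  expect_equal(loocv_accuracy(xdup, labels, rank_features(xdup, labels), 4), 1)
})

test_that("permutation nulls are seeded, reproducible, and dispersed", {
  x <- make_null_features(12, 5, seed = 10)
  labels <- balanced_labels(12)
  p1 <- permutation_null(x, labels, n_perm = 10, seed = 77)
  p2 <- permutation_null(x, labels, n_perm = 10, seed = 77)
  expect_identical(p1, p2)
  p3 <- permutation_null(x, labels, n_perm = 10, seed = 78)
  expect_false(identical(p1$null_mean, p3$null_mean))
  p <- permutation_null(x, labels, n_perm = 25, seed = 5)
  expect_true(all(p$null_sd > 0))
  expect_length(p$null_peaks, 25)
})

test_that("peak detection takes the smallest k attaining the maximum", {
  expect_equal(find_peak(c(0.5, 0.8, 0.8, 0.6)),
               list(peak_k = 2L, peak_accuracy = 0.8))
  expect_equal(find_peak(rep(0.4, 7)), list(peak_k = 1L, peak_accuracy = 0.4))
})

test_that("edge reports carry group means and direction flags", {
  x <- make_null_features(20, 6, seed = 11, mean = 0.3, sd = 0.05)
  labels <- balanced_labels(20)
  x[labels == "PP", 2] <- x[labels == "PP", 2] + 0.4   # PP higher
  x[labels == "CTRL", 5] <- x[labels == "CTRL", 5] + 0.4  # CTRL higher
  rk <- rank_features(x, labels)
  rep <- edge_report(x, labels, rk, 4,
                     edge_names = paste0("e", 1:6))
  expect_equal(nrow(rep), 4)
  expect_equal(rep$direction[rep$edge == "e2"], "PP>CTRL")
  expect_equal(rep$direction[rep$edge == "e5"], "CTRL>PP")
  expect_equal(rep$mean_r_CTRL[rep$edge == "e2"],
               mean(x[labels == "CTRL", 2]))
  # exact ties are flagged
  xt <- x; xt[, 1] <- rep(c(1, 2), 10)
  rept <- edge_report(xt, labels, seq_len(6), 1)
  expect_equal(rept$direction, "tie")
})

test_that("classify_cohort ties the pieces together consistently", {
  x <- make_null_features(16, 6, seed = 12)
  labels <- balanced_labels(16)
  x[, 3] <- ifelse(labels == "CTRL", -2, 2)
  res <- classify_cohort(x, labels, n_perm = 15, seed = 3)
  expect_s3_class(res, "fc_curve")
  expect_equal(res$peak_accuracy, max(res$accuracy))
  expect_equal(unname(res$accuracy[res$peak_k]), res$peak_accuracy)
  expect_equal(nrow(res$report), res$peak_k)
  expect_equal(res$chance, 0.5)
  expect_length(res$null_mean, 6)
  # nested per-fold ranking is available
  acc_nested <- incremental_curve(x, labels, nested = TRUE)
  expect_length(acc_nested, 6)
  expect_equal(unname(acc_nested[6]),
               loocv_accuracy(x, labels, rank_features(x, labels), 6))
})

test_that("null cohorts rarely beat their own permutation null at the peak", {
  n_seeds <- 50
  exceed <- vapply(seq_len(n_seeds), function(seed) {
    x <- make_null_features(8, 6, seed = 200 + seed)
    labels <- balanced_labels(8)
    res <- classify_cohort(x, labels, n_perm = 30, seed = 300 + seed)
    res$peak_accuracy > quantile(res$null_peaks, 0.95)
  }, logical(1))
  expect_lte(mean(exceed), 0.16)
})
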