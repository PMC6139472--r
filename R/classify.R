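# Connectivity-feature MVPA: feature ranking, incremental-feature linear SVM
# under leave-one-out cross-validation, label-permutation null, peak
# detection, and Table-style edge reports.

.check_labels <- function(labels, n) {
  labels <- as.factor(labels)
  if (length(labels) != n) stop("labels length must match the subject count")
  if (nlevels(labels) != 2) stop("exactly two classes are required")
  if (any(table(labels) < 2))
    stop("each class needs at least 2 subjects (got ",
         paste(table(labels), collapse = " and "), ")")
  labels
}

# Vectorized Welch two-sample t statistic per column (group a minus group b).
.welch_t <- function(x, ga, gb) {
  na <- sum(ga); nb <- sum(gb)
  ma <- colMeans(x[ga, , drop = FALSE])
  mb <- colMeans(x[gb, , drop = FALSE])
  va <- apply(x[ga, , drop = FALSE], 2, var)
  vb <- apply(x[gb, , drop = FALSE], 2, var)
  se2 <- va / na + vb / nb
  t <- (ma - mb) / sqrt(se2)
  t[se2 == 0 & ma == mb] <- 0        # no variance, no difference
  t                                   # se2 == 0, ma != mb -> +-Inf
}

#' Rank connectivity features by group discriminability
#'
#' Default method orders edges by descending absolute two-sample (Welch) t
#' statistic between the groups, ties broken by ascending edge index. Edges
#' with zero within-group variance and unequal means get infinite |t| and are
#' ranked first (flagged in the result). Method `"svm_weight"` ranks by
#' absolute weight of a linear SVM trained on all features.
#'
#' @param x subjects x features matrix.
#' @param labels two-level group factor.
#' @param method `"tstat"` (default) or `"svm_weight"`.
#' @param cost SVM cost (for `"svm_weight"`).
#' @return object of class `fc_ranking`: list with `order` (permutation of
#'   feature indices, best first), `statistic` (per feature, in original
#'   order), `method`, `degenerate` (indices flagged for zero variance).
#' @export
rank_features <- function(x, labels, method = c("tstat", "svm_weight"),
                          cost = 1) {
  method <- match.arg(method)
  labels <- .check_labels(labels, nrow(x))
  ga <- labels == levels(labels)[1]
  stat <- switch(method,
    tstat = .welch_t(x, ga, !ga),
    svm_weight = {
      fit <- e1071::svm(x, labels, kernel = "linear", cost = cost,
                        scale = FALSE)
      drop(crossprod(fit$coefs, fit$SV))
    })
  ord <- order(-abs(stat), seq_along(stat))
  structure(list(order = ord, statistic = stat, method = method,
                 degenerate = which(is.infinite(stat))),
            class = "fc_ranking")
}

#' Leave-one-out SVM accuracy with the top-k features
#'
#' For each subject, a linear SVM (cost `cost`, no kernel, unscaled features
#' by default) is trained on all other subjects using the `k` best-ranked
#' features and predicts the held-out subject.
#'
#' @param x subjects x features matrix.
#' @param labels two-level group factor.
#' @param ranking an `fc_ranking`, or an integer feature order.
#' @param k number of top features to use (1..ncol(x)).
#' @param cost SVM cost parameter (default 1).
#' @param standardize if `TRUE`, z-score features within each training fold
#'   (default `FALSE`: raw r values, see the methods vignette).
#' @return fraction of correctly classified subjects.
#' @export
loocv_accuracy <- function(x, labels, ranking, k, cost = 1,
                           standardize = FALSE) {
  ord <- if (inherits(ranking, "fc_ranking")) ranking$order else as.integer(ranking)
  if (k < 1 || k > ncol(x)) stop("k must be between 1 and ", ncol(x))
  labels <- .check_labels(labels, nrow(x))
  feats <- ord[seq_len(k)]
  correct <- vapply(seq_len(nrow(x)), function(i) {
    .svm_fold(x[, feats, drop = FALSE], labels, i, cost, standardize)
  }, logical(1))
  mean(correct)
}

# Train on all but fold i, predict subject i; returns TRUE when correct.
.svm_fold <- function(xk, labels, i, cost, standardize) {
  xtr <- xk[-i, , drop = FALSE]
  xte <- xk[i, , drop = FALSE]
  if (standardize) {
    mu <- colMeans(xtr)
    sdv <- apply(xtr, 2, sd); sdv[sdv == 0] <- 1
    xtr <- sweep(sweep(xtr, 2, mu), 2, sdv, "/")
    xte <- sweep(sweep(xte, 2, mu), 2, sdv, "/")
  }
  fit <- e1071::svm(xtr, labels[-i], kernel = "linear", cost = cost,
                    scale = FALSE)
  predict(fit, xte) == labels[i]
}

#' Incremental-feature LOOCV accuracy curve
#'
#' Repeats the LOOCV classification while growing the number of included
#' features from 1 to `ncol(x)` along the ranking. With `nested = TRUE` the
#' ranking is recomputed inside each training fold (removing the selection
#' bias of a whole-cohort ranking, at the cost of a fold-dependent feature
#' order).
#'
#' @inheritParams loocv_accuracy
#' @param ranking an `fc_ranking` (ignored when `nested = TRUE`).
#' @param method ranking method for nested mode.
#' @param ks feature counts to evaluate (default all).
#' @param nested recompute the ranking within each LOOCV fold.
#' @return numeric vector `accuracy[k]` over `ks`.
#' @export
incremental_curve <- function(x, labels, ranking = NULL,
                              method = "tstat", ks = seq_len(ncol(x)),
                              cost = 1, standardize = FALSE,
                              nested = FALSE) {
  labels <- .check_labels(labels, nrow(x))
  if (!nested && is.null(ranking)) ranking <- rank_features(x, labels, method)
  n <- nrow(x)
  correct <- matrix(NA, n, length(ks))
  for (i in seq_len(n)) {
    ord <- if (nested)
      rank_features(x[-i, , drop = FALSE], labels[-i], method)$order
    else if (inherits(ranking, "fc_ranking")) ranking$order else as.integer(ranking)
    for (kk in seq_along(ks)) {
      feats <- ord[seq_len(ks[kk])]
      correct[i, kk] <- .svm_fold(x[, feats, drop = FALSE], labels, i,
                                  cost, standardize)
    }
  }
  acc <- colMeans(correct)
  names(acc) <- ks
  acc
}

#' Permutation null of the incremental accuracy curve
#'
#' Group labels are shuffled (class counts preserved) `n_perm` times; for
#' each permutation the feature ranking is recomputed on the shuffled labels
#' and the incremental curve re-evaluated. Returns the per-k mean and SD of
#' the null curves, plus each permutation's peak accuracy.
#'
#' @inheritParams incremental_curve
#' @param n_perm number of permutations (>= 1).
#' @param seed RNG seed for the shuffles.
#' @return list with `null_mean`, `null_sd` (per k), `null_peaks` (length
#'   `n_perm`), `n_perm`, `seed`.
#' @export
permutation_null <- function(x, labels, n_perm, seed = 1L,
                             method = "tstat", ks = seq_len(ncol(x)),
                             cost = 1, standardize = FALSE,
                             nested = FALSE) {
  stopifnot(n_perm >= 1)
  labels <- .check_labels(labels, nrow(x))
  curves <- with_seed_or_not(seed, {
    vapply(seq_len(n_perm), function(p) {
      lp <- labels[sample.int(length(labels))]
      incremental_curve(x, lp, method = method, ks = ks, cost = cost,
                        standardize = standardize, nested = nested)
    }, numeric(length(ks)))
  })
  curves <- matrix(curves, nrow = length(ks))
  list(null_mean = rowMeans(curves),
       null_sd = apply(curves, 1, sd),
       null_peaks = apply(curves, 2, max),
       n_perm = n_perm, seed = seed)
}

#' Locate the peak of an accuracy curve
#'
#' @param curve numeric accuracy vector (index = number of features), or an
#'   `fc_curve` object.
#' @return list with `peak_k` (smallest k attaining the maximum) and
#'   `peak_accuracy`.
#' @export
find_peak <- function(curve) {
  acc <- if (inherits(curve, "fc_curve")) curve$accuracy else as.numeric(curve)
  stopifnot(length(acc) >= 1)
  k <- which.max(acc)           # which.max returns the first maximum
  list(peak_k = unname(k), peak_accuracy = unname(acc[k]))
}

#' Group-mean connectivity report for the included edges
#'
#' For each of the top `peak_k` ranked edges, reports the plain within-group
#' averages of the subject r values and a direction flag (which group has the
#' larger mean, or `"tie"`).
#'
#' @param x subjects x features matrix of r values.
#' @param labels two-level group factor.
#' @param ranking an `fc_ranking` or integer order.
#' @param peak_k number of edges to report.
#' @param edge_names optional edge labels (default: column names of `x`).
#' @return data frame with columns `rank`, `edge`, `mean_r_<group1>`,
#'   `mean_r_<group2>`, `direction`.
#' @export
edge_report <- function(x, labels, ranking, peak_k, edge_names = colnames(x)) {
  ord <- if (inherits(ranking, "fc_ranking")) ranking$order else as.integer(ranking)
  stopifnot(peak_k >= 1, peak_k <= ncol(x))
  labels <- .check_labels(labels, nrow(x))
  lv <- levels(labels)
  if (is.null(edge_names)) edge_names <- paste0("edge", seq_len(ncol(x)))
  feats <- ord[seq_len(peak_k)]
  m1 <- colMeans(x[labels == lv[1], feats, drop = FALSE])
  m2 <- colMeans(x[labels == lv[2], feats, drop = FALSE])
  direction <- ifelse(m1 > m2, paste0(lv[1], ">", lv[2]),
                      ifelse(m2 > m1, paste0(lv[2], ">", lv[1]), "tie"))
  out <- data.frame(rank = seq_len(peak_k), edge = edge_names[feats],
                    m1 = unname(m1), m2 = unname(m2),
                    direction = direction, stringsAsFactors = FALSE)
  names(out)[3:4] <- paste0("mean_r_", lv)
  rownames(out) <- NULL
  out
}

#' Full connectivity-MVPA classification of a cohort
#'
#' Ranks features, evaluates the incremental LOOCV curve, optionally computes
#' the permutation null, finds the peak, and assembles the edge report.
#'
#' @inheritParams incremental_curve
#' @param n_perm permutations for the null (0 skips it).
#' @param seed RNG seed for the permutations.
#' @param edge_names optional edge labels.
#' @return object of class `fc_curve`: list with `accuracy`, `null_mean`,
#'   `null_sd`, `null_peaks`, `peak_k`, `peak_accuracy`, `ranking`, `report`,
#'   `chance` (majority-class proportion), `labels`, `n_perm`, `seed`.
#' @export
classify_cohort <- function(x, labels, method = "tstat", n_perm = 0,
                            seed = 1L, cost = 1, standardize = FALSE,
                            nested = FALSE, edge_names = colnames(x)) {
  labels <- .check_labels(labels, nrow(x))
  ranking <- rank_features(x, labels, method, cost = cost)
  acc <- incremental_curve(x, labels, ranking = ranking, method = method,
                           cost = cost, standardize = standardize,
                           nested = nested)
  null <- if (n_perm > 0)
    permutation_null(x, labels, n_perm = n_perm, seed = seed, method = method,
                     cost = cost, standardize = standardize, nested = nested)
  peak <- find_peak(acc)
  report <- edge_report(x, labels, ranking, peak$peak_k,
                        edge_names = edge_names)
  structure(list(
    accuracy = acc,
    null_mean = null$null_mean, null_sd = null$null_sd,
    null_peaks = null$null_peaks,
    peak_k = peak$peak_k, peak_accuracy = peak$peak_accuracy,
    ranking = ranking, report = report,
    chance = max(table(labels)) / length(labels),
    labels = labels, n_perm = if (is.null(null)) 0L else null$n_perm,
    seed = seed, method = method, cost = cost), class = "fc_curve")
}

#' @export
print.fc_curve <- function(x, ...) {
  cat(sprintf(
    "Incremental LOOCV classification over %d features\n  peak accuracy %.3f at k = %d (chance: 0.5; majority class: %.3f)\n",
    length(x$accuracy), x$peak_accuracy, x$peak_k, x$chance))
  if (x$n_perm > 0)
    cat(sprintf("  permutation null at peak k: %.3f +/- %.3f (%d permutations)\n",
                x$null_mean[x$peak_k], x$null_sd[x$peak_k], x$n_perm))
  invisible(x)
}

#' Plot an incremental classification curve
#'
#' Accuracy versus number of included features (thick line), with the
#' permutation-null mean as a dashed line and +/- 1 SD error bars, plus the
#' chance levels.
#'
#' @param x an `fc_curve` object.
#' @param ... passed to [plot()].
#' @export
plot.fc_curve <- function(x, ...) {
  ks <- seq_along(x$accuracy)
  plot(ks, x$accuracy, type = "l", lwd = 3, ylim = c(0, 1),
       xlab = "Number of features included", ylab = "LOOCV accuracy", ...)
  if (!is.null(x$null_mean)) {
    graphics::lines(ks, x$null_mean, lty = 2)
    nz <- which(x$null_sd > 0)    # zero-length arrows are undrawable
    if (length(nz))
      graphics::arrows(ks[nz], x$null_mean[nz] - x$null_sd[nz], ks[nz],
                       x$null_mean[nz] + x$null_sd[nz],
                       angle = 90, code = 3, length = 0.02, col = "grey50")
  }
  graphics::abline(h = c(0.5, x$chance), col = c("grey70", "grey40"),
                   lty = 3)
  graphics::points(x$peak_k, x$peak_accuracy, pch = 19)
  invisible(x)
}
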