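# Task-dependent (PPI-style) node time-series and connectivity features:
# deconvolve voxel BOLD to neural level, detrend, multiply by the R-vs-K
# psychological stick contrast, reconvolve with the HRF, detrend, average
# voxels per node, correlate node pairs.

#' Build the R-hit vs K-hit psychological stick factor
#'
#' A vector over volumes with +1 at R-hit onset bins, -1 at K-hit onset bins,
#' and 0 elsewhere. Onsets are binned to the nearest TR.
#'
#' @param events event table with `onset` (s) and `trial_type` columns.
#' @param n_volumes number of volumes in the run.
#' @param tr repetition time in seconds.
#' @return integer vector of length `n_volumes` with values in {-1, 0, 1}.
#' @export
make_psych_factor <- function(events, n_volumes, tr) {
  psych <- integer(n_volumes)
  keep <- which(events$trial_type %in% c("R-hit", "K-hit"))
  if (length(keep) == 0) return(psych)
  bins <- round(events$onset[keep] / tr) + 1
  if (any(bins < 1 | bins > n_volumes))
    stop("event onsets outside the run (trials ",
         paste(keep[bins < 1 | bins > n_volumes], collapse = ", "), ")")
  sign <- ifelse(events$trial_type[keep] == "R-hit", 1L, -1L)
  clash <- tapply(sign, bins, function(s) length(unique(s)) > 1)
  if (any(clash)) {
    bad_bins <- as.integer(names(clash)[clash])
    bad_trials <- keep[bins %in% bad_bins]
    stop("ambiguous psychological stick: R-hit and K-hit onsets fall in the ",
         "same TR bin (trials ", paste(bad_trials, collapse = ", "), ")")
  }
  psych[bins] <- sign
  psych
}

#' Task-dependent (PPI) time-series of one node
#'
#' Per voxel of the node block: deconvolve the BOLD series to neural level,
#' detrend, multiply elementwise by the psychological factor, reconvolve with
#' the HRF (causal, truncated to run length), and detrend again; the 27 voxel
#' series are then averaged into one representative node series.
#'
#' @param block 27 x n_volumes voxel matrix from [extract_block()].
#' @param psych stick factor from [make_psych_factor()].
#' @param hrf an [canonical_hrf()] kernel.
#' @param lambda deconvolution penalty (`NULL` = per-voxel GCV).
#' @param deconv_op optional precomputed operator (internal reuse).
#' @return numeric vector of length n_volumes.
#' @export
ppi_node_series <- function(block, psych, hrf, lambda = NULL,
                            deconv_op = NULL) {
  stopifnot(ncol(block) == length(psych))
  kernel <- hrf_values(hrf)
  Y <- t(block)                                  # time x voxels
  if (is.null(deconv_op)) deconv_op <- deconv_operator(nrow(Y), kernel)
  neural <- .deconv_solve(deconv_op, Y, lambda = lambda)$coef
  neural <- .detrend_mat(neural)
  inter <- neural * psych                        # recycles over columns
  reconv <- conv_matrix(nrow(Y), kernel) %*% inter
  reconv <- .detrend_mat(reconv)
  rowMeans(reconv)
}

#' Compute all task-dependent node time-series of one subject
#'
#' Runs [extract_block()] and the PPI chain for every node, sharing one
#' deconvolution operator across all voxels.
#'
#' @param bold_run 4D BOLD array or `RNifti` image.
#' @param nodes named list of `fc_node` objects from [build_nodes()].
#' @param events event table for the run.
#' @param tr repetition time in seconds.
#' @param hrf HRF kernel (default: canonical at `tr`).
#' @param lambda deconvolution penalty (`NULL` = GCV).
#' @param subject_id optional identifier carried through to reports.
#' @return object of class `fc_node_signals`: list with `signals`
#'   (n_nodes x n_volumes matrix, rows detrended), `node_names`,
#'   `subject_id`, `tr`.
#' @export
node_signal_set <- function(bold_run, nodes, events, tr,
                            hrf = canonical_hrf(tr), lambda = NULL,
                            subject_id = NULL) {
  arr <- if (is.array(bold_run)) bold_run else as.array(bold_run)
  nv <- dim(arr)[4]
  psych <- make_psych_factor(events, nv, tr)
  op <- deconv_operator(nv, hrf_values(hrf))
  sig <- t(vapply(nodes, function(nd) {
    ppi_node_series(extract_block(arr, nd), psych, hrf, lambda = lambda,
                    deconv_op = op)
  }, numeric(nv)))
  rownames(sig) <- names(nodes)
  structure(list(signals = sig, node_names = names(nodes),
                 subject_id = subject_id, tr = tr),
            class = "fc_node_signals")
}

#' Lower-triangle edge index map
#'
#' Edges are enumerated row-major over the lower triangle: (2,1), (3,1),
#' (3,2), (4,1), ... so 16 nodes give 120 edges. Edge names join the two node
#' labels with `"~"`.
#'
#' @param node_names character vector of node labels.
#' @return data frame with columns `index`, `i`, `j` (i > j), `name`.
#' @export
edge_index_map <- function(node_names) {
  n <- length(node_names)
  ij <- do.call(rbind, lapply(seq_len(n)[-1], function(i)
    cbind(i = i, j = seq_len(i - 1))))
  data.frame(index = seq_len(nrow(ij)), i = ij[, "i"], j = ij[, "j"],
             name = paste(node_names[ij[, "i"]], node_names[ij[, "j"]],
                          sep = "~"),
             stringsAsFactors = FALSE)
}

#' Pairwise Pearson connectivity features
#'
#' Zero-lag Pearson correlation between every pair of node series, flattened
#' over the lower triangle (row-major, i > j) into the feature vector.
#'
#' @param signals an `fc_node_signals` object, or a bare n_nodes x n_volumes
#'   matrix.
#' @return object of class `fc_features`: list with `r` (feature vector,
#'   named by edge), `edges` (the [edge_index_map()]), `matrix` (full
#'   symmetric correlation matrix), `subject_id`.
#' @export
connectivity_features <- function(signals) {
  mat <- if (inherits(signals, "fc_node_signals")) signals$signals else signals
  subject_id <- if (inherits(signals, "fc_node_signals")) signals$subject_id
  stopifnot(is.matrix(mat), nrow(mat) >= 2)
  sds <- apply(mat, 1, sd)
  if (any(sds == 0 | !is.finite(sds))) {
    bad <- rownames(mat)[sds == 0 | !is.finite(sds)]
    if (is.null(bad)) bad <- which(sds == 0 | !is.finite(sds))
    stop("constant time-series (correlation undefined) for node(s): ",
         paste(bad, collapse = ", "))
  }
  R <- cor(t(mat))
  nm <- rownames(mat)
  if (is.null(nm)) nm <- paste0("node", seq_len(nrow(mat)))
  edges <- edge_index_map(nm)
  r <- R[cbind(edges$i, edges$j)]
  names(r) <- edges$name
  structure(list(r = r, edges = edges, matrix = R, subject_id = subject_id),
            class = "fc_features")
}

#' @export
print.fc_node_signals <- function(x, ...) {
  cat(sprintf("Task-dependent node signals: %d nodes x %d volumes (TR %g s)%s\n",
              nrow(x$signals), ncol(x$signals), x$tr,
              if (!is.null(x$subject_id)) paste0(" [", x$subject_id, "]") else ""))
  invisible(x)
}

#' @export
print.fc_features <- function(x, ...) {
  cat(sprintf("Connectivity features: %d edges over %d nodes%s\n",
              length(x$r), nrow(x$matrix),
              if (!is.null(x$subject_id)) paste0(" [", x$subject_id, "]") else ""))
  invisible(x)
}
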