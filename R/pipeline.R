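# End-to-end orchestration over directories: simulate -> connectivity ->
# classify. Each stage reads/writes plain files (NIfTI, TSV, CSV, JSON) so
# runs are restartable and auditable; a thin command-line wrapper lives at
# inst/cli/fcmvpa.

#' Simulate a cohort to disk
#'
#' Wraps [generate_cohort()] + [write_cohort()].
#'
#' @param config an [sim_cohort_config()] object.
#' @param dir output directory.
#' @return the cohort manifest, invisibly.
#' @export
fc_simulate <- function(config, dir) {
  cohort <- generate_cohort(config, render = TRUE)
  write_cohort(cohort, dir)
  message("wrote ", length(cohort$subjects), " subjects to ", dir)
  invisible(cohort$manifest)
}

# Subject ids present in a cohort directory.
.cohort_subjects <- function(cohort_dir) {
  pf <- file.path(cohort_dir, "participants.tsv")
  if (!file.exists(pf)) stop("no participants.tsv in ", cohort_dir)
  p <- read.delim(pf, stringsAsFactors = FALSE)
  if (nrow(p) == 0) stop("no subjects found in ", cohort_dir)
  p
}

#' Compute connectivity features for every subject of a cohort directory
#'
#' For each subject: build nodes on the run's grid, extract the voxel blocks,
#' run the PPI chain, and write the node-signal matrix
#' (`<id>_node_signals.csv`), the connectivity matrix
#' (`<id>_connectivity.csv`), and the feature vector (`<id>_features.csv`,
#' columns `edge`, `r`). Subjects whose feature file already exists are
#' skipped unless `force = TRUE`; per-subject failures are collected and
#' summarized rather than aborting the run.
#'
#' @param cohort_dir directory written by [fc_simulate()] (or any directory
#'   with `participants.tsv`, `nodes.csv`, `<id>_bold.nii.gz`,
#'   `<id>_events.tsv`).
#' @param out_dir output directory (default: `cohort_dir`).
#' @param node_table override the cohort's node table.
#' @param tr repetition time; default read from the NIfTI header is not
#'   assumed -- pass the protocol value (default 2).
#' @param lambda deconvolution penalty (`NULL` = GCV).
#' @param force recompute subjects whose outputs exist.
#' @return data frame summarizing per-subject status, invisibly.
#' @export
fc_connectivity <- function(cohort_dir, out_dir = cohort_dir,
                            node_table = NULL, tr = 2, lambda = NULL,
                            force = FALSE) {
  participants <- .cohort_subjects(cohort_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(node_table))
    node_table <- read_node_table(file.path(cohort_dir, "nodes.csv"))
  hrf <- canonical_hrf(tr)
  # archive the analysis settings actually used alongside the outputs
  jsonlite::write_json(list(
    package_version = as.character(utils::packageVersion("fcmvpa")),
    tr = tr, lambda = if (is.null(lambda)) "GCV" else lambda,
    hrf = hrf$params, n_nodes = nrow(node_table),
    voxel_order = "lexicographic (x, y, z), 0-based",
    psych_binning = "nearest TR"),
    file.path(out_dir, "connectivity_config.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  status <- character(nrow(participants))
  for (i in seq_len(nrow(participants))) {
    id <- participants$id[i]
    feat_file <- file.path(out_dir, paste0(id, "_features.csv"))
    if (file.exists(feat_file) && !force) {
      status[i] <- "skipped"
      next
    }
    res <- tryCatch({
      bold <- RNifti::readNifti(file.path(cohort_dir,
                                          paste0(id, "_bold.nii.gz")))
      ev_file <- file.path(cohort_dir, paste0(id, "_events.tsv"))
      if (!file.exists(ev_file)) stop("missing events file ", ev_file)
      events <- read.delim(ev_file, stringsAsFactors = FALSE)
      affine <- RNifti::xform(bold, useQuaternionFirst = FALSE)
      nodes <- build_nodes(node_table, affine, dim(bold)[1:3])
      sigs <- node_signal_set(bold, nodes, events, tr, hrf = hrf,
                              lambda = lambda, subject_id = id)
      feats <- connectivity_features(sigs)
      write.csv(data.frame(edge = names(feats$r), r = unname(feats$r)),
                feat_file, row.names = FALSE)
      write.csv(as.data.frame(feats$matrix),
                file.path(out_dir, paste0(id, "_connectivity.csv")),
                row.names = TRUE)
      write.csv(as.data.frame(sigs$signals),
                file.path(out_dir, paste0(id, "_node_signals.csv")),
                row.names = TRUE)
      "ok"
    }, error = function(e) paste("error:", conditionMessage(e)))
    status[i] <- res
  }
  failed <- grepl("^error", status)
  if (any(failed))
    warning(sum(failed), " subject(s) failed: ",
            paste(participants$id[failed], collapse = ", "))
  message(sprintf("connectivity: %d ok, %d skipped, %d failed",
                  sum(status == "ok"), sum(status == "skipped"),
                  sum(failed)))
  invisible(data.frame(id = participants$id, status = status))
}

#' Assemble the cohort feature matrix from per-subject feature files
#'
#' @param features_dir directory holding `<id>_features.csv` files.
#' @param participants data frame with `id` and `group` (default: read from
#'   `participants.tsv` in `features_dir`).
#' @return list with `x` (subjects x features matrix, edge names as column
#'   names), `labels` (factor), `ids`.
#' @export
cohort_feature_matrix <- function(features_dir, participants = NULL) {
  if (is.null(participants)) participants <- .cohort_subjects(features_dir)
  rows <- lapply(participants$id, function(id) {
    f <- file.path(features_dir, paste0(id, "_features.csv"))
    if (!file.exists(f)) stop("missing feature file for subject ", id)
    read.csv(f, stringsAsFactors = FALSE)
  })
  edges <- rows[[1]]$edge
  x <- t(vapply(rows, function(d) d$r, numeric(length(edges))))
  colnames(x) <- edges
  rownames(x) <- participants$id
  list(x = x, labels = factor(participants$group), ids = participants$id)
}

#' Classify a cohort from its feature files
#'
#' Wraps [classify_cohort()] over a feature directory and writes
#' `curve.csv` (k, accuracy, null_mean, null_sd), `results.json` (peak,
#' chance levels, settings), and `edge_report.csv` (Table-style group means,
#' 2-decimal display columns alongside full precision).
#'
#' @param features_dir directory from [fc_connectivity()].
#' @param out_dir output directory (default: `features_dir`).
#' @param method feature-ranking method.
#' @param n_perm permutations for the null (0 disables it, with a warning
#'   that the curve has no null columns).
#' @param seed permutation seed.
#' @param cost SVM cost.
#' @param standardize z-score features within training folds.
#' @param nested recompute rankings inside each LOOCV fold.
#' @param plot_file optional path for a curve plot (PDF/PNG by extension).
#' @return the `fc_curve` object, invisibly.
#' @export
fc_classify <- function(features_dir, out_dir = features_dir,
                        method = "tstat", n_perm = 2000, seed = 1L,
                        cost = 1, standardize = FALSE, nested = FALSE,
                        plot_file = NULL) {
  fm <- cohort_feature_matrix(features_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (n_perm == 0)
    warning("n_perm = 0: curve written without permutation-null columns")
  res <- classify_cohort(fm$x, fm$labels, method = method, n_perm = n_perm,
                         seed = seed, cost = cost,
                         standardize = standardize, nested = nested)
  curve <- data.frame(k = seq_along(res$accuracy), accuracy = res$accuracy)
  if (res$n_perm > 0) {
    curve$null_mean <- res$null_mean
    curve$null_sd <- res$null_sd
  }
  write.csv(curve, file.path(out_dir, "curve.csv"), row.names = FALSE)
  report <- res$report
  mcols <- grep("^mean_r_", names(report))
  for (cc in mcols) report[[paste0(names(report)[cc], "_2dp")]] <-
    sprintf("%.2f", report[[cc]])
  write.csv(report, file.path(out_dir, "edge_report.csv"), row.names = FALSE)
  jsonlite::write_json(list(
    peak_k = res$peak_k, peak_accuracy = res$peak_accuracy,
    chance_majority = res$chance, chance_balanced = 0.5,
    n_perm = res$n_perm, seed = seed, method = method, cost = cost,
    standardize = standardize, nested = nested,
    n_subjects = nrow(fm$x), n_features = ncol(fm$x),
    class_counts = as.list(table(fm$labels))),
    file.path(out_dir, "results.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  if (!is.null(plot_file)) {
    ext <- tolower(tools::file_ext(plot_file))
    if (ext == "png") grDevices::png(plot_file, 900, 600)
    else grDevices::pdf(plot_file, 7, 5)
    plot(res, main = "Incremental-feature LOOCV classification")
    grDevices::dev.off()
  }
  invisible(res)
}

#' Run one subject end-to-end in memory
#'
#' Convenience path from a rendered BOLD run + events to connectivity
#' features, used by tests and examples.
#'
#' @param bold 4D array or `RNifti` image.
#' @param events event table.
#' @param node_table node table data frame.
#' @param tr repetition time (s).
#' @param affine voxel-to-mm map (default: centered grid affine).
#' @param lambda deconvolution penalty (`NULL` = GCV).
#' @param subject_id optional id.
#' @return an `fc_features` object with the `fc_node_signals` attached as
#'   attribute `"signals"`.
#' @export
subject_features <- function(bold, events, node_table, tr,
                             affine = NULL, lambda = NULL,
                             subject_id = NULL) {
  arr <- if (is.array(bold)) bold else as.array(bold)
  if (is.null(affine)) {
    affine <- attr(bold, "affine")
    if (is.null(affine) && inherits(bold, "niftiImage"))
      affine <- RNifti::xform(bold, useQuaternionFirst = FALSE)
    if (is.null(affine)) affine <- make_affine(dim(arr)[1:3])
  }
  nodes <- build_nodes(node_table, affine, dim(arr)[1:3])
  sigs <- node_signal_set(arr, nodes, events, tr, lambda = lambda,
                          subject_id = subject_id)
  feats <- connectivity_features(sigs)
  attr(feats, "signals") <- sigs
  feats
}
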