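# Synthetic two-group cohorts of event-related BOLD runs with known
# condition-dependent inter-node coupling. The generator is the ground truth
# against which the PPI/classification chain is verified.

#' Configuration for a synthetic cohort
#'
#' Defines the study conditions the generator emulates: an event-related
#' Remember/Know test run (120 old + 60 new items, 4-s back-to-back trials,
#' 360 volumes at TR = 2 s) for a control (CTRL) and a postpartum-like (PP)
#' group, with condition-dependent inter-node coupling. On `effect_edges`,
#' the inter-node correlation of PP subjects rises to `base_rho + delta_rho`
#' during R-hit trial epochs; all other bins, edges, and the whole CTRL group
#' use `base_rho`. The R-hit-minus-K-hit coupling contrast therefore differs
#' between groups by `delta_rho` (see the methods vignette for why the
#' injection is one-sided).
#'
#' @param n_ctrl,n_pp subjects per group (defaults 27 and 25).
#' @param n_volumes volumes per run (default 360).
#' @param tr repetition time in seconds (default 2).
#' @param n_old_items,n_new_items old/new test items (defaults 120 and 60).
#' @param trial_duration trial length in seconds (default 4).
#' @param node_table node specification data frame (default
#'   [synthetic_node_table()]).
#' @param grid_shape,voxel_size rendering grid (default 64x64x32 at 3 mm).
#' @param base_rho population baseline inter-node correlation, in (-1, 1)
#'   (default 0.3).
#' @param subject_rho_sd between-subject standard deviation of the intrinsic
#'   edge-level coupling around `base_rho` (default 0.2; 0 disables
#'   heterogeneity). Implemented as a Wishart-style draw: each subject's
#'   baseline coupling matrix is the sample correlation of
#'   `m = ((1 - base_rho^2) / subject_rho_sd)^2` latent draws from the
#'   population coupling, which is positive definite by construction and
#'   jitters every edge independently with approximately this sd.
#' @param effect_edges `NULL`, or data frame with columns `i`, `j` (node
#'   indices, i > j) and `delta_rho` (R-hit coupling increment for the PP
#'   group; may be negative).
#' @param noise_sd voxel noise standard deviation (default 0.5; latent node
#'   signals have unit variance per time bin).
#' @param drift_amplitude peak-to-peak linear scanner drift added to every
#'   voxel (default 1).
#' @param signal_scale amplitude of the rendered node signal (default 1).
#' @param p_old response probabilities for old items (R-hit, K-hit, miss);
#'   default `c(0.45, 0.35, 0.20)`.
#' @param p_new response probabilities for new items (CR, FA); default
#'   `c(0.9, 0.1)`.
#' @param seed master seed; the entire cohort is a pure function of the
#'   config including this seed.
#' @return an object of class `fc_cohort_config`.
#' @export
sim_cohort_config <- function(n_ctrl = 27, n_pp = 25, n_volumes = 360,
                              tr = 2, n_old_items = 120, n_new_items = 60,
                              trial_duration = 4,
                              node_table = synthetic_node_table(),
                              grid_shape = c(64, 64, 32), voxel_size = 3,
                              base_rho = 0.3, subject_rho_sd = 0.2,
                              effect_edges = NULL,
                              noise_sd = 0.5, drift_amplitude = 1,
                              signal_scale = 1,
                              p_old = c(0.45, 0.35, 0.20),
                              p_new = c(0.9, 0.1), seed = 1L) {
  stopifnot(n_ctrl >= 1, n_pp >= 1, n_volumes >= 1, tr > 0,
            n_old_items >= 0, n_new_items >= 0, trial_duration > 0,
            noise_sd >= 0, signal_scale >= 0,
            length(p_old) == 3, length(p_new) == 2,
            abs(sum(p_old) - 1) < 1e-8, abs(sum(p_new) - 1) < 1e-8,
            abs(base_rho) < 1, subject_rho_sd >= 0)
  node_table <- validate_node_table(node_table)
  if ((n_old_items + n_new_items) * trial_duration > n_volumes * tr)
    stop("run too short: ", n_old_items + n_new_items, " trials of ",
         trial_duration, " s need ",
         (n_old_items + n_new_items) * trial_duration,
         " s but the run has ", n_volumes * tr, " s")
  if (!is.null(effect_edges)) {
    stopifnot(is.data.frame(effect_edges),
              all(c("i", "j", "delta_rho") %in% names(effect_edges)))
    if (any(effect_edges$i <= effect_edges$j))
      stop("effect_edges must use lower-triangle indexing (i > j)")
    if (any(effect_edges$i > nrow(node_table) | effect_edges$j < 1))
      stop("effect_edges indices outside the node table")
    if (any(abs(base_rho + effect_edges$delta_rho) >= 1))
      stop("|base_rho + delta_rho| must stay below 1 for every effect edge")
  }
  structure(list(
    n_ctrl = n_ctrl, n_pp = n_pp, n_volumes = n_volumes, tr = tr,
    n_old_items = n_old_items, n_new_items = n_new_items,
    trial_duration = trial_duration, node_table = node_table,
    grid_shape = grid_shape, voxel_size = voxel_size,
    base_rho = base_rho, subject_rho_sd = subject_rho_sd,
    effect_edges = effect_edges,
    noise_sd = noise_sd, drift_amplitude = drift_amplitude,
    signal_scale = signal_scale, p_old = p_old, p_new = p_new,
    seed = as.integer(seed)), class = "fc_cohort_config")
}

#' Generate an event table for one test run
#'
#' Old and new items are interleaved in random order and presented
#' back-to-back. Old items are labeled `R-hit`, `K-hit`, or `miss`; new items
#' `CR` or `FA`, with the config's response probabilities.
#'
#' @param config an [sim_cohort_config()] object.
#' @param seed RNG seed (default: the config's master seed).
#' @return data frame with columns `onset` (s), `duration` (s), `trial_type`,
#'   `item_type`; onsets strictly increasing.
#' @export
generate_events <- function(config, seed = config$seed) {
  n_trials <- config$n_old_items + config$n_new_items
  if (n_trials * config$trial_duration > config$n_volumes * config$tr)
    stop("run too short for ", n_trials, " trials of ",
         config$trial_duration, " s")
  if (n_trials == 0)
    return(data.frame(onset = numeric(0), duration = numeric(0),
                      trial_type = character(0), item_type = character(0),
                      stringsAsFactors = FALSE))
  with_seed_or_not(seed, {
    item <- sample(c(rep("old", config$n_old_items),
                     rep("new", config$n_new_items)))
    resp <- character(n_trials)
    old_i <- item == "old"
    resp[old_i] <- sample(c("R-hit", "K-hit", "miss"), sum(old_i),
                          replace = TRUE, prob = config$p_old)
    resp[!old_i] <- sample(c("CR", "FA"), sum(!old_i),
                           replace = TRUE, prob = config$p_new)
    data.frame(onset = (seq_len(n_trials) - 1) * config$trial_duration,
               duration = config$trial_duration,
               trial_type = resp, item_type = item,
               stringsAsFactors = FALSE)
  })
}

# Per-volume condition label: "R-hit"/"K-hit" inside the nearest-TR-binned
# epoch (onset to onset + duration) of those trials, "base" elsewhere.
condition_bins <- function(events, n_volumes, tr) {
  cond <- rep("base", n_volumes)
  keep <- events$trial_type %in% c("R-hit", "K-hit")
  for (r in which(keep)) {
    b0 <- round(events$onset[r] / tr)
    nb <- max(1, round(events$duration[r] / tr))
    bins <- (b0:(b0 + nb - 1)) + 1
    bins <- bins[bins >= 1 & bins <= n_volumes]
    cond[bins] <- events$trial_type[r]
  }
  cond
}

# Compound-symmetry correlation matrix with per-edge overrides.
.make_sigma <- function(n_nodes, base_rho, edges = NULL, deltas = NULL) {
  S <- matrix(base_rho, n_nodes, n_nodes)
  diag(S) <- 1
  if (!is.null(edges) && nrow(edges) > 0) {
    for (r in seq_len(nrow(edges))) {
      v <- base_rho + deltas[r]
      S[edges$i[r], edges$j[r]] <- v
      S[edges$j[r], edges$i[r]] <- v
    }
  }
  S
}

.chol_or_edges <- function(S, edges, what) {
  out <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(out)) {
    msg <- if (!is.null(edges) && nrow(edges) > 0)
      paste0(" offending effect edges: ",
             paste(sprintf("(%d,%d)", edges$i, edges$j), collapse = ", "))
    else ""
    stop("requested ", what, " correlation matrix is not positive definite;",
         msg)
  }
  out
}

#' Simulate latent node-level neural signals
#'
#' Per time bin, node signals are drawn from a zero-mean correlated Gaussian.
#' Off-effect edges carry `base_rho` in every bin; effect edges carry
#' `base_rho + delta_rho` during R-hit epochs of PP subjects and `base_rho`
#' otherwise, so the group difference in the R-vs-K coupling contrast equals
#' `delta_rho`.
#'
#' @param config an [sim_cohort_config()] object.
#' @param events event table from [generate_events()].
#' @param group_label `"CTRL"` or `"PP"`.
#' @param seed RNG seed.
#' @return n_nodes x n_volumes matrix of latent signals (unit variance per
#'   bin), with row names from the node table.
#' @export
simulate_node_neural <- function(config, events, group_label,
                                 seed = config$seed) {
  stopifnot(group_label %in% c("CTRL", "PP"))
  n_nodes <- nrow(config$node_table)
  nv <- config$n_volumes
  S_pop <- .make_sigma(n_nodes, config$base_rho)
  .chol_or_edges(S_pop, NULL, "population baseline")
  use_effect <- group_label == "PP" && !is.null(config$effect_edges) &&
    nrow(config$effect_edges) > 0
  if (use_effect) {
    # population-level feasibility: the requested R-epoch matrix must be PD
    S_pop_r <- .apply_deltas(S_pop, config$effect_edges)
    .chol_or_edges(S_pop_r, config$effect_edges, "R-hit epoch")
  }
  cond <- condition_bins(events, nv, config$tr)
  lat <- with_seed_or_not(seed, {
    S_subj <- .subject_coupling(S_pop, config$base_rho,
                                config$subject_rho_sd)
    # a pathological jitter draw can break PD once deltas are added; shrink
    # that subject's jitter toward the population coupling until it holds
    for (shrink in 0:5) {
      S_try <- S_pop + 0.5^shrink * (S_subj - S_pop)
      R_base <- tryCatch(chol(S_try), error = function(e) NULL)
      R_rhit <- if (!is.null(R_base) && use_effect)
        tryCatch(chol(.apply_deltas(S_try, config$effect_edges)),
                 error = function(e) NULL)
      else R_base
      if (!is.null(R_base) && !is.null(R_rhit)) break
    }
    if (is.null(R_base) || is.null(R_rhit))
      .chol_or_edges(.apply_deltas(S_pop, config$effect_edges),
                     config$effect_edges, "R-hit epoch")
    Z <- matrix(rnorm(nv * n_nodes), nv, n_nodes)
    L <- matrix(0, nv, n_nodes)
    rhit <- cond == "R-hit"
    if (any(rhit))  L[rhit, ]  <- Z[rhit, , drop = FALSE] %*% R_rhit
    if (any(!rhit)) L[!rhit, ] <- Z[!rhit, , drop = FALSE] %*% R_base
    L
  })
  lat <- t(lat)
  rownames(lat) <- config$node_table$name
  lat
}

# Add the R-epoch coupling increments to a baseline matrix, clamping the
# resulting correlations to +/-0.95.
.apply_deltas <- function(S, effect_edges) {
  for (r in seq_len(nrow(effect_edges))) {
    i <- effect_edges$i[r]; j <- effect_edges$j[r]
    v <- max(-0.95, min(0.95, S[i, j] + effect_edges$delta_rho[r]))
    S[i, j] <- v; S[j, i] <- v
  }
  S
}

# Subject-specific intrinsic coupling: the sample correlation matrix of m
# latent draws from the population coupling. Positive definite whenever
# m > n_nodes; per-edge jitter sd is approximately (1 - rho^2) / sqrt(m).
.subject_coupling <- function(S_pop, base_rho, subject_rho_sd) {
  if (subject_rho_sd <= 0) return(S_pop)
  n <- nrow(S_pop)
  m <- max(n + 2, ceiling(((1 - base_rho^2) / subject_rho_sd)^2))
  R <- chol(S_pop)
  draws <- matrix(rnorm(m * n), m, n) %*% R
  cor(draws)
}

#' Render a 4D BOLD run from latent node signals
#'
#' Each node's latent series is convolved with the canonical HRF, scaled by
#' `signal_scale`, and added to all 27 voxels of its cube. Every voxel
#' (background included) receives linear drift plus white Gaussian noise.
#'
#' @param latent n_nodes x n_volumes latent matrix from
#'   [simulate_node_neural()].
#' @param config an [sim_cohort_config()] object (grid, node table, noise,
#'   drift, HRF at the config's TR).
#' @param seed RNG seed for the noise field.
#' @return an `RNifti` image (4D, float data; sform set to the grid affine)
#'   with attribute `"affine"`.
#' @export
render_bold <- function(latent, config, seed = config$seed) {
  gs <- config$grid_shape
  nv <- config$n_volumes
  stopifnot(ncol(latent) == nv)
  affine <- make_affine(gs, config$voxel_size)
  nodes <- build_nodes(config$node_table, affine, gs)
  hrf <- canonical_hrf(config$tr)
  bold <- with_seed_or_not(seed, {
    arr <- array(rnorm(prod(gs) * nv, sd = config$noise_sd), dim = c(gs, nv))
    drift <- config$drift_amplitude * seq(-0.5, 0.5, length.out = nv)
    for (t in seq_len(nv)) arr[, , , t] <- arr[, , , t] + drift[t]
    for (k in seq_len(nrow(config$node_table))) {
      sig <- config$signal_scale * conv_causal(latent[k, ], hrf$values)
      cube <- nodes[[k]]$voxel_cube + 1
      for (r in seq_len(nrow(cube)))
        arr[cube[r, 1], cube[r, 2], cube[r, 3], ] <-
          arr[cube[r, 1], cube[r, 2], cube[r, 3], ] + sig
    }
    arr
  })
  img <- RNifti::asNifti(bold)
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  attr(img, "affine") <- affine
  img
}

#' Generate a full synthetic cohort
#'
#' Draws `n_ctrl + n_pp` subjects. Per-subject seeds for events, latent
#' signals, and noise are derived deterministically from the config's master
#' seed, so the whole cohort is reproducible from the config alone.
#'
#' @param config an [sim_cohort_config()] object.
#' @param render if `FALSE`, skip BOLD rendering (events + latent signals
#'   only; useful when only feature-level ground truth is needed).
#' @return an object of class `fc_cohort`: list with `subjects` (each having
#'   `id`, `group`, `events`, `latent`, `seeds`, and `bold` when rendered)
#'   and `manifest` (all generating parameters and per-subject seeds).
#' @export
generate_cohort <- function(config, render = TRUE) {
  n <- config$n_ctrl + config$n_pp
  seeds <- matrix(derive_seeds(config$seed, 3 * n), nrow = 3)
  groups <- c(rep("CTRL", config$n_ctrl), rep("PP", config$n_pp))
  ids <- sprintf("sub-%03d", seq_len(n))
  subjects <- lapply(seq_len(n), function(i) {
    ev <- generate_events(config, seed = seeds[1, i])
    lat <- simulate_node_neural(config, ev, groups[i], seed = seeds[2, i])
    s <- list(id = ids[i], group = groups[i], events = ev, latent = lat,
              seeds = seeds[, i])
    if (render) s$bold <- render_bold(lat, config, seed = seeds[3, i])
    s
  })
  manifest <- list(
    package_version = as.character(utils::packageVersion("fcmvpa")),
    parameters = config[setdiff(names(config), "node_table")],
    node_table = config$node_table,
    subjects = data.frame(id = ids, group = groups,
                          event_seed = seeds[1, ], neural_seed = seeds[2, ],
                          noise_seed = seeds[3, ]))
  structure(list(subjects = subjects, manifest = manifest),
            class = "fc_cohort")
}

#' Write a cohort to disk
#'
#' Per subject: a 4D NIfTI (`<id>_bold.nii.gz`) and a BIDS-style events TSV
#' (`<id>_events.tsv` with columns onset, duration, trial_type). Cohort-level:
#' `participants.tsv`, `nodes.csv`, and `manifest.json`.
#'
#' @param cohort an `fc_cohort` from [generate_cohort()] (rendered).
#' @param dir output directory (created if missing).
#' @param datatype NIfTI storage type (default `"float"`).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, datatype = "float") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort$subjects) {
    if (is.null(s$bold))
      stop("subject ", s$id, " has no rendered BOLD run; ",
           "call generate_cohort(render = TRUE)")
    RNifti::writeNifti(s$bold, file.path(dir, paste0(s$id, "_bold.nii.gz")),
                       datatype = datatype)
    utils::write.table(
      s$events[, c("onset", "duration", "trial_type")],
      file.path(dir, paste0(s$id, "_events.tsv")),
      sep = "\t", row.names = FALSE, quote = FALSE)
  }
  utils::write.table(cohort$manifest$subjects[, c("id", "group")],
                     file.path(dir, "participants.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  write.csv(cohort$manifest$node_table, file.path(dir, "nodes.csv"),
            row.names = FALSE)
  jsonlite::write_json(cohort$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
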