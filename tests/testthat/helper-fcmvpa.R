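# Shared fixtures, built in code at test time.

# Compact rendering grid used throughout the tests (3 mm isotropic); the
# synthetic node table fits it by construction.
test_grid <- c(24L, 24L, 16L)

test_config <- function(...) {
  sim_cohort_config(grid_shape = test_grid, ...)
}

# One rendered subject on the compact grid, cached per argument set.
.subject_cache <- new.env(parent = emptyenv())
cached_subject <- function(seed = 101, noise_sd = 0.2, node_table = NULL,
                           group = "CTRL") {
  key <- paste(seed, noise_sd, group,
               if (is.null(node_table)) "full" else nrow(node_table))
  if (!is.null(.subject_cache[[key]])) return(.subject_cache[[key]])
  cfg <- if (is.null(node_table)) test_config(noise_sd = noise_sd, seed = seed)
         else test_config(noise_sd = noise_sd, node_table = node_table,
                          seed = seed)
  ev <- generate_events(cfg, seed = seed)
  lat <- simulate_node_neural(cfg, ev, group, seed = seed + 1)
  bold <- render_bold(lat, cfg, seed = seed + 2)
  res <- list(config = cfg, events = ev, latent = lat, bold = bold)
  .subject_cache[[key]] <- res
  res
}

# Feature matrix + labels for a rendered cohort (the slow path, used where a
# test genuinely needs the full chain).
cohort_features <- function(cfg) {
  coh <- generate_cohort(cfg, render = TRUE)
  feats <- lapply(coh$subjects, function(s)
    subject_features(s$bold, s$events, cfg$node_table, tr = cfg$tr,
                     subject_id = s$id))
  list(x = t(vapply(feats, function(f) f$r, numeric(length(feats[[1]]$r)))),
       labels = factor(vapply(coh$subjects, `[[`, "", "group")),
       edges = feats[[1]]$edges, cohort = coh)
}
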