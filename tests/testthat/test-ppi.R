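test_that("psychological sticks land on the nearest TR bin with the right sign", {
  ev <- data.frame(onset = c(10, 20, 33), duration = 4,
                   trial_type = c("R-hit", "K-hit", "miss"))
  psych <- make_psych_factor(ev, n_volumes = 30, tr = 2)
  expected <- integer(30)
  expected[6] <- 1L    # 10 s -> bin 5 (0-based) -> element 6
  expected[11] <- -1L  # 20 s -> bin 10
  expect_identical(psych, expected)   # miss trials contribute nothing
})

test_that("the stick vector sums to #R-hit minus #K-hit", {
  for (seed in 1:3) {
    cfg <- test_config(seed = seed)
    ev <- generate_events(cfg)
    psych <- make_psych_factor(ev, cfg$n_volumes, cfg$tr)
    expect_equal(sum(psych),
                 sum(ev$trial_type == "R-hit") - sum(ev$trial_type == "K-hit"))
    expect_true(all(psych %in% c(-1L, 0L, 1L)))
  }
  none <- data.frame(onset = c(2, 6), duration = 4,
                     trial_type = c("miss", "CR"))
  expect_identical(make_psych_factor(none, 10, 2), integer(10))
})

test_that("opposite-sign onsets in one bin are refused with trial ids", {
  ev <- data.frame(onset = c(10, 10.4), duration = 4,
                   trial_type = c("R-hit", "K-hit"))
  expect_error(make_psych_factor(ev, 20, 2), "ambiguous.*trials 1, 2")
})

test_that("a zero psych factor annihilates the PPI series", {
  withr::with_seed(2, block <- matrix(rnorm(27 * 80), 27, 80))
  h <- canonical_hrf(2)
  out <- ppi_node_series(block, integer(80), h, lambda = 1e-3)
  expect_equal(out, numeric(80))
})

test_that("identical voxel series average to the single-voxel result", {
  withr::with_seed(3, v <- rnorm(80))
  h <- canonical_hrf(2)
  psych <- integer(80); psych[c(6, 20, 41)] <- c(1L, -1L, 1L)
  one <- ppi_node_series(matrix(v, 1, 80), psych, h, lambda = 1e-3)
  many <- ppi_node_series(matrix(v, 27, 80, byrow = TRUE), psych, h,
                          lambda = 1e-3)
  expect_equal(many, one)
})

test_that("negating the psych factor negates PPI series, leaving |r| fixed", {
  s <- cached_subject(seed = 101, noise_sd = 0.2,
                      node_table = synthetic_node_table()[1:4, ])
  nodes <- build_nodes(s$config$node_table, make_affine(test_grid), test_grid)
  psych <- make_psych_factor(s$events, 360, 2)
  h <- canonical_hrf(2)
  blocks <- lapply(nodes, function(n) extract_block(s$bold, n))
  pos <- vapply(blocks, ppi_node_series, numeric(360),
                psych = psych, hrf = h, lambda = 1e-2)
  neg <- vapply(blocks, ppi_node_series, numeric(360),
                psych = -psych, hrf = h, lambda = 1e-2)
  expect_equal(neg, -pos)
  expect_equal(abs(connectivity_features(t(neg))$r),
               abs(connectivity_features(t(pos))$r))
})

test_that("16 nodes yield 120 lower-triangle features in row-major order", {
  em <- edge_index_map(paste0("n", 1:16))
  expect_equal(nrow(em), 120)
  expect_true(all(em$i > em$j))
  expect_equal(em$i[1:4], c(2L, 3L, 3L, 4L))
  expect_equal(em$j[1:4], c(1L, 1L, 2L, 1L))
  expect_equal(em$name[1], "n2~n1")
  expect_equal(nrow(edge_index_map(paste0("n", 1:4))), 6)
})

test_that("connectivity features reproduce hand-computed correlations", {
  mat <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = c(4, 3, 2, 1))
  f <- connectivity_features(mat)
  expect_equal(unname(f$r[f$edges$name == "b~a"]), 1)
  expect_equal(unname(f$r[f$edges$name == "c~a"]), -1)
  dup <- rbind(mat, d = c(1, 2, 3, 4))
  expect_equal(unname(connectivity_features(dup)$r)[
    connectivity_features(dup)$edges$name == "d~a"], 1)
})

test_that("connectivity matrices are symmetric, unit-diagonal, bounded", {
  for (seed in 1:3) {
    withr::with_seed(seed, mat <- matrix(rnorm(16 * 50), 16, 50))
    f <- connectivity_features(mat)
    expect_equal(f$matrix, t(f$matrix))
    expect_equal(unname(diag(f$matrix)), rep(1, 16))
    expect_true(all(f$r >= -1 & f$r <= 1))
    expect_length(f$r, 120)
  }
})

test_that("constant node series are refused by name", {
  mat <- rbind(a = rnorm(10), flatline = rep(2, 10), c = rnorm(10))
  expect_error(connectivity_features(mat), "flatline")
})

test_that("the node-signal chain is deterministic and detrended", {
  s <- cached_subject(seed = 101, noise_sd = 0.2)
  nodes <- build_nodes(s$config$node_table, make_affine(test_grid), test_grid)
  sig1 <- node_signal_set(s$bold, nodes, s$events, tr = 2)
  sig2 <- node_signal_set(s$bold, nodes, s$events, tr = 2)
  expect_identical(sig1$signals, sig2$signals)
  expect_equal(dim(sig1$signals), c(16, 360))
  t <- seq_len(360)
  for (k in c(1, 8, 16)) {
    expect_lt(abs(mean(sig1$signals[k, ])), 1e-8)
    expect_lt(abs(unname(coef(lm(sig1$signals[k, ] ~ t))[2])), 1e-8)
  }
  # features from the set match features from the bare matrix
  expect_equal(connectivity_features(sig1)$r,
               connectivity_features(sig1$signals)$r)
})

test_that("coupled nodes show stronger PPI correlation than uncoupled ones", {
  nt <- synthetic_node_table()[1:6, ]
  eff <- data.frame(i = 2, j = 1, delta_rho = 0.6)
  for (seed in 1:5) {
    cfg <- test_config(n_ctrl = 1, n_pp = 1, node_table = nt,
                       subject_rho_sd = 0, effect_edges = eff,
                       noise_sd = 0.1, seed = seed)
    ev <- generate_events(cfg, seed = seed)
    lat <- simulate_node_neural(cfg, ev, "PP", seed = seed + 50)
    bold <- render_bold(lat, cfg, seed = seed + 100)
    f <- subject_features(bold, ev, nt, tr = 2)
    r_eff <- f$r[f$edges$i == 2 & f$edges$j == 1]
    r_other <- f$r[!(f$edges$i == 2 & f$edges$j == 1)]
    # the coupled pair beats the uncoupled population, and sits near the top
    expect_gt(r_eff, median(r_other))
    expect_lte(sum(r_other > r_eff), 2)
  }
})
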