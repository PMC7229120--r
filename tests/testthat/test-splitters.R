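test_that("tuning curves implement the stated occupancy normalisation", {
  # 1 bin; left trial: 2 events over 0.5 s occupancy -> 4 events/s
  s <- toy_stem_session(turns = c("left", "right"),
                        events_by_trial = list(c(1L, 3L), integer(0)),
                        frame_rate = 10, frames_per_trial = 5L)
  tun <- stem_tuning_curves(s$raster, s$trace, s$trials, neuron = 1,
                            geometry = s$geometry)
  expect_equal(tun$tc_left, 4)
  expect_equal(tun$tc_right, 0)
  expect_equal(tun$occupancy_left, 0.5)

  # zero events: both curves identically zero
  s0 <- toy_stem_session(turns = c("left", "right"),
                         events_by_trial = list(integer(0), integer(0)))
  tun0 <- stem_tuning_curves(s0$raster, s0$trace, s0$trials, 1,
                             geometry = s0$geometry)
  expect_true(all(tun0$tc_left == 0) && all(tun0$tc_right == 0))

  # halving the frame rate doubles occupancy and halves the curves
  s2 <- toy_stem_session(turns = c("left", "right"),
                         events_by_trial = list(c(1L, 3L), integer(0)),
                         frame_rate = 5, frames_per_trial = 5L)
  tun2 <- stem_tuning_curves(s2$raster, s2$trace, s2$trials, 1,
                             geometry = s2$geometry)
  expect_equal(tun2$tc_left, tun$tc_left / 2)
})

test_that("identical rasters across trials give no significant bins", {
  s <- toy_stem_session(turns = rep(c("left", "right"), 3),
                        events_by_trial = rep(list(c(2L)), 6))
  tun <- stem_tuning_curves(s$raster, s$trace, s$trials, 1,
                            geometry = s$geometry)
  pt <- permutation_test(tun, n_shuffles = 200, seed = 3)
  expect_true(all(pt$real_diff == 0))
  expect_true(all(pt$rel_per_bin == 0))
  expect_false(any(pt$sig_bin_mask))
})

test_that("permutation exceedance matches exhaustive enumeration (3L+3R)", {
  cfg <- quick_config(n_neurons = 6L, n_trials = 6L, error_rate = 0,
                      frac_splitter = 0.5, frac_stem_pc = 0.5,
                      frac_arm_pc = 0)
  b <- generate_session(cfg)
  geom <- synth_geometry(cfg)
  tr <- parse_trials(b$behavior, geom)
  mats <- splitscope:::stem_count_matrices(b$raster, b$behavior, tr, geom)
  combos <- utils::combn(6L, 3L)            # all 20 label assignments
  for (n in 1:4) {
    tun <- splitscope:::stem_tuning_from_matrices(
      mats$counts[n, , , drop = FALSE], mats, n)
    rate_diff <- function(is_l) {
      abs(colSums(tun$counts[is_l, , drop = FALSE]) /
            colSums(tun$occ[is_l, , drop = FALSE]) -
          colSums(tun$counts[!is_l, , drop = FALSE]) /
            colSums(tun$occ[!is_l, , drop = FALSE]))
    }
    real <- rate_diff(tun$turn == "left")
    stats_enum <- apply(combos, 2L, function(ix) {
      rate_diff(seq_len(6L) %in% ix)
    })
    exceed <- real > stats_enum
    exceed[is.na(exceed)] <- FALSE      # same tie/NA convention as the test
    rel_enum <- rowMeans(exceed)
    pt <- permutation_test(tun, n_shuffles = 1000, seed = 50 + n)
    ok <- is.finite(real)
    expect_lt(max(abs(pt$rel_per_bin[ok] - rel_enum[ok])), 0.04)
  }
})

test_that("splitter classification applies both thresholds", {
  mask3 <- c(rep(TRUE, 3), rep(FALSE, 47))
  expect_true(classify_splitter(mask3, n_stem_event_trials = 5))
  expect_false(classify_splitter(c(rep(TRUE, 2), rep(FALSE, 48)),
                                 n_stem_event_trials = 20))
  expect_false(classify_splitter(rep(TRUE, 10), n_stem_event_trials = 4))
})

test_that("discriminability follows its closed form", {
  tun_eq <- tuning_from_counts(rbind(c(2, 2), c(2, 2)),
                               occ = matrix(1, 2, 2),
                               turn = c("left", "right"))
  expect_equal(discriminability(tun_eq), 0)

  tun_disj <- tuning_from_counts(rbind(c(1, 0), c(0, 1)),
                                 occ = matrix(1, 2, 2),
                                 turn = c("left", "right"))
  expect_equal(discriminability(tun_disj), 1)

  tun_mid <- tuning_from_counts(rbind(c(2, 1), c(1, 1)),
                                occ = matrix(1, 2, 2),
                                turn = c("left", "right"))
  expect_equal(discriminability(tun_mid), 0.2)

  tun_zero <- tuning_from_counts(matrix(0, 2, 2), occ = matrix(1, 2, 2),
                                 turn = c("left", "right"))
  expect_true(is.na(discriminability(tun_zero)))

  # invariance to a common positive rescaling of both curves
  tun_scaled <- tuning_from_counts(rbind(c(2, 1), c(1, 1)) * 7,
                                   occ = matrix(1, 2, 2),
                                   turn = c("left", "right"))
  expect_equal(discriminability(tun_scaled), 0.2)
})

test_that("reliability summary is the mean and max over valid bins", {
  expect_equal(reliability_summary(c(0.2, 1.0, 0.6)),
               c(mean = 0.6, peak = 1.0))
  expect_equal(reliability_summary(c(0, 0, 0)), c(mean = 0, peak = 0))
  expect_equal(reliability_summary(c(0.2, 1.0, 0.6), c(TRUE, FALSE, TRUE)),
               c(mean = 0.4, peak = 0.6))
})

test_that("1 - Spearman's rho matches hand-computed values", {
  tun <- tuning_from_counts(rbind(c(1, 2, 3), c(2, 1, 3)),
                            occ = matrix(1, 2, 3),
                            turn = c("left", "right"))
  expect_equal(tuning_correlation_metric(tun), 0.5)

  tun_same <- tuning_from_counts(rbind(c(1, 2, 3), c(2, 4, 6)),
                                 occ = matrix(1, 2, 3),
                                 turn = c("left", "right"))
  expect_equal(tuning_correlation_metric(tun_same), 0)

  tun_rev <- tuning_from_counts(rbind(c(1, 2, 3), c(3, 2, 1)),
                                occ = matrix(1, 2, 3),
                                turn = c("left", "right"))
  expect_equal(tuning_correlation_metric(tun_rev), 2)

  tun_flat <- tuning_from_counts(rbind(c(1, 1, 1), c(1, 2, 3)),
                                 occ = matrix(1, 2, 3),
                                 turn = c("left", "right"))
  expect_true(is.na(tuning_correlation_metric(tun_flat)))
})

test_that("ANOVA check confirms real modulation, rejects a lateral confound", {
  cfg <- quick_config(n_neurons = 4L, frac_splitter = 1, frac_stem_pc = 0,
                      frac_arm_pc = 0, n_trials = 40L, seed = 21L)
  b <- generate_session(cfg)
  geom <- synth_geometry(cfg)
  tr <- parse_trials(b$behavior, geom)
  chk <- anova_covariate_check(b$raster, b$behavior, tr,
                               b$raster$neuron_ids[1], geom)
  expect_true(chk$confirmed)

  # a neuron driven purely by lateral position (trajectory-independent
  # confound): events wherever the animal drifts left of the midline
  ev2 <- matrix(as.integer(b$behavior$lateral < -0.5 &
                             b$behavior$section %in% "stem"), 1)
  ras2 <- event_raster(ev2, cfg$frame_rate_hz, neuron_ids = 99L)
  chk2 <- anova_covariate_check(ras2, b$behavior, tr, 99L, geom)
  expect_false(chk2$confirmed)
})

test_that("metric-performance correlation handles both aggregation levels", {
  perf <- c(0.5, 0.6, 0.7, 0.8, 0.9, 0.95)
  out <- correlate_metric_with_performance(perf, perf)
  expect_equal(out$estimate, 1)

  with_seed_metric <- c(0.3, 0.1, 0.25, 0.15, 0.2, 0.22)
  mice <- rep(c("m1", "m2", "m3"), each = 2)
  out_m <- correlate_metric_with_performance(with_seed_metric, perf,
                                             mouse = mice, level = "mice")
  expect_equal(out_m$n, 3L)
  expect_error(correlate_metric_with_performance(c(1, 2), c(1, 2)),
               "insufficient data")

  # independence: large-sample correlation near zero
  set.seed(4)
  a <- runif(400); b <- runif(400)
  expect_lt(abs(correlate_metric_with_performance(a, b)$estimate), 0.15)
})

test_that("discriminability grows with modulation ratio in expectation", {
  means <- vapply(c(1, 2, 4), function(r) {
    cfg <- quick_config(n_neurons = 40L, frac_splitter = 1,
                        frac_stem_pc = 0, frac_arm_pc = 0,
                        modulation_ratio = r, n_trials = 30L, seed = 31L)
    b <- generate_session(cfg)
    geom <- synth_geometry(cfg)
    tr <- parse_trials(b$behavior, geom)
    d <- vapply(b$raster$neuron_ids, function(id)
      discriminability(stem_tuning_curves(b$raster, b$behavior, tr, id,
                                          geom)),
      numeric(1))
    mean(d, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})
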