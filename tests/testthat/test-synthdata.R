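test_that("invalid configurations name the offending field", {
  expect_error(synth_config(frac_splitter = 1.2), "frac_splitter")
  expect_error(synth_config(frac_splitter = 0.6, frac_stem_pc = 0.6),
               "frac_splitter")
  expect_error(synth_config(base_event_rate_hz = 0), "base_event_rate_hz")
  expect_error(synth_config(modulation_ratio = 0.5), "modulation_ratio")
  expect_error(synth_config(n_trials = 0), "n_trials")
  expect_error(synth_config(persist_prob = c(splitter = 0.5)),
               "persist_prob")
})

test_that("generation is deterministic given (config, seed)", {
  cfg <- quick_config(n_sessions = 2L)
  a <- generate_experiment(cfg)
  b <- generate_experiment(cfg)
  expect_identical(a$truth, b$truth)
  expect_identical(a$sessions[[2]]$raster$events, b$sessions[[2]]$raster$events)
  expect_identical(a$sessions[[1]]$behavior$x, b$sessions[[1]]$behavior$x)
  expect_identical(a$sessions[[2]]$roi, b$sessions[[2]]$roi)
})

test_that("adding neurons does not reshuffle existing neurons' draws", {
  # same class for every neuron so per-neuron field parameters line up;
  # the event streams of the first five neurons must be unchanged
  small <- generate_session(quick_config(n_neurons = 5L, frac_splitter = 0,
                                         frac_stem_pc = 1, frac_arm_pc = 0))
  big <- generate_session(quick_config(n_neurons = 12L, frac_splitter = 0,
                                       frac_stem_pc = 1, frac_arm_pc = 0))
  expect_identical(small$raster$events[1:5, ], big$raster$events[1:5, ])
  expect_identical(small$behavior$x, big$behavior$x)
})

test_that("error-free behavior alternates strictly and parses as correct", {
  cfg <- quick_config(error_rate = 0, n_trials = 10L)
  b <- generate_session(cfg)
  expect_true(all(b$turns[-1] != b$turns[-10]))
  tr <- parse_trials(b$behavior, synth_geometry(cfg))
  expect_equal(nrow(tr), 10L)
  expect_identical(tr$turn, b$turns)
  expect_true(all(tr$correct))
})

test_that("session performance converges to 1 - error_rate", {
  cfg <- quick_config(error_rate = 0.25, n_trials = 120L, n_neurons = 1L)
  b <- generate_session(cfg)
  tr <- parse_trials(b$behavior, synth_geometry(cfg))
  perf <- session_performance(tr)
  # binomial 99% band around 1 - error_rate (first trial always correct)
  se <- sqrt(0.25 * 0.75 / 120)
  expect_lt(abs(perf - 0.75), 3 * se + 1 / 120)
})

test_that("in-field transient-onset rate matches the configured rate", {
  cfg <- quick_config(n_neurons = 10L, frac_splitter = 0, frac_stem_pc = 1,
                      frac_arm_pc = 0, n_trials = 200L, seed = 5L)
  b <- generate_session(cfg)
  truth <- make_ground_truth(cfg)
  obs <- exp_t <- 0
  for (j in seq_len(10L)) {
    ctr <- truth$field_center_cm[truth$neuron_id == b$raster$neuron_ids[j]]
    near <- abs(b$behavior$y - ctr) <= 2 &
      abs(b$behavior$x) <= 6
    obs <- obs + sum(b$onsets[j, near])
    exp_t <- exp_t + sum(near) / cfg$frame_rate_hz
  }
  gain <- exp(-(2 / cfg$field_width_cm)^2 / 2)   # conservative edge gain
  rate_hat <- obs / exp_t
  expect_lt(abs(rate_hat - cfg$base_event_rate_hz) /
              cfg$base_event_rate_hz, 0.1 + (1 - gain))
})

test_that("unmodulated neurons have matched left/right stem rates", {
  cfg <- quick_config(n_neurons = 40L, frac_splitter = 1, frac_stem_pc = 0,
                      frac_arm_pc = 0, modulation_ratio = 1, n_trials = 40L)
  b <- generate_session(cfg)
  geom <- synth_geometry(cfg)
  tr <- parse_trials(b$behavior, geom)
  diffs <- vapply(b$raster$neuron_ids, function(id) {
    tun <- stem_tuning_curves(b$raster, b$behavior, tr, id, geom)
    v <- tun$valid
    mean(tun$tc_left[v] - tun$tc_right[v])
  }, numeric(1))
  # signed differences average out across neurons under no modulation
  expect_lt(abs(mean(diffs)), 3 * stats::sd(diffs) / sqrt(length(diffs)))
})

test_that("class-dependent persistence shows up in stay-active frequency", {
  cfg <- synth_config(n_neurons = 600L, frac_splitter = 0.5,
                      frac_stem_pc = 0, frac_arm_pc = 0.5, n_sessions = 2L,
                      n_trials = 4L,
                      persist_prob = c(splitter = 0.9, stem_pc = 0.7,
                                       arm_pc = 0.5, stem_npc = 0.7,
                                       arm_npc = 0.7),
                      seed = 9L)
  truth <- make_ground_truth(cfg)
  act <- attr(truth, "active")
  stay <- tapply(act[, 2], truth$true_class, mean)
  expect_gt(stay[["splitter"]], stay[["arm_pc"]])
  expect_lt(abs(stay[["splitter"]] - 0.9), 3 * sqrt(0.9 * 0.1 / 300))
  expect_lt(abs(stay[["arm_pc"]] - 0.5), 3 * sqrt(0.5 * 0.5 / 300))
})

test_that("single-session experiments mark every neuron active in session 1", {
  cfg <- quick_config(n_sessions = 1L)
  ex <- generate_experiment(cfg)
  expect_length(ex$sessions, 1L)
  expect_true(all(vapply(seq_len(cfg$n_neurons),
                         function(n) identical(active_sessions(ex$truth, n),
                                               1L),
                         logical(1))))
})

test_that("persist_prob = 1 keeps every neuron active in all sessions", {
  cfg <- quick_config(n_sessions = 4L, persist_prob = 1)
  truth <- make_ground_truth(cfg)
  expect_true(all(attr(truth, "active")))
})

test_that("fixtures round-trip losslessly through the readers", {
  cfg <- quick_config(n_neurons = 6L, n_trials = 4L, n_sessions = 2L)
  ex <- generate_experiment(cfg)
  dir <- withr::local_tempdir()
  manifest <- write_fixtures(ex, dir)
  for (s in 1:2) {
    expect_setequal(manifest$kind[manifest$session == s &
                                    !is.na(manifest$session)],
                    c("behavior", "raster", "raster_meta", "roi"))
    back <- read_session_bundle(file.path(dir, sprintf("s%02d", s)))
    orig <- ex$sessions[[s]]
    expect_identical(back$raster$events, orig$raster$events)
    expect_identical(back$raster$neuron_ids, orig$raster$neuron_ids)
    expect_equal(back$behavior$x, orig$behavior$x, tolerance = 1e-9)
    expect_equal(back$roi$orientation_deg, orig$roi$orientation_deg,
                 tolerance = 1e-9)
  }
})

test_that("an empty session writes valid header-only files", {
  cfg <- quick_config(n_neurons = 0L, n_trials = 3L)
  ex <- generate_experiment(cfg)
  dir <- withr::local_tempdir()
  write_fixtures(ex, dir)
  back <- read_session_bundle(file.path(dir, "s01"))
  expect_equal(nrow(back$raster$events), 0L)
  expect_equal(nrow(back$roi), 0L)
})
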