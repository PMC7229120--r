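roi_table <- function(x, y, ori, ids = seq_along(x)) {
  data.frame(neuron_id = ids, x_um = x, y_um = y, orientation_deg = ori)
}

test_that("registration matches identical tables and rejects large shifts", {
  roi <- roi_table(x = c(10, 50, 90), y = c(10, 50, 90), ori = c(0, 45, 90))
  reg <- register_sessions(roi, roi)
  expect_equal(reg$neuron_a, reg$neuron_b)
  expect_true(all(reg$distance_um == 0))
  expect_true(all(reg$d_orientation_deg == 0))

  shifted <- roi_table(x = roi$x_um + 50, y = roi$y_um, ori = roi$orientation_deg)
  expect_equal(nrow(register_sessions(roi, shifted, max_dist_um = 5)), 0L)
  expect_error(register_sessions(roi[, 1:2], roi), "registration error")
})

test_that("registration recovers ground-truth identity under ROI jitter", {
  cfg <- quick_config(n_neurons = 200L, n_sessions = 2L, n_trials = 2L,
                      persist_prob = 1, roi_jitter_um = 1.5, seed = 43L)
  ex <- generate_experiment(cfg)
  reg <- register_sessions(ex$sessions[[1]]$roi, ex$sessions[[2]]$roi,
                           max_dist_um = 8)
  hits <- sum(reg$neuron_a == reg$neuron_b)
  expect_gte(hits / cfg$n_neurons, 0.99)
})

test_that("orientation QC passes true matches and fails random pairings", {
  set.seed(11)
  n <- 60L
  ori <- runif(n, 0, 180)
  roi_a <- roi_table(x = runif(n, 0, 500), y = runif(n, 0, 500), ori = ori)
  roi_b <- roi_table(x = roi_a$x_um + rnorm(n, 0, 1),
                     y = roi_a$y_um + rnorm(n, 0, 1),
                     ori = (ori + rnorm(n, 0, 3)) %% 180)
  reg <- register_sessions(roi_a, roi_b, max_dist_um = 6)
  qc <- registration_qc(reg, roi_a, roi_b, seed = 2L)
  expect_equal(qc$verdict, "pass")
  expect_lt(qc$real_mean_deg, qc$null_mean_deg)

  # scrambled identities: orientation changes look like chance
  roi_b_scr <- roi_b
  roi_b_scr$orientation_deg <- sample(roi_b$orientation_deg)
  qc_scr <- registration_qc(reg, roi_a, roi_b_scr, seed = 2L)
  expect_equal(qc_scr$verdict, "fail")

  expect_equal(registration_qc(reg[1:5, ], roi_a, roi_b)$verdict,
               "indeterminate")
})

test_that("functional labels follow the designation rules exactly", {
  lab <- assign_coding_labels(
    is_splitter  = c(TRUE,  TRUE,  FALSE, FALSE, FALSE, FALSE),
    is_place_cell = c(TRUE, FALSE, TRUE,  TRUE,  FALSE, FALSE),
    stem_active  = c(TRUE,  TRUE,  FALSE, TRUE,  TRUE,  FALSE))
  expect_identical(as.character(lab),
                   c("splitter", "splitter", "arm_pc", "stem_pc",
                     "stem_npc", "arm_npc"))
  expect_false(anyNA(lab))               # the labels partition the neurons
})

test_that("stay-active probabilities follow the counting rules", {
  reg <- data.frame(neuron_a = 1:10, neuron_b = 101:110,
                    distance_um = 0, d_orientation_deg = 0)
  labels <- factor(c(rep("splitter", 10), rep("arm_pc", 3)),
                   levels = c("splitter", "stem_pc", "arm_pc", "stem_npc",
                              "arm_npc"))
  neurons <- 1:13
  events <- c(rep(10L, 9), 4L, rep(10L, 3))
  # second session retains neurons 101:107 only
  tab <- stay_active_probability(reg, labels, neurons, events,
                                 neurons_b = 101:107, lag = 1L)
  # neuron 10 has 4 events (< 5): excluded from the base population
  spl <- tab[tab$class == "splitter", ]
  expect_equal(spl$n_base, 9L)
  expect_equal(spl$n_stay, 7L)
  expect_equal(spl$probability, 7 / 9)
  # arm_pc has 3 cells (< 4): row excluded with a reason
  expect_false("arm_pc" %in% tab$class)
  expect_true("arm_pc" %in% attr(tab, "excluded"))
})

test_that("event-rate matching drops low-rate cells up to the reference", {
  rates <- c(2, 3, 1, 2, 3)               # splitters mean 2.5
  labels <- c("splitter", "splitter", "arm_pc", "arm_pc", "arm_pc")
  keep <- event_rate_match(rates, labels)
  # arm rates {1,2,3} vs reference mean 2.5: drop the 1 (new mean 2.5)
  expect_identical(keep, structure(c(TRUE, TRUE, FALSE, TRUE, TRUE),
                                   failed_classes = character(0)))
  # class already above the reference: untouched
  keep2 <- event_rate_match(c(1, 1, 5, 6), c("splitter", "splitter",
                                             "arm_pc", "arm_pc"))
  expect_true(all(keep2))
  # reference rates everywhere: no drops
  keep3 <- event_rate_match(rep(2, 4), c("splitter", "arm_pc", "arm_pc",
                                         "stem_pc"))
  expect_true(all(keep3))
  # reference class is never touched even when it has the lowest rates
  keep4 <- event_rate_match(c(1, 9, 9), c("splitter", "arm_pc", "arm_pc"))
  expect_true(keep4[1])
})

test_that("cross-session map correlations respect rank invariance", {
  mk <- function(rate) {
    structure(list(rate = rate, visited = !is.na(rate), bin_cm = 1),
              class = "smoothed_map")
  }
  base <- matrix(runif(100, 0, 5), 10, 10)
  reg <- data.frame(neuron_a = c(1L, 2L), neuron_b = c(1L, 2L),
                    distance_um = 0, d_orientation_deg = 0)
  maps_a <- list(`1` = mk(base), `2` = mk(base))
  maps_b <- list(`1` = mk(base), `2` = mk(base^3 * 2))  # monotone rescale
  out <- spatial_correlation_across_sessions(maps_a, maps_b, reg)
  expect_equal(out$rho, c(1, 1))

  # too few mutually visited bins: skipped with a reason
  sparse <- mk(matrix(c(1:5, rep(NA, 95)), 10, 10))
  out2 <- spatial_correlation_across_sessions(list(`1` = sparse),
                                              list(`1` = sparse),
                                              reg[1, ])
  expect_true(is.na(out2$rho))
  expect_match(out2$reason, "mutually visited")

  # independent maps: correlations centred on zero
  set.seed(3)
  rhos <- replicate(40, {
    a <- mk(matrix(runif(100), 10, 10))
    b <- mk(matrix(runif(100), 10, 10))
    spatial_correlation_across_sessions(list(`1` = a), list(`1` = b),
                                        reg[1, ])$rho
  })
  expect_lt(abs(mean(rhos)), 0.06)
})

test_that("lag comparisons correct over tested lags only", {
  set.seed(5)
  lag <- rep(1:4, each = 8)
  spl <- 0.9 + rnorm(32, 0, 0.02)
  oth <- spl - 0.25 + rnorm(32, 0, 0.02)   # uniformly lower
  tab <- lag_comparison_test(lag, spl, oth)
  expect_equal(tab$lag, 1:4)
  expect_true(all(tab$significant))
  expect_equal(tab$p_holm, stats::p.adjust(tab$p, "holm"))

  # identical paired samples: no effect, nothing significant
  tab0 <- lag_comparison_test(lag, spl, spl)
  expect_false(any(tab0$significant))

  # lags with too few pairs are not part of the correction family
  lag2 <- c(rep(1L, 8), rep(2L, 3))
  tab2 <- lag_comparison_test(lag2, c(spl[1:8], 1, 1, 1),
                              c(oth[1:8], 0, 0, 0))
  expect_equal(tab2$lag, 1L)

  # the sign-test variant is available
  tabs <- lag_comparison_test(lag, spl, oth, test = "sign")
  expect_true(all(tabs$significant))
})
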