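# Shared fixture builders. Everything is generated in code; no data files.

# A deterministic raw-position table tracing the figure-8 maze for a
# given turn sequence (independent of the generator's path code).
raw_positions_for_turns <- function(turns, geom = maze_geometry(),
                                    step_cm = 1.5, dt = 0.05) {
  L <- geom$stem_length_cm
  y_top <- L + geom$choice_depth_cm / 2
  y_bot <- -geom$base_depth_cm / 2
  pts <- list()
  for (turn in turns) {
    s <- if (turn == "left") -1 else 1
    ax <- s * (geom$arm_inner_cm + geom$arm_outer_cm) / 2
    wp <- rbind(c(0, y_bot), c(0, y_top), c(ax, y_top), c(ax, y_bot),
                c(0, y_bot))
    for (i in seq_len(nrow(wp) - 1L)) {
      seg <- wp[i + 1L, ] - wp[i, ]
      len <- sqrt(sum(seg^2))
      n <- max(2L, ceiling(len / step_cm))
      f <- seq(0, 1, length.out = n + 1L)[-(n + 1L)]
      pts[[length(pts) + 1L]] <- cbind(wp[i, 1] + f * seg[1],
                                       wp[i, 2] + f * seg[2])
    }
  }
  xy <- do.call(rbind, pts)
  data.frame(time = (seq_len(nrow(xy)) - 1L) * dt, x = xy[, 1], y = xy[, 2])
}

trace_for_turns <- function(turns, geom = maze_geometry()) {
  raw <- raw_positions_for_turns(turns, geom)
  align_behavior_to_imaging(raw, raw$time, geometry = geom)
}

# Minimal hand-built stem session: a trace marching through the stem once
# per trial at fixed dwell, with a manually assembled trial table. Used
# for arithmetic oracles where every count and occupancy is known.
toy_stem_session <- function(turns, events_by_trial, frame_rate = 10,
                             frames_per_trial = 5L, stem_length = 1,
                             n_neurons = 1L) {
  n_trials <- length(turns)
  n_frames <- n_trials * frames_per_trial
  y <- rep(stem_length / 2, n_frames)       # all frames in the single bin
  trace <- data.frame(time = (seq_len(n_frames) - 1L) / frame_rate,
                      x = 0, y = y, speed = 10, valid = TRUE,
                      section = "stem", lateral = 0)
  class(trace) <- c("behavior_trace", "data.frame")
  attr(trace, "frame_rate_hz") <- frame_rate
  tt <- data.frame(trial = seq_len(n_trials), turn = turns,
                   correct = TRUE, forced = FALSE,
                   stem_start = (seq_len(n_trials) - 1L) * frames_per_trial
                   + 1L,
                   stem_end = seq_len(n_trials) * frames_per_trial)
  class(tt) <- c("trial_table", "data.frame")
  ev <- matrix(0L, n_neurons, n_frames)
  for (k in seq_along(events_by_trial)) {
    fr <- events_by_trial[[k]]
    if (length(fr)) ev[1L, (k - 1L) * frames_per_trial + fr] <- 1L
  }
  list(raster = event_raster(ev, frame_rate), trace = trace, trials = tt,
       geometry = maze_geometry(stem_length_cm = stem_length,
                                stem_restrict = c(0, 1)))
}

# A synth_tuning object built directly from count/occupancy matrices.
tuning_from_counts <- function(counts, occ, turn) {
  mats <- list(counts = array(counts, c(1L, nrow(counts), ncol(counts))),
               occ = occ, turn = turn,
               bin_edges = 0:ncol(counts), n_bins = ncol(counts))
  splitscope:::stem_tuning_from_matrices(mats$counts, mats, 1L)
}

# Small default generator config for quick multi-purpose sessions.
quick_config <- function(...) {
  args <- list(...)
  defaults <- list(n_neurons = 20L, n_trials = 12L, seed = 7L,
                   error_rate = 0.1)
  do.call(synth_config, utils::modifyList(defaults, args))
}
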