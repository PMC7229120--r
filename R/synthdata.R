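NEURON_CLASSES <- c("splitter", "stem_pc", "arm_pc", "stem_npc", "arm_npc")

#' Synthetic experiment configuration
#'
#' Parameters of the synthetic figure-8 alternation experiment. The
#' generator emulates the behavioral and neural structure of a
#' continuous-alternation calcium-imaging study: trial-by-trial
#' alternation with occasional errors, ballistic stem traversals with
#' speed and lateral-position jitter, per-frame Bernoulli calcium
#' transient onsets modulated by a Gaussian place field and (for
#' splitters) by upcoming turn direction, multi-session cell turnover
#' with class-dependent persistence, and ROI centroid/orientation jitter
#' across sessions.
#'
#' Transient onsets are drawn per frame with probability
#' \code{rate / frame_rate}; each transient marks the raster active for
#' \code{transient_duration_s} (its rising phase spans several frames, as
#' the upstream event extraction produces). \code{base_event_rate_hz} is
#' the transient-onset rate at the field peak.
#'
#' @param n_neurons number of neurons in the experiment.
#' @param frac_splitter,frac_stem_pc,frac_arm_pc class proportions; the
#'   remainder are non-place cells, split between arm and stem non-place
#'   cells by \code{npc_arm_frac}.
#' @param n_trials trials per session.
#' @param n_sessions number of sessions.
#' @param frame_rate_hz imaging frame rate (default 20 Hz).
#' @param stem_length_cm central stem length (default 64 cm).
#' @param modulation_ratio preferred:non-preferred transient-rate ratio for
#'   splitters on the stem (>= 1; 1 = no trajectory modulation).
#' @param base_event_rate_hz peak in-field transient-onset rate (events/s).
#' @param field_width_cm Gaussian place-field s.d. (cm).
#' @param error_rate probability a free trial violates alternation.
#' @param persist_prob per-class probability an active neuron remains
#'   active in the next session (scalar or named vector over classes).
#' @param roi_jitter_um ROI centroid jitter s.d. across sessions (um).
#' @param seed integer master seed; every random draw derives from it.
#' @param transient_duration_s duration a transient keeps the raster
#'   active (s).
#' @param run_speed_cms nominal running speed (cm/s).
#' @param speed_jitter_cms per-frame Gaussian speed jitter s.d. (cm/s).
#' @param lateral_sd_cm s.d. of smooth lateral-position noise on the stem.
#' @param npc_rate_scale non-place-cell transient rate as a fraction of
#'   \code{base_event_rate_hz}.
#' @param npc_arm_frac fraction of non-place cells confined to the arms
#'   (the rest are spatially uniform over the whole maze).
#' @param onset_delay_max latest session (1 + delay) at which a splitter's
#'   trajectory modulation can switch on; 0 = modulated from session 1.
#'   Before its onset session a splitter expresses its place field without
#'   trajectory modulation.
#' @param field_shift_mode if TRUE, splitters shift their field peak
#'   between left and right trials instead of scaling its rate.
#' @param session_days calendar day of each session (default one session
#'   per day).
#' @return a \code{synth_config} object.
#' @export
synth_config <- function(n_neurons = 100L, frac_splitter = 0.15,
                         frac_stem_pc = 0.20, frac_arm_pc = 0.30,
                         n_trials = 44L, n_sessions = 1L,
                         frame_rate_hz = 20, stem_length_cm = 64,
                         modulation_ratio = 4, base_event_rate_hz = 1.5,
                         field_width_cm = 10, error_rate = 0.15,
                         persist_prob = c(splitter = 0.95, stem_pc = 0.85,
                                          arm_pc = 0.75, stem_npc = 0.65,
                                          arm_npc = 0.65),
                         roi_jitter_um = 2, seed = 1L,
                         transient_duration_s = 0.5, run_speed_cms = 20,
                         speed_jitter_cms = 4, lateral_sd_cm = 1.5,
                         npc_rate_scale = 0.3, npc_arm_frac = 0.5,
                         onset_delay_max = 0L, field_shift_mode = FALSE,
                         session_days = NULL) {
  check_count(n_neurons, "n_neurons", min = 0L)
  check_scalar_prob(frac_splitter, "frac_splitter")
  check_scalar_prob(frac_stem_pc, "frac_stem_pc")
  check_scalar_prob(frac_arm_pc, "frac_arm_pc")
  if (frac_splitter + frac_stem_pc + frac_arm_pc > 1 + 1e-12)
    stop_config("frac_splitter", "class fractions must sum to at most 1")
  check_count(n_trials, "n_trials")
  check_count(n_sessions, "n_sessions")
  check_positive(frame_rate_hz, "frame_rate_hz")
  check_positive(stem_length_cm, "stem_length_cm")
  if (!is.numeric(modulation_ratio) || any(modulation_ratio < 1))
    stop_config("modulation_ratio", "must be >= 1")
  check_positive(base_event_rate_hz, "base_event_rate_hz")
  check_positive(field_width_cm, "field_width_cm")
  check_scalar_prob(error_rate, "error_rate")
  if (length(persist_prob) == 1L && is.null(names(persist_prob)))
    persist_prob <- stats::setNames(rep(persist_prob, 5L), NEURON_CLASSES)
  if (!all(NEURON_CLASSES %in% names(persist_prob)))
    stop_config("persist_prob",
                "must be a scalar or named over all five classes")
  persist_prob <- persist_prob[NEURON_CLASSES]
  if (any(persist_prob < 0 | persist_prob > 1))
    stop_config("persist_prob", "entries must be probabilities in [0, 1]")
  check_positive(roi_jitter_um, "roi_jitter_um", strict = FALSE)
  check_positive(transient_duration_s, "transient_duration_s")
  check_positive(run_speed_cms, "run_speed_cms")
  check_positive(speed_jitter_cms, "speed_jitter_cms", strict = FALSE)
  check_positive(lateral_sd_cm, "lateral_sd_cm", strict = FALSE)
  check_positive(npc_rate_scale, "npc_rate_scale")
  check_scalar_prob(npc_arm_frac, "npc_arm_frac")
  check_count(onset_delay_max, "onset_delay_max", min = 0L)
  if (is.null(session_days)) session_days <- seq_len(n_sessions)
  if (length(session_days) != n_sessions)
    stop_config("session_days", "must have one day per session")
  cfg <- list(n_neurons = as.integer(n_neurons),
              frac_splitter = frac_splitter, frac_stem_pc = frac_stem_pc,
              frac_arm_pc = frac_arm_pc, n_trials = as.integer(n_trials),
              n_sessions = as.integer(n_sessions),
              frame_rate_hz = frame_rate_hz,
              stem_length_cm = stem_length_cm,
              modulation_ratio = modulation_ratio,
              base_event_rate_hz = base_event_rate_hz,
              field_width_cm = field_width_cm, error_rate = error_rate,
              persist_prob = persist_prob, roi_jitter_um = roi_jitter_um,
              seed = as.integer(seed),
              transient_duration_s = transient_duration_s,
              run_speed_cms = run_speed_cms,
              speed_jitter_cms = speed_jitter_cms,
              lateral_sd_cm = lateral_sd_cm,
              npc_rate_scale = npc_rate_scale,
              npc_arm_frac = npc_arm_frac,
              onset_delay_max = as.integer(onset_delay_max),
              field_shift_mode = isTRUE(field_shift_mode),
              session_days = as.integer(session_days))
  class(cfg) <- "synth_config"
  cfg
}

#' Maze geometry implied by a synthetic configuration
#' @param config a \code{\link{synth_config}}.
#' @return a \code{\link{maze_geometry}}.
#' @export
synth_geometry <- function(config) {
  maze_geometry(stem_length_cm = config$stem_length_cm)
}

#' Ground truth for a synthetic experiment
#'
#' Assigns each neuron a coding class, field parameters, splitter onset
#' session, base ROI position and the set of sessions in which it is
#' active. Activity persists session-to-session as a Markov chain with
#' class-dependent persistence (all neurons are active in session 1;
#' dropout is absorbing), so the probability of staying active across a
#' lag of k sessions decays geometrically.
#'
#' @param config a \code{\link{synth_config}}.
#' @return a \code{ground_truth} data.frame (one row per neuron) with an
#'   \code{active} logical neuron x session matrix attached as an
#'   attribute.
#' @export
make_ground_truth <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_neurons
  n_split <- floor(config$frac_splitter * n)
  n_stem_pc <- floor(config$frac_stem_pc * n)
  n_arm_pc <- floor(config$frac_arm_pc * n)
  n_npc <- n - n_split - n_stem_pc - n_arm_pc
  n_arm_npc <- round(config$npc_arm_frac * n_npc)
  classes <- rep(NEURON_CLASSES,
                 c(n_split, n_stem_pc, n_arm_pc, n_npc - n_arm_npc,
                   n_arm_npc))
  g <- synth_geometry(config)
  with_rng(derive_seed(config$seed, 0L, 0L), {
    stem_lo <- 0.15 * config$stem_length_cm
    stem_hi <- 0.85 * config$stem_length_cm
    field_center <- rep(NA_real_, n)
    on_stem <- classes %in% c("splitter", "stem_pc")
    field_center[on_stem] <- stats::runif(sum(on_stem), stem_lo, stem_hi)
    on_arm <- classes == "arm_pc"
    field_center[on_arm] <- stats::runif(sum(on_arm), 0,
                                         0.85 * config$stem_length_cm)
    field_side <- rep(NA_character_, n)
    field_side[on_arm] <- sample(c("left", "right"), sum(on_arm),
                                 replace = TRUE)
    preferred_turn <- rep(NA_character_, n)
    is_split <- classes == "splitter"
    preferred_turn[is_split] <- sample(c("left", "right"), sum(is_split),
                                       replace = TRUE)
    onset_session <- rep(1L, n)
    if (config$onset_delay_max > 0L && any(is_split))
      onset_session[is_split] <-
        1L + sample.int(config$onset_delay_max + 1L, sum(is_split),
                        replace = TRUE) - 1L
    # base ROI centroids: jittered grid in a 500 x 500 um field of view,
    # guaranteeing spacing well above typical registration jitter
    k <- max(1L, ceiling(sqrt(n)))
    pitch <- 500 / k
    gx <- ((seq_len(n) - 1L) %% k + 0.5) * pitch
    gy <- ((seq_len(n) - 1L) %/% k + 0.5) * pitch
    roi_x <- gx + stats::runif(n, -pitch / 5, pitch / 5)
    roi_y <- gy + stats::runif(n, -pitch / 5, pitch / 5)
    roi_orient <- stats::runif(n, 0, 180)
    active <- matrix(FALSE, n, config$n_sessions)
    if (n > 0) {
      active[, 1L] <- TRUE
      if (config$n_sessions > 1L) {
        pp <- config$persist_prob[classes]
        for (s in 2L:config$n_sessions)
          active[, s] <- active[, s - 1L] & (stats::runif(n) < pp)
      }
    }
    truth <- data.frame(neuron_id = seq_len(n), true_class = classes,
                        field_center_cm = field_center,
                        field_side = field_side,
                        preferred_turn = preferred_turn,
                        modulation_ratio = ifelse(is_split,
                                                  config$modulation_ratio, 1),
                        true_onset_session = onset_session,
                        roi_x_um = roi_x, roi_y_um = roi_y,
                        roi_orientation_deg = roi_orient,
                        stringsAsFactors = FALSE)
    attr(truth, "active") <- active
    class(truth) <- c("ground_truth", "data.frame")
    truth
  })
}

#' Sessions in which a neuron is active
#' @param truth a \code{ground_truth}.
#' @param neuron neuron id.
#' @return integer vector of session indices.
#' @export
active_sessions <- function(truth, neuron) {
  which(attr(truth, "active")[neuron, ])
}

# Waypoints of one trial's traversal, by turn direction.
trial_waypoints <- function(turn, geometry) {
  g <- geometry
  L <- g$stem_length_cm
  side <- if (turn == "left") -1 else 1
  arm_x <- side * (g$arm_inner_cm + g$arm_outer_cm) / 2
  y_choice <- L + g$choice_depth_cm / 2
  y_back <- -g$base_depth_cm / 2
  rbind(c(0, y_back),        # base
        c(0, 0),             # stem entry
        c(0, L),             # stem top
        c(0, y_choice),      # choice
        c(arm_x, y_choice),  # entry
        c(arm_x, y_back),    # return arm
        c(0, y_back))        # approach -> base
}

# Position on the piecewise-linear trial path at arc length s.
path_position <- function(s, wp) {
  seg <- sqrt(rowSums(diff(wp)^2))
  cum <- c(0, cumsum(seg))
  s <- pmin(pmax(s, 0), cum[length(cum)])
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  i <- pmin(i, nrow(wp) - 1L)
  f <- (s - cum[i]) / seg[i]
  cbind(wp[i, 1] + f * (wp[i + 1, 1] - wp[i, 1]),
        wp[i, 2] + f * (wp[i + 1, 2] - wp[i, 2]))
}

# Per-frame transient-onset rate (Hz) for one neuron over the session.
neuron_rate <- function(info, config, x, y, frame_turn, session_index) {
  g_hw <- maze_geometry()$stem_halfwidth_cm  # corridor half width fixed
  sigma <- config$field_width_cm
  base <- config$base_event_rate_hz
  n <- length(x)
  rate <- numeric(n)
  cls <- info$true_class
  if (cls %in% c("splitter", "stem_pc")) {
    corridor <- abs(x) <= g_hw
    modulated <- cls == "splitter" && session_index >= info$true_onset_session
    if (modulated && config$field_shift_mode) {
      shift <- 0.75 * sigma
      center <- ifelse(frame_turn == info$preferred_turn,
                       info$field_center_cm + shift,
                       info$field_center_cm - shift)
      rate[corridor] <- base *
        exp(-(y[corridor] - center[corridor])^2 / (2 * sigma^2))
    } else {
      gpeak <- exp(-(y - info$field_center_cm)^2 / (2 * sigma^2))
      mod <- if (modulated)
        ifelse(frame_turn == info$preferred_turn, 1,
               1 / info$modulation_ratio)
      else 1
      rate[corridor] <- (base * gpeak * mod)[corridor]
    }
  } else if (cls == "arm_pc") {
    side <- if (info$field_side == "left") x < 0 else x > 0
    on_arm <- side & abs(x) > maze_geometry()$arm_inner_cm
    rate[on_arm] <- base *
      exp(-(y[on_arm] - info$field_center_cm)^2 / (2 * sigma^2))
  } else if (cls == "stem_npc") {
    rate[] <- base * config$npc_rate_scale
  } else { # arm_npc: uniform rate anywhere off the stem corridor
    rate[abs(x) > g_hw] <- base * config$npc_rate_scale
  }
  rate
}

#' Generate one synthetic session
#'
#' Simulates the behavior trace and the calcium activity of every neuron
#' active in the requested session. Deterministic given (config seed,
#' session index): behavior and each neuron draw from independent derived
#' RNG streams, so adding neurons does not reshuffle existing ones.
#'
#' @param config a \code{\link{synth_config}}.
#' @param session_index 1-based session index.
#' @param truth ground truth from \code{\link{make_ground_truth}} (built
#'   from \code{config} if omitted).
#' @return a \code{synth_session} list: \code{behavior} (a
#'   \code{behavior_trace}), \code{raster} (\code{\link{event_raster}} of
#'   the session's active neurons), \code{onsets} (transient-onset matrix
#'   matching the raster), \code{roi} (ROI table), \code{turns} (true turn
#'   sequence), \code{session_index}, \code{day}.
#' @export
generate_session <- function(config, session_index = 1L,
                             truth = make_ground_truth(config)) {
  stopifnot(inherits(config, "synth_config"))
  check_count(session_index, "session_index")
  if (session_index > config$n_sessions)
    stop_config("session_index", "exceeds n_sessions")
  geom <- synth_geometry(config)
  fr <- config$frame_rate_hz
  dt <- 1 / fr

  beh <- with_rng(derive_seed(config$seed, session_index, 0L), {
    turns <- character(config$n_trials)
    turns[1L] <- sample(c("left", "right"), 1L)
    if (config$n_trials > 1L) {
      for (t in 2L:config$n_trials) {
        err <- stats::runif(1) < config$error_rate
        turns[t] <- if (err) turns[t - 1L] else
          setdiff(c("left", "right"), turns[t - 1L])
      }
    }
    xs <- list(); ys <- list(); trial_of <- list()
    for (t in seq_len(config$n_trials)) {
      wp <- trial_waypoints(turns[t], geom)
      total <- sum(sqrt(rowSums(diff(wp)^2)))
      n_guess <- ceiling(total / max(config$run_speed_cms -
                                       3 * config$speed_jitter_cms, 3) *
                           fr) + 10L
      sp <- pmax(stats::rnorm(n_guess, config$run_speed_cms,
                              config$speed_jitter_cms), 3)
      s <- cumsum(sp * dt)
      keep <- s < total
      pos <- path_position(s[keep], wp)
      xs[[t]] <- pos[, 1]; ys[[t]] <- pos[, 2]
      trial_of[[t]] <- rep(t, sum(keep))
    }
    x <- unlist(xs); y <- unlist(ys); tri <- unlist(trial_of)
    # smooth lateral jitter on the central corridor
    n <- length(x)
    phi <- 0.9
    lat <- as.numeric(stats::filter(
      stats::rnorm(n, 0, config$lateral_sd_cm * sqrt(1 - phi^2)),
      phi, method = "recursive"))
    lat <- pmin(pmax(lat, -(geom$stem_halfwidth_cm - 1)),
                geom$stem_halfwidth_cm - 1)
    on_corridor <- abs(x) <= geom$stem_halfwidth_cm
    x[on_corridor] <- lat[on_corridor]
    list(x = x, y = y, trial = tri, turns = turns)
  })
  n_frames <- length(beh$x)
  frame_times <- seq(0, by = dt, length.out = n_frames)
  trace <- align_behavior_to_imaging(
    data.frame(time = frame_times, x = beh$x, y = beh$y),
    frame_times, geometry = geom)
  frame_turn <- beh$turns[beh$trial]

  act_mask <- attr(truth, "active")[, session_index]
  ids <- truth$neuron_id[act_mask]
  d_frames <- max(1L, round(config$transient_duration_s * fr))
  events <- matrix(0L, length(ids), n_frames)
  onsets <- matrix(0L, length(ids), n_frames)
  roi <- data.frame(neuron_id = ids, x_um = numeric(length(ids)),
                    y_um = numeric(length(ids)),
                    orientation_deg = numeric(length(ids)))
  for (j in seq_along(ids)) {
    info <- truth[truth$neuron_id == ids[j], ]
    with_rng(derive_seed(config$seed, session_index, ids[j]), {
      jit <- stats::rnorm(3L, 0, c(config$roi_jitter_um,
                                   config$roi_jitter_um, 3))
      roi$x_um[j] <- info$roi_x_um + jit[1L]
      roi$y_um[j] <- info$roi_y_um + jit[2L]
      roi$orientation_deg[j] <- (info$roi_orientation_deg + jit[3L]) %% 180
      rate <- neuron_rate(info, config, beh$x, beh$y, frame_turn,
                          session_index)
      on <- as.integer(stats::runif(n_frames) < pmin(rate * dt, 1))
      onsets[j, ] <- on
      if (any(on == 1L)) {
        act <- stats::filter(on, rep(1, d_frames), sides = 1)
        act[seq_len(min(d_frames - 1L, n_frames))] <-
          cumsum(on[seq_len(min(d_frames - 1L, n_frames))])
        events[j, ] <- as.integer(act > 0)
      }
    })
  }
  structure(list(
    behavior = trace,
    raster = event_raster(events, fr, frame_times, neuron_ids = ids,
                          session_id = sprintf("s%02d", session_index)),
    onsets = onsets,
    roi = structure(roi, class = c("roi_table", "data.frame")),
    turns = beh$turns,
    session_index = as.integer(session_index),
    day = config$session_days[session_index]
  ), class = "synth_session")
}

#' Generate a full multi-session synthetic experiment
#'
#' @param config a \code{\link{synth_config}}.
#' @return a \code{synth_experiment}: list of session bundles
#'   (\code{sessions}), the \code{truth} table, and the \code{config}.
#' @export
generate_experiment <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  truth <- make_ground_truth(config)
  sessions <- lapply(seq_len(config$n_sessions), function(s)
    generate_session(config, s, truth))
  structure(list(sessions = sessions, truth = truth, config = config),
            class = "synth_experiment")
}

#' @export
print.synth_experiment <- function(x, ...) {
  cat(sprintf("synth_experiment: %d neurons, %d sessions, %d trials/session\n",
              x$config$n_neurons, x$config$n_sessions, x$config$n_trials))
  print(table(x$truth$true_class))
  invisible(x)
}

#' Write a synthetic experiment to disk as text fixtures
#'
#' Emits one subdirectory per session in the delimited formats of
#' \code{\link{write_session_bundle}}, plus a ground-truth JSON; the
#' bundles round-trip losslessly through \code{\link{read_session_bundle}}.
#'
#' @param experiment a \code{synth_experiment}.
#' @param dir output directory.
#' @return data.frame manifest of emitted files.
#' @export
write_fixtures <- function(experiment, dir) {
  stopifnot(inherits(experiment, "synth_experiment"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("I/O failure: cannot create directory ", dir)
  manifest <- list()
  for (b in experiment$sessions) {
    sdir <- file.path(dir, sprintf("s%02d", b$session_index))
    files <- write_session_bundle(b, sdir)
    manifest[[length(manifest) + 1L]] <-
      data.frame(session = b$session_index, kind = names(files),
                 path = unname(files), stringsAsFactors = FALSE)
  }
  truth_path <- file.path(dir, "ground_truth.json")
  tr <- experiment$truth
  jsonlite::write_json(
    list(neurons = tr,
         active = apply(attr(tr, "active"), 1L, which, simplify = FALSE)),
    truth_path, auto_unbox = TRUE, digits = NA)
  manifest[[length(manifest) + 1L]] <-
    data.frame(session = NA_integer_, kind = "ground_truth",
               path = truth_path, stringsAsFactors = FALSE)
  do.call(rbind, manifest)
}
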