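#' Figure-8 maze geometry
#'
#' Describes the idealised figure-8 alternation maze in maze-aligned
#' centimetres. The maze is symmetric about the stem midline (x = 0): the
#' central stem runs from y = 0 to y = \code{stem_length_cm}, the base sits
#' below it, the choice area above it, and the two return arms run down the
#' outside at x = +/-(arm_inner..arm_outer). Section membership of a
#' position is decided by these rectangles (see
#' \code{\link{classify_sections}}).
#'
#' \code{stem_restrict} gives the fraction of the stem used for
#' trajectory-dependence analysis: trajectories diverge near the base and
#' the choice point, so tuning curves are computed on a central window only
#' (default the central 80 percent).
#'
#' @param stem_length_cm length of the central stem (cm).
#' @param stem_halfwidth_cm half-width of the stem corridor (cm).
#' @param base_depth_cm depth of the base section below the stem (cm).
#' @param choice_depth_cm depth of the choice section above the stem (cm).
#' @param arm_inner_cm,arm_outer_cm inner/outer x extent of the return arms.
#' @param stem_restrict length-2 numeric, fractional window of the stem
#'   retained for stem tuning-curve analysis.
#' @return an object of class \code{maze_geometry}.
#' @export
maze_geometry <- function(stem_length_cm = 64, stem_halfwidth_cm = 6,
                          base_depth_cm = 12, choice_depth_cm = 10,
                          arm_inner_cm = 24, arm_outer_cm = 36,
                          stem_restrict = c(0.1, 0.9)) {
  check_positive(stem_length_cm, "stem_length_cm")
  check_positive(stem_halfwidth_cm, "stem_halfwidth_cm")
  check_positive(base_depth_cm, "base_depth_cm")
  check_positive(choice_depth_cm, "choice_depth_cm")
  check_positive(arm_inner_cm, "arm_inner_cm")
  check_positive(arm_outer_cm, "arm_outer_cm")
  if (arm_outer_cm <= arm_inner_cm)
    stop_config("arm_outer_cm", "must exceed arm_inner_cm")
  if (arm_inner_cm <= stem_halfwidth_cm)
    stop_config("arm_inner_cm", "must exceed stem_halfwidth_cm")
  if (length(stem_restrict) != 2L || any(stem_restrict < 0) ||
      any(stem_restrict > 1) || stem_restrict[1] >= stem_restrict[2])
    stop_config("stem_restrict", "must be increasing fractions in [0, 1]")
  structure(list(
    stem_length_cm = stem_length_cm,
    stem_halfwidth_cm = stem_halfwidth_cm,
    base_depth_cm = base_depth_cm,
    choice_depth_cm = choice_depth_cm,
    arm_inner_cm = arm_inner_cm,
    arm_outer_cm = arm_outer_cm,
    stem_restrict = stem_restrict,
    stem_range = stem_restrict * stem_length_cm
  ), class = "maze_geometry")
}

MAZE_SECTIONS <- c("base", "stem", "choice", "entry", "return_arm",
                   "approach")

#' Classify maze positions into sections
#'
#' Maps maze-aligned (x, y) positions to the six maze sections
#' (base, stem, choice, entry, return_arm, approach); positions outside all
#' sections give NA.
#'
#' @param x,y numeric positions in maze cm.
#' @param geometry a \code{\link{maze_geometry}}.
#' @return character vector of section labels (NA outside the maze).
#' @export
classify_sections <- function(x, y, geometry) {
  stopifnot(inherits(geometry, "maze_geometry"))
  g <- geometry
  L <- g$stem_length_cm
  hw <- g$stem_halfwidth_cm
  out <- rep(NA_character_, length(x))
  ax <- abs(x)
  corridor <- ax <= hw
  out[corridor & y >= 0 & y < L] <- "stem"
  out[corridor & y >= -g$base_depth_cm & y < 0] <- "base"
  out[corridor & y >= L & y < L + g$choice_depth_cm] <- "choice"
  out[!corridor & ax <= g$arm_outer_cm & y >= L &
        y < L + g$choice_depth_cm] <- "entry"
  out[ax > g$arm_inner_cm & ax <= g$arm_outer_cm & y >= -g$base_depth_cm &
        y < L] <- "return_arm"
  out[ax > hw & ax <= g$arm_inner_cm & y >= -g$base_depth_cm &
        y < 0] <- "approach"
  out
}

#' Align behavioral tracking to imaging frames
#'
#' Interpolates raw position samples (time, x, y) at the imaging frame
#' times, synchronised on a common clock, and derives running speed by
#' finite differences. Frames outside the tracking time range are flagged
#' invalid (positions NA).
#'
#' @param raw_positions data.frame with columns \code{time}, \code{x},
#'   \code{y} (seconds / maze cm); need not be sampled at the frame rate.
#' @param frame_times numeric vector of imaging frame times (s), strictly
#'   increasing.
#' @param geometry optional \code{\link{maze_geometry}}; when supplied the
#'   trace is annotated with section labels and stem-lateral position.
#' @param smooth_frames odd integer; width of an optional boxcar applied to
#'   speed (1 = no smoothing).
#' @return a \code{behavior_trace} data.frame with one row per imaging
#'   frame: time, x, y, speed, valid, and (if geometry was given) section
#'   and lateral.
#' @export
align_behavior_to_imaging <- function(raw_positions, frame_times,
                                      geometry = NULL, smooth_frames = 1L) {
  need <- c("time", "x", "y")
  if (!all(need %in% names(raw_positions)))
    stop("raw_positions must have columns time, x, y")
  rt <- raw_positions$time
  if (is.unsorted(rt, strictly = TRUE))
    stop("raw position times must be strictly increasing")
  if (is.unsorted(frame_times, strictly = TRUE))
    stop("frame_times must be strictly increasing")
  if (min(rt) > max(frame_times) || max(rt) < min(frame_times))
    stop("alignment error: tracking and imaging time ranges do not overlap")
  x <- stats::approx(rt, raw_positions$x, xout = frame_times, rule = 1)$y
  y <- stats::approx(rt, raw_positions$y, xout = frame_times, rule = 1)$y
  valid <- !is.na(x) & !is.na(y)
  n <- length(frame_times)
  speed <- rep(0, n)
  if (n > 1L) {
    step <- sqrt(diff(x)^2 + diff(y)^2) / diff(frame_times)
    speed[-1L] <- step
    speed[1L] <- step[1L]
    speed[is.na(speed)] <- 0
    if (smooth_frames > 1L) {
      k <- rep(1 / smooth_frames, smooth_frames)
      sm <- stats::filter(speed, k, sides = 2)
      speed <- ifelse(is.na(sm), speed, as.numeric(sm))
    }
  }
  trace <- data.frame(time = frame_times, x = x, y = y, speed = speed,
                      valid = valid)
  if (!is.null(geometry)) {
    trace$section <- classify_sections(x, y, geometry)
    trace$lateral <- x      # signed offset from the stem midline (x = 0)
  } else {
    trace$section <- NA_character_
    trace$lateral <- x
  }
  class(trace) <- c("behavior_trace", "data.frame")
  attr(trace, "frame_rate_hz") <-
    if (n > 1L) 1 / stats::median(diff(frame_times)) else NA_real_
  trace
}

#' Parse a behavior trace into alternation trials
#'
#' A trial is one full traversal base -> stem -> choice -> entry ->
#' return_arm -> approach. Turn direction is taken from the side of the
#' entry section; the correct flag follows the continuous-alternation rule
#' (a trial is correct iff its turn differs from the previous trial's; the
#' first free trial is correct by convention). Incomplete traversals are
#' dropped and counted in \code{attr(, "n_dropped")}. Forced trials keep
#' their position in the alternation sequence but are flagged so downstream
#' selectors can exclude them.
#'
#' @param trace a \code{behavior_trace} with section annotations.
#' @param geometry the \code{\link{maze_geometry}} used to annotate it.
#' @param forced_trials integer indices (in parsed-trial order) of trials
#'   that were experimenter-forced.
#' @return a \code{trial_table} data.frame: trial, turn, correct, forced,
#'   start/end frame and per-section frame spans (1-based, inclusive).
#' @export
parse_trials <- function(trace, geometry, forced_trials = integer(0)) {
  stopifnot(inherits(trace, "behavior_trace"))
  if (!inherits(geometry, "maze_geometry"))
    stop_config("geometry", "must be a maze_geometry object")
  sec <- trace$section
  if (all(is.na(sec)))
    stop("trace has no section annotations; align with a geometry first")
  secf <- ifelse(is.na(sec), "none", sec)
  r <- rle(secf)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  vals <- r$values
  nrun <- length(vals)

  order_after <- c("choice", "entry", "return_arm", "approach")
  rows <- list()
  n_dropped <- 0L
  i <- 1L
  while (i <= nrun) {
    if (vals[i] == "stem" && i > 1L && vals[i - 1L] == "base") {
      # candidate trial anchored at this stem run
      span <- list(base = c(starts[i - 1L], ends[i - 1L]),
                   stem = c(starts[i], ends[i]))
      j <- i + 1L
      ok <- TRUE
      for (sect in order_after) {
        while (j <= nrun && vals[j] == "none") j <- j + 1L
        if (j > nrun || vals[j] != sect) { ok <- FALSE; break }
        span[[sect]] <- c(starts[j], ends[j])
        j <- j + 1L
      }
      if (ok) {
        ent <- span$entry
        turn <- if (mean(trace$x[ent[1]:ent[2]]) < 0) "left" else "right"
        rows[[length(rows) + 1L]] <- data.frame(
          turn = turn,
          start_frame = span$base[1], end_frame = span$approach[2],
          base_start = span$base[1], base_end = span$base[2],
          stem_start = span$stem[1], stem_end = span$stem[2],
          choice_start = span$choice[1], choice_end = span$choice[2],
          entry_start = span$entry[1], entry_end = span$entry[2],
          return_start = span$return_arm[1], return_end = span$return_arm[2],
          approach_start = span$approach[1], approach_end = span$approach[2],
          stringsAsFactors = FALSE)
        i <- j - 1L            # resume at the run after this approach
        next
      } else {
        n_dropped <- n_dropped + 1L
      }
    }
    i <- i + 1L
  }
  if (length(rows) == 0L) {
    tt <- data.frame(trial = integer(0), turn = character(0),
                     correct = logical(0), forced = logical(0))
  } else {
    tt <- do.call(rbind, rows)
    tt$trial <- seq_len(nrow(tt))
    tt$forced <- tt$trial %in% forced_trials
    tt$correct <- c(TRUE, tt$turn[-1L] != tt$turn[-nrow(tt)])
    tt <- tt[, c("trial", "turn", "correct", "forced",
                 setdiff(names(tt), c("trial", "turn", "correct", "forced")))]
  }
  class(tt) <- c("trial_table", "data.frame")
  attr(tt, "n_dropped") <- n_dropped
  tt
}

#' Session behavioral performance
#'
#' Fraction of free (non-forced) trials performed correctly.
#'
#' @param trials a \code{trial_table}.
#' @return numeric in [0, 1].
#' @export
session_performance <- function(trials) {
  free <- !trials$forced
  if (sum(free) < 1L)
    stop("undefined performance: session has no free trials")
  mean(trials$correct[free])
}

#' Task acquisition session
#'
#' The acquisition session is the third consecutive session at or above the
#' performance criterion (default 70 percent correct).
#'
#' @param performances numeric vector of per-session performance, in
#'   session order.
#' @param criterion performance criterion (default 0.70).
#' @param run_length number of consecutive criterion sessions required.
#' @return index of the acquisition session, or NA if never reached.
#' @export
acquisition_session <- function(performances, criterion = 0.70,
                                run_length = 3L) {
  ok <- performances >= criterion
  if (length(ok) < run_length) return(NA_integer_)
  for (i in seq(run_length, length(ok))) {
    if (all(ok[(i - run_length + 1L):i])) return(i)
  }
  NA_integer_
}
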