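# Session-level classification pipeline: ties the behavior, splitter and
# place-cell modules together and produces the per-neuron functional
# labels that the longitudinal and ontogeny analyses consume.

#' Classify every neuron of one session
#'
#' Runs trial parsing, the splitter permutation analysis, the
#' spatial-information place-cell test, the activity filter, and the
#' functional label assignment for one session.
#'
#' @param raster an \code{\link{event_raster}}.
#' @param trace the session's section-annotated \code{behavior_trace}.
#' @param geometry a \code{\link{maze_geometry}}.
#' @param trials optional pre-parsed \code{trial_table} (parsed from the
#'   trace otherwise).
#' @param n_shuffles shuffles for both the splitter permutation test and
#'   the SI shuffle test (default 1000).
#' @param seed RNG seed.
#' @param min_active_events minimum transients for a neuron to count as
#'   active (default 4).
#' @param anova_confirm run the splitter ANOVA covariate check (default
#'   TRUE).
#' @param speed_min_cms running-speed threshold for spatial analyses.
#' @return a \code{session_classification} data.frame, one row per
#'   neuron: event counts, rates, splitter metrics and flags, SI and
#'   place flag, stem activity, functional \code{label} (NA for neurons
#'   failing the activity filter); the underlying \code{splitter_result}
#'   and trial table ride along as attributes.
#' @export
classify_session <- function(raster, trace, geometry = maze_geometry(),
                             trials = NULL, n_shuffles = 1000L, seed = 1L,
                             min_active_events = 4L, anova_confirm = TRUE,
                             speed_min_cms = 1) {
  if (is.null(trials)) trials <- parse_trials(trace, geometry)
  spl <- splitter_analysis(raster, trace, trials, geometry,
                           n_shuffles = n_shuffles, seed = seed,
                           anova_confirm = anova_confirm)
  n_events <- count_events(raster)
  running <- trace$speed > speed_min_cms
  run_minutes <- sum(running) / raster$frame_rate_hz / 60
  run_events <- count_events(raster$events[, running, drop = FALSE])
  stem_frames <- which(trace$section == "stem")
  stem_active <- rowSums(
    raster$events[, stem_frames, drop = FALSE]) > 0
  n_neurons <- nrow(raster$events)
  si <- rep(NA_real_, n_neurons)
  is_pc <- rep(FALSE, n_neurons)
  for (n in seq_len(n_neurons)) {
    pc <- place_cell_test(raster$events[n, ], trace,
                          n_shuffles = n_shuffles,
                          seed = derive_seed(seed, 1L, n),
                          speed_min_cms = speed_min_cms)
    si[n] <- pc$SI
    is_pc[n] <- pc$is_place_cell
  }
  active <- n_events >= min_active_events
  out <- data.frame(
    neuron = raster$neuron_ids,
    n_events = n_events,
    n_running_events = run_events,
    event_rate_per_min = run_events / max(run_minutes, 1e-9),
    active = active,
    stem_active = stem_active,
    is_splitter = spl$is_splitter,
    splitting_extent = spl$splitting_extent,
    discriminability = spl$discriminability,
    reliability_mean = spl$reliability_mean,
    reliability_peak = spl$reliability_peak,
    one_minus_rho = spl$one_minus_rho,
    SI = si,
    is_place_cell = is_pc)
  lab <- assign_coding_labels(out$is_splitter, out$is_place_cell,
                              out$stem_active)
  lab[!active] <- NA
  out$label <- lab
  attr(out, "splitter_result") <- spl
  attr(out, "trials") <- trials
  class(out) <- c("session_classification", "data.frame")
  out
}

#' @export
summary.session_classification <- function(object, ...) {
  cat(sprintf("session_classification: %d neurons (%d active)\n",
              nrow(object), sum(object$active)))
  print(table(object$label, useNA = "ifany"))
  invisible(object)
}
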