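#' Calcium event raster
#'
#' Binary neuron-by-frame indicator of inferred spiking activity. A
#' calcium transient is marked on every frame of its rising phase, so one
#' transient typically spans several consecutive frames; transient counts
#' are recovered from rising edges (\code{\link{count_events}}).
#'
#' @param events neuron x frame matrix of 0/1 indicators.
#' @param frame_rate_hz imaging frame rate (Hz).
#' @param frame_times frame timestamps (s); defaults to a regular grid at
#'   the frame rate starting at 0.
#' @param neuron_ids identifiers for the rows (default 1..n).
#' @param session_id optional session identifier.
#' @return an \code{event_raster} object.
#' @export
event_raster <- function(events, frame_rate_hz, frame_times = NULL,
                         neuron_ids = NULL, session_id = NA_character_) {
  events <- as.matrix(events)
  storage.mode(events) <- "integer"
  if (nrow(events) > 0 && !all(events %in% c(0L, 1L)))
    stop("format error: event raster values must be 0 or 1")
  check_positive(frame_rate_hz, "frame_rate_hz")
  n_frames <- ncol(events)
  if (is.null(frame_times))
    frame_times <- seq(0, length.out = n_frames, by = 1 / frame_rate_hz)
  if (length(frame_times) != n_frames)
    stop("format error: frame_times length must equal number of frames")
  if (n_frames > 1L && is.unsorted(frame_times, strictly = TRUE))
    stop("format error: frame times must be strictly increasing")
  if (is.null(neuron_ids)) neuron_ids <- seq_len(nrow(events))
  if (length(neuron_ids) != nrow(events))
    stop("format error: neuron_ids length must equal number of neurons")
  structure(list(events = events, frame_rate_hz = frame_rate_hz,
                 frame_times = as.numeric(frame_times),
                 neuron_ids = neuron_ids, session_id = session_id),
            class = "event_raster")
}

#' @export
print.event_raster <- function(x, ...) {
  cat(sprintf("event_raster: %d neurons x %d frames @ %.1f Hz (%.1f s)\n",
              nrow(x$events), ncol(x$events), x$frame_rate_hz,
              ncol(x$events) / x$frame_rate_hz))
  invisible(x)
}

#' Count calcium transients per neuron
#'
#' Counts rising edges of the binary activity raster, i.e. distinct
#' calcium transients (overlapping transients merge into one edge).
#'
#' @param raster an \code{\link{event_raster}} or a 0/1 matrix/vector.
#' @return integer vector, one count per neuron.
#' @export
count_events <- function(raster) {
  ev <- if (inherits(raster, "event_raster")) raster$events else
    rbind(raster)
  if (ncol(ev) == 0L) return(integer(nrow(ev)))
  rises <- ev[, -1L, drop = FALSE] == 1L & ev[, -ncol(ev), drop = FALSE] == 0L
  as.integer(ev[, 1L] + rowSums(rises))
}

#' Active-neuron filter
#'
#' A neuron must produce at least \code{min_events} calcium events in a
#' session to be considered active (default 4).
#'
#' @param raster an \code{\link{event_raster}}.
#' @param min_events minimum transient count.
#' @return logical vector (named by neuron id): active on this session.
#' @export
neuron_activity_filter <- function(raster, min_events = 4L) {
  n <- count_events(raster)
  stats::setNames(n >= min_events, raster$neuron_ids)
}

#' Fit the half-decay time of a calcium transient
#'
#' Least-squares single-exponential fit \eqn{y = a e^{-bt}} to the decaying
#' portion of a transient (segment starting at the transient peak); the
#' half-life is \eqn{\ln 2 / b}.
#'
#' @param time,fluor numeric vectors: timestamps (s) and fluorescence of
#'   the decay segment, beginning at the peak.
#' @return half-life in seconds, or NA if the segment is not fittable
#'   (fewer than 5 samples, or non-decaying).
#' @export
fit_transient_half_life <- function(time, fluor) {
  if (length(time) < 5L || length(fluor) != length(time)) return(NA_real_)
  t0 <- time - time[1L]
  pos <- fluor > 0
  if (sum(pos) < 5L) return(NA_real_)
  # log-linear start values, refined by nonlinear least squares
  lf <- stats::lm(log(fluor[pos]) ~ t0[pos])
  b0 <- -unname(stats::coef(lf)[2L])
  if (!is.finite(b0) || b0 <= 0) return(NA_real_)
  a0 <- exp(unname(stats::coef(lf)[1L]))
  fit <- tryCatch(
    suppressWarnings(
      stats::nls(fluor ~ a * exp(-b * t0), start = list(a = a0, b = b0),
                 control = stats::nls.control(warnOnly = TRUE))),
    error = function(e) NULL)
  b <- if (is.null(fit)) b0 else unname(stats::coef(fit)["b"])
  if (!is.finite(b) || b <= 0) return(NA_real_)
  log(2) / b
}

#' Calcium-trace quality control
#'
#' Estimates each neuron's transient half-decay time from the last
#' recorded transient and excludes neurons with half-decay > 2 s
#' (potentially unhealthy cells). A fitted half-life above
#' \code{retry_threshold_s} (default 7 s) is taken as contamination by a
#' neighbouring neuron's fluorescence, and the fit is retried on the
#' previous transient, iterating backwards; a neuron with no fittable
#' transient is excluded as unfittable.
#'
#' @param fluor numeric fluorescence trace for one neuron.
#' @param time frame timestamps (s).
#' @param onset_frames frame indices (1-based) of transient onsets, in
#'   increasing order.
#' @param max_half_decay_s exclusion threshold (s).
#' @param retry_threshold_s contamination threshold triggering a retry on
#'   the previous transient (s).
#' @return list with \code{half_decay_s}, \code{excluded},
#'   \code{exclusion_reason} (NA when kept).
#' @export
trace_qc <- function(fluor, time, onset_frames, max_half_decay_s = 2,
                     retry_threshold_s = 7) {
  onset_frames <- sort(onset_frames)
  k <- length(onset_frames)
  if (k == 0L)
    return(list(half_decay_s = NA_real_, excluded = TRUE,
                exclusion_reason = "no transients"))
  n <- length(fluor)
  half <- NA_real_
  for (idx in rev(seq_len(k))) {
    seg_start <- onset_frames[idx]
    seg_end <- if (idx < k) onset_frames[idx + 1L] - 1L else n
    seg <- seg_start:seg_end
    if (length(seg) < 5L) next
    peak <- seg[which.max(fluor[seg])]
    if (peak >= seg_end) next
    h <- fit_transient_half_life(time[peak:seg_end], fluor[peak:seg_end])
    if (is.na(h)) next
    if (h > retry_threshold_s) next   # contaminated: use previous transient
    half <- h
    break
  }
  if (is.na(half))
    return(list(half_decay_s = NA_real_, excluded = TRUE,
                exclusion_reason = "unfittable"))
  list(half_decay_s = half, excluded = half > max_half_decay_s,
       exclusion_reason = if (half > max_half_decay_s)
         sprintf("half-decay %.2f s > %g s", half, max_half_decay_s)
       else NA_character_)
}

#' Synthesize a fluorescence trace from transient onsets
#'
#' Builds an idealised calcium trace — linear rise over a few frames
#' followed by exponential decay with the requested half-life — used as a
#' fixture for half-decay quality-control fitting. Synthetic by
#' construction; it models no indicator biophysics beyond the decay shape.
#'
#' @param onset_frames 1-based frame indices of transient onsets.
#' @param n_frames trace length in frames.
#' @param frame_rate_hz frame rate (Hz).
#' @param half_decay_s decay half-life (s).
#' @param amplitude transient peak amplitude.
#' @param rise_frames frames of linear rise to peak.
#' @param noise_sd Gaussian noise s.d. added to the trace.
#' @return numeric fluorescence vector of length \code{n_frames}.
#' @export
simulate_calcium_trace <- function(onset_frames, n_frames, frame_rate_hz = 20,
                                   half_decay_s = 0.5, amplitude = 1,
                                   rise_frames = 2L, noise_sd = 0) {
  lambda <- log(2) / half_decay_s
  t <- seq(0, by = 1 / frame_rate_hz, length.out = n_frames)
  kern_len <- min(n_frames, rise_frames + ceiling(6 * half_decay_s *
                                                    frame_rate_hz))
  kt <- seq_len(kern_len) - 1
  kern <- ifelse(kt < rise_frames, amplitude * (kt + 1) / rise_frames,
                 amplitude * exp(-lambda * (kt - rise_frames + 1) /
                                   frame_rate_hz))
  y <- numeric(n_frames)
  for (f in onset_frames) {
    idx <- f:min(n_frames, f + kern_len - 1L)
    y[idx] <- y[idx] + kern[seq_along(idx)]
  }
  if (noise_sd > 0) y <- y + stats::rnorm(n_frames, 0, noise_sd)
  y
}

# ---------------------------------------------------------------------------
# Session bundle file formats (all plain delimited text + JSON sidecars).
#
# Dialect: 0-based frame indices in files (converted to R's 1-based on
# read); times in seconds; coordinates in maze cm; ROI centroids in um;
# orientations in degrees mod 180. Rasters are sparse long format
# (neuron_id, frame) listing active frames only, with a JSON sidecar
# giving the frame rate, frame count and the full neuron id list (so
# silent neurons survive the round trip).
# ---------------------------------------------------------------------------

fmt_num <- function(x) formatC(x, format = "g", digits = 12)

#' Write a session bundle to delimited text files
#'
#' @param bundle list with elements \code{raster} (an
#'   \code{\link{event_raster}}), \code{behavior} (data.frame with time, x,
#'   y) and \code{roi} (data.frame neuron_id, x_um, y_um, orientation_deg).
#' @param dir output directory (created if needed).
#' @return named character vector of file paths (the manifest).
#' @export
write_session_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("I/O failure: cannot create directory ", dir)
  beh_path <- file.path(dir, "behavior.csv")
  ras_path <- file.path(dir, "raster.csv")
  meta_path <- file.path(dir, "raster.json")
  roi_path <- file.path(dir, "roi.csv")

  beh <- bundle$behavior
  utils::write.table(
    data.frame(time = fmt_num(beh$time), x = fmt_num(beh$x),
               y = fmt_num(beh$y)),
    beh_path, sep = ",", row.names = FALSE, quote = FALSE)

  ras <- bundle$raster
  idx <- which(ras$events == 1L, arr.ind = TRUE)
  ord <- order(idx[, 1L], idx[, 2L])
  idx <- idx[ord, , drop = FALSE]
  utils::write.table(
    data.frame(neuron_id = ras$neuron_ids[idx[, 1L]],
               frame = idx[, 2L] - 1L, value = rep(1L, nrow(idx))),
    ras_path, sep = ",", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(frame_rate_hz = ras$frame_rate_hz, n_frames = ncol(ras$events),
         t0 = if (length(ras$frame_times)) ras$frame_times[1L] else 0,
         session_id = ras$session_id, neuron_ids = ras$neuron_ids),
    meta_path, auto_unbox = TRUE, digits = NA)

  roi <- bundle$roi
  utils::write.table(
    data.frame(neuron_id = roi$neuron_id, x_um = fmt_num(roi$x_um),
               y_um = fmt_num(roi$y_um),
               orientation_deg = fmt_num(roi$orientation_deg)),
    roi_path, sep = ",", row.names = FALSE, quote = FALSE)

  c(behavior = beh_path, raster = ras_path, raster_meta = meta_path,
    roi = roi_path)
}

read_checked_csv <- function(path, required) {
  if (!file.exists(path)) stop("I/O failure: missing file ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(d))
  if (length(miss))
    stop(sprintf("format error in %s: missing column(s) %s", path,
                 paste(miss, collapse = ", ")))
  d
}

#' Read a session bundle written by \code{\link{write_session_bundle}}
#'
#' Validates the documented dialects (monotone times, binary event values)
#' and reports schema violations with the offending file and row.
#'
#' @param dir directory containing behavior.csv, raster.csv, raster.json,
#'   roi.csv.
#' @return list with \code{behavior} (raw time/x/y data.frame),
#'   \code{raster} (\code{\link{event_raster}}) and \code{roi} data.frame.
#' @export
read_session_bundle <- function(dir) {
  beh <- read_checked_csv(file.path(dir, "behavior.csv"), c("time", "x", "y"))
  if (nrow(beh) > 1L && is.unsorted(beh$time, strictly = TRUE))
    stop(sprintf("format error in %s: time not strictly increasing",
                 file.path(dir, "behavior.csv")))
  meta <- jsonlite::read_json(file.path(dir, "raster.json"),
                              simplifyVector = TRUE)
  ras <- read_checked_csv(file.path(dir, "raster.csv"),
                          c("neuron_id", "frame", "value"))
  bad <- which(!(ras$value %in% c(0L, 1L)))
  if (length(bad))
    stop(sprintf("format error in %s: non-binary event value at row %d",
                 file.path(dir, "raster.csv"), bad[1L]))
  bad <- which(ras$frame < 0L | ras$frame >= meta$n_frames)
  if (length(bad))
    stop(sprintf("format error in %s: frame index out of range at row %d",
                 file.path(dir, "raster.csv"), bad[1L]))
  ids <- meta$neuron_ids
  ev <- matrix(0L, nrow = length(ids), ncol = meta$n_frames)
  if (nrow(ras)) {
    ri <- match(ras$neuron_id, ids)
    if (anyNA(ri))
      stop(sprintf("format error in %s: neuron_id not in sidecar at row %d",
                   file.path(dir, "raster.csv"), which(is.na(ri))[1L]))
    ev[cbind(ri[ras$value == 1L], ras$frame[ras$value == 1L] + 1L)] <- 1L
  }
  frame_times <- (meta$t0 %||% 0) +
    seq(0, length.out = meta$n_frames, by = 1 / meta$frame_rate_hz)
  roi <- read_checked_csv(file.path(dir, "roi.csv"),
                          c("neuron_id", "x_um", "y_um", "orientation_deg"))
  list(behavior = beh,
       raster = event_raster(ev, meta$frame_rate_hz, frame_times,
                             neuron_ids = ids,
                             session_id = meta$session_id %||% NA_character_),
       roi = roi)
}
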