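# Place-cell identification from spatial mutual information.
#
# Calcium activity is binned on a 2D spatial grid (4 cm for the
# information calculation, 1 cm for smoothed maps), restricted to frames
# on which the animal moved faster than 1 cm/s. The spatial information
#
#   I_pos(x_i) = sum_{k in {0,1}} P(k|x_i) log2( P(k|x_i) / P_k )
#   SI         = sum_i P(x_i) I_pos(x_i)
#
# is the mutual information (bits) between the binary per-frame event
# indicator and the binned position.

#' Spatial occupancy / event-probability map
#'
#' @param events 0/1 activity vector for one neuron (one entry per frame),
#'   or an \code{\link{event_raster}} together with \code{neuron}.
#' @param trace the session \code{behavior_trace}.
#' @param neuron neuron id when \code{events} is a raster.
#' @param bin_cm square bin size (default 4 cm).
#' @param speed_min_cms minimum running speed; slower frames are excluded
#'   from both occupancy and events (default 1 cm/s).
#' @return a \code{spatial_map}: occupancy probability \code{P_x}, the
#'   conditional event probability \code{P_k1_given_x}, the marginal
#'   \code{P_1}, per-bin frame and event counts, occupancy seconds, and
#'   the occupied-bin mask (all matrices x-bin by y-bin).
#' @export
spatial_event_map <- function(events, trace, neuron = NULL, bin_cm = 4,
                              speed_min_cms = 1) {
  ev <- extract_event_vector(events, neuron)
  grid <- spatial_grid(trace, bin_cm, speed_min_cms)
  if (length(grid$frames) == 0L)
    stop("empty map: no frames above the speed threshold")
  nb <- grid$n_xbins * grid$n_ybins
  frame_count <- matrix(tabulate(grid$bin_index, nb), grid$n_xbins)
  event_count <- matrix(
    tabulate(grid$bin_index[ev[grid$frames] == 1L], nb), grid$n_xbins)
  occupied <- frame_count > 0L
  p_x <- frame_count / sum(frame_count)
  p_k1 <- matrix(NA_real_, grid$n_xbins, grid$n_ybins)
  p_k1[occupied] <- event_count[occupied] / frame_count[occupied]
  structure(list(
    bin_cm = bin_cm, x_edges = grid$x_edges, y_edges = grid$y_edges,
    P_x = p_x, P_k1_given_x = p_k1,
    P_1 = sum(p_x[occupied] * p_k1[occupied]),
    frame_count = frame_count, event_count = event_count,
    occupancy_s = frame_count / attr(trace, "frame_rate_hz"),
    occupied = occupied, n_frames = length(grid$frames)
  ), class = "spatial_map")
}

extract_event_vector <- function(events, neuron) {
  if (inherits(events, "event_raster")) {
    if (is.null(neuron)) stop("supply a neuron id with an event_raster")
    n <- match(neuron, events$neuron_ids)
    if (is.na(n)) stop("neuron ", neuron, " not present in raster")
    events$events[n, ]
  } else as.integer(events)
}

# Speed-filtered frame selection and 2D bin index for a trace.
spatial_grid <- function(trace, bin_cm, speed_min_cms) {
  ok <- which(trace$valid & trace$speed > speed_min_cms)
  x <- trace$x[ok]; y <- trace$y[ok]
  x0 <- floor(min(trace$x, na.rm = TRUE))
  y0 <- floor(min(trace$y, na.rm = TRUE))
  n_xbins <- floor((max(trace$x, na.rm = TRUE) - x0) / bin_cm) + 1L
  n_ybins <- floor((max(trace$y, na.rm = TRUE) - y0) / bin_cm) + 1L
  xi <- pmin(pmax(floor((x - x0) / bin_cm) + 1L, 1L), n_xbins)
  yi <- pmin(pmax(floor((y - y0) / bin_cm) + 1L, 1L), n_ybins)
  list(frames = ok, bin_index = xi + (yi - 1L) * n_xbins,
       n_xbins = n_xbins, n_ybins = n_ybins,
       x_edges = x0 + (0:n_xbins) * bin_cm,
       y_edges = y0 + (0:n_ybins) * bin_cm)
}

#' Spatial information of a map (bits)
#'
#' Mutual information between the binary event indicator and binned
#' position; \eqn{0 \log(0/\cdot)} terms are defined as 0. Always >= 0 and
#' 0 exactly when the conditional event probability is bin-independent.
#'
#' @param map a \code{\link{spatial_event_map}} result.
#' @return spatial information in bits.
#' @export
spatial_information <- function(map) {
  occ <- map$occupied
  si_terms(map$P_x[occ], map$P_k1_given_x[occ])
}

# SI from occupancy probabilities and conditional event probabilities.
si_terms <- function(p_x, p_k1) {
  p1 <- sum(p_x * p_k1)
  if (p1 <= 0 || p1 >= 1) return(0)
  xlogx <- function(p, q) ifelse(p > 0, p * log2(p / q), 0)
  sum(p_x * (xlogx(p_k1, p1) + xlogx(1 - p_k1, 1 - p1)))
}

#' Shuffle-based place-cell test
#'
#' The neuron's spatial information is compared to a null distribution
#' obtained by shuffling its calcium event timestamps relative to
#' position: by default each shuffle circularly shifts the whole activity
#' train by a uniform random offset (preserving event count and
#' inter-event structure); \code{method = "permute"} instead scatters the
#' event frames uniformly over the included frames. A neuron is a place
#' cell when it has at least \code{min_transients} transients and its real
#' SI strictly exceeds more than 95 percent of the shuffled SIs (ties
#' count against classification, keeping the level at or below 5
#' percent).
#'
#' @inheritParams spatial_event_map
#' @param n_shuffles number of shuffles (default 1000).
#' @param seed RNG seed.
#' @param method "circular" (default) or "permute".
#' @param min_transients minimum transient count (default 5).
#' @return a \code{spatial_info_result}: \code{SI}, \code{shuffle_SIs},
#'   \code{p_rank} (proportion of shuffles >= real SI),
#'   \code{is_place_cell}, \code{n_transients}, \code{reason}.
#' @export
place_cell_test <- function(events, trace, neuron = NULL, n_shuffles = 1000L,
                            seed = 1L, bin_cm = 4, speed_min_cms = 1,
                            method = c("circular", "permute"),
                            min_transients = 5L) {
  method <- match.arg(method)
  ev <- extract_event_vector(events, neuron)
  n_transients <- count_events(matrix(ev, nrow = 1L))
  grid <- spatial_grid(trace, bin_cm, speed_min_cms)
  if (length(grid$frames) == 0L)
    stop("empty map: no frames above the speed threshold")
  nb <- grid$n_xbins * grid$n_ybins
  n_total <- length(ev)
  # bin index over all frames; 0 marks excluded frames (tabulate drops 0)
  bin_full <- integer(n_total)
  bin_full[grid$frames] <- grid$bin_index
  frame_count <- tabulate(grid$bin_index, nb)
  occ <- frame_count > 0L
  p_x <- frame_count[occ] / sum(frame_count)
  fc_occ <- frame_count[occ]
  occ_index <- integer(nb); occ_index[occ] <- seq_len(sum(occ))
  si_of <- function(event_frames) {
    cnt <- tabulate(bin_full[event_frames], nb)[occ]
    si_terms(p_x, cnt / fc_occ)
  }
  ev_frames <- which(ev == 1L)
  real <- si_of(ev_frames)
  shuffle <- with_rng(seed, {
    vapply(seq_len(n_shuffles), function(s) {
      if (method == "circular") {
        off <- sample.int(n_total - 1L, 1L)
        si_of(((ev_frames - 1L + off) %% n_total) + 1L)
      } else {
        si_of(sample(grid$frames, min(length(ev_frames),
                                      length(grid$frames))))
      }
    }, numeric(1))
  })
  enough <- n_transients >= min_transients
  passes <- sum(real > shuffle) > 0.95 * n_shuffles
  structure(list(
    SI = real, shuffle_SIs = shuffle,
    p_rank = mean(shuffle >= real),
    n_transients = n_transients,
    is_place_cell = enough && passes,
    reason = if (!enough) sprintf("only %d transients (< %d)", n_transients,
                                  min_transients) else NA_character_
  ), class = "spatial_info_result")
}

#' @export
print.spatial_info_result <- function(x, ...) {
  cat(sprintf(
    "spatial_info_result: SI = %.4f bits, shuffle rank p = %.3f, %d transients -> %s\n",
    x$SI, x$p_rank, x$n_transients,
    if (x$is_place_cell) "place cell" else "not a place cell"))
  invisible(x)
}

#' Smoothed occupancy-normalised rate map
#'
#' Event rate per bin (events per second of occupancy) on a fine grid
#' (default 1 cm), convolved with a Gaussian kernel (default sigma =
#' 2.5 cm). Unvisited bins are treated as zero during convolution and
#' masked NA afterwards; correlations between maps must use bins visited
#' in both.
#'
#' @inheritParams spatial_event_map
#' @param sigma_cm Gaussian smoothing s.d. in cm (0 disables smoothing).
#' @return a \code{smoothed_map}: \code{rate} (smoothed matrix, NA where
#'   unvisited), \code{visited}, \code{raw_rate}, bin edges.
#' @export
smoothed_rate_map <- function(events, trace, neuron = NULL, bin_cm = 1,
                              sigma_cm = 2.5, speed_min_cms = 1) {
  m <- spatial_event_map(events, trace, neuron, bin_cm, speed_min_cms)
  raw <- matrix(0, nrow(m$frame_count), ncol(m$frame_count))
  raw[m$occupied] <- m$event_count[m$occupied] / m$occupancy_s[m$occupied]
  sm <- gaussian_smooth_2d(raw, sigma_cm / bin_cm)
  sm[!m$occupied] <- NA_real_
  structure(list(rate = sm, raw_rate = ifelse(m$occupied, raw, NA_real_),
                 visited = m$occupied, bin_cm = bin_cm,
                 x_edges = m$x_edges, y_edges = m$y_edges,
                 sigma_cm = sigma_cm),
            class = "smoothed_map")
}

# Separable Gaussian convolution with boundary renormalisation: the
# kernel is re-normalised over the in-range support at every position,
# so edges are smoothed without leaking rate mass off the grid.
gaussian_smooth_2d <- function(mat, sigma_bins) {
  if (sigma_bins <= 1e-9) return(mat)
  r <- max(1L, ceiling(3 * sigma_bins))
  k <- stats::dnorm(-r:r, sd = sigma_bins)
  k <- k / sum(k)
  smooth_axis <- function(m, along_rows) {
    out <- matrix(0, nrow(m), ncol(m))
    wsum <- matrix(0, nrow(m), ncol(m))
    n <- if (along_rows) nrow(m) else ncol(m)
    for (d in -r:r) {
      w <- k[d + r + 1L]
      src <- seq_len(n) - d
      okk <- src >= 1L & src <= n
      if (along_rows) {
        out[okk, ] <- out[okk, ] + w * m[src[okk], ]
        wsum[okk, ] <- wsum[okk, ] + w
      } else {
        out[, okk] <- out[, okk] + w * m[, src[okk]]
        wsum[, okk] <- wsum[, okk] + w
      }
    }
    out / wsum
  }
  smooth_axis(smooth_axis(mat, TRUE), FALSE)
}

#' Extract the place field of a smoothed rate map
#'
#' The field is the 4-connected component of bins whose smoothed rate
#' exceeds 50 percent of the peak rate, containing the peak bin. Field
#' length is the field area divided by the 5 cm effective corridor width.
#'
#' @param smap a \code{\link{smoothed_rate_map}} result.
#' @param threshold_frac rate threshold as a fraction of peak (default
#'   0.5).
#' @param corridor_cm effective corridor width used to convert area to
#'   length (default 5 cm).
#' @return a \code{place_field}: logical \code{field_mask},
#'   \code{field_area_cm2}, \code{field_length_cm}, \code{peak_rate},
#'   \code{has_field}.
#' @export
extract_place_field <- function(smap, threshold_frac = 0.5,
                                corridor_cm = 5) {
  rate <- smap$rate
  peak <- suppressWarnings(max(rate, na.rm = TRUE))
  if (!is.finite(peak) || peak <= 0)
    return(structure(list(field_mask = matrix(FALSE, nrow(rate), ncol(rate)),
                          field_area_cm2 = 0,
                          field_length_cm = NA_real_, peak_rate = NA_real_,
                          has_field = FALSE), class = "place_field"))
  peak_idx <- which(rate == peak, arr.ind = TRUE)[1L, ]
  above <- !is.na(rate) & rate > threshold_frac * peak
  # flood fill (4-neighbour) from the peak bin
  mask <- matrix(FALSE, nrow(rate), ncol(rate))
  stack <- list(peak_idx)
  while (length(stack)) {
    p <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- p[1L]; j <- p[2L]
    if (i < 1L || j < 1L || i > nrow(rate) || j > ncol(rate)) next
    if (mask[i, j] || !above[i, j]) next
    mask[i, j] <- TRUE
    stack <- c(stack, list(c(i - 1L, j), c(i + 1L, j), c(i, j - 1L),
                           c(i, j + 1L)))
  }
  area <- sum(mask) * smap$bin_cm^2
  structure(list(field_mask = mask, field_area_cm2 = area,
                 field_length_cm = area / corridor_cm, peak_rate = peak,
                 has_field = TRUE), class = "place_field")
}
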