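# Coding ontogeny: when does a tracked neuron first satisfy a coding
# criterion, and how do its trajectory/spatial metrics evolve around that
# onset?

#' First session at which each neuron passes a coding criterion
#'
#' @param flags logical neuron x session matrix: whether the neuron
#'   passed the class criteria that session (NA where the neuron was not
#'   registered/active).
#' @return integer vector of onset session indices (NA if never).
#' @export
onset_sessions <- function(flags) {
  apply(flags, 1L, function(f) {
    w <- which(!is.na(f) & f)
    if (length(w)) w[1L] else NA_integer_
  })
}

#' Onset table for splitter and place coding
#'
#' @param splitter_onsets,place_onsets per-neuron onset session indices.
#' @param session_days calendar day of each session.
#' @return data.frame: neuron, splitter_onset_session,
#'   place_onset_session, onset_day_difference (splitter day - place day;
#'   NA unless both onsets exist).
#' @export
build_onset_table <- function(splitter_onsets, place_onsets, session_days) {
  n <- length(splitter_onsets)
  stopifnot(length(place_onsets) == n)
  day_of <- function(s) ifelse(is.na(s), NA_integer_, session_days[s])
  data.frame(
    neuron = seq_len(n),
    splitter_onset_session = splitter_onsets,
    place_onset_session = place_onsets,
    onset_day_difference = day_of(splitter_onsets) - day_of(place_onsets))
}

#' Align a per-session metric on each neuron's onset day
#'
#' Re-indexes a neuron x session metric matrix by day relative to each
#' neuron's onset session (day 0 = onset session's day), keeping relative
#' days within \code{window} days. When two sessions share a calendar
#' day, the earlier session defines that day's metric and the later one
#' is excluded.
#'
#' @param metric numeric neuron x session matrix (NA where undefined).
#' @param onsets per-neuron onset session indices.
#' @param session_days calendar day per session.
#' @param window day window around onset (default 10).
#' @return long data.frame: neuron, session, rel_day, value.
#' @export
aligned_metric_series <- function(metric, onsets, session_days,
                                  window = 10L) {
  keep_session <- !duplicated(session_days)   # earlier session defines a day
  rows <- list()
  for (n in seq_len(nrow(metric))) {
    if (is.na(onsets[n])) next
    d0 <- session_days[onsets[n]]
    for (s in which(keep_session)) {
      rd <- session_days[s] - d0
      v <- metric[n, s]
      if (is.na(v) || abs(rd) > window) next
      rows[[length(rows) + 1L]] <-
        data.frame(neuron = n, session = s, rel_day = rd, value = v)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(neuron = integer(0), session = integer(0),
                      rel_day = integer(0), value = numeric(0)))
  do.call(rbind, rows)
}

#' Compare splitter and place-cell onset distributions
#'
#' One-sided two-sample Kolmogorov-Smirnov test of the onset-day
#' distributions (default alternative: splitter onsets are
#' stochastically later than place onsets), plus a chi-squared
#' goodness-of-fit test of the per-neuron onset-day-difference
#' distribution against a sign-symmetric (label-swap) null: under the
#' null each nonzero difference d is equally likely to be -d, so the
#' expected count of each of (d, -d) is half their combined count.
#'
#' @param splitter_days onset days of splitter coding.
#' @param place_days onset days of place coding.
#' @param differences per-neuron onset-day differences (splitter -
#'   place), for neurons with both onsets.
#' @param min_onsets minimum onsets per class (default 10).
#' @return list: \code{ks} (statistic, p), \code{chisq} (statistic, df,
#'   p), \code{mean_difference}, \code{median_difference}.
#' @export
onset_comparison <- function(splitter_days, place_days, differences,
                             min_onsets = 10L) {
  splitter_days <- splitter_days[!is.na(splitter_days)]
  place_days <- place_days[!is.na(place_days)]
  if (length(splitter_days) < min_onsets || length(place_days) < min_onsets)
    stop("insufficient data: need at least ", min_onsets,
         " onsets per class")
  # alternative "less": the CDF of x lies below that of y, i.e. splitter
  # onsets stochastically later than place onsets
  ks <- suppressWarnings(stats::ks.test(splitter_days, place_days,
                                        alternative = "less"))
  differences <- differences[!is.na(differences)]
  chisq <- symmetric_null_chisq(differences)
  list(ks = list(statistic = unname(ks$statistic), p = ks$p.value),
       chisq = chisq,
       mean_difference = mean(differences),
       median_difference = stats::median(differences))
}

# Chi-squared goodness of fit of a difference histogram against a
# sign-symmetric null.
symmetric_null_chisq <- function(d) {
  d <- d[d != 0]
  if (length(d) == 0L)
    return(list(statistic = 0, df = 0L, p = 1))
  mags <- sort(unique(abs(d)))
  stat <- 0; df <- 0L
  for (m in mags) {
    o_pos <- sum(d == m); o_neg <- sum(d == -m)
    e <- (o_pos + o_neg) / 2
    stat <- stat + (o_pos - e)^2 / e + (o_neg - e)^2 / e
    df <- df + 1L
  }
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Within-session recruitment times by class
#'
#' For each neuron, the clock time and trial index of its first calcium
#' event in the session; splitter and place-cell recruitment
#' distributions are compared with one-sided KS tests (alternative:
#' splitters recruit earlier). Silent neurons are excluded.
#'
#' @param raster an \code{\link{event_raster}}.
#' @param trials a \code{trial_table}.
#' @param labels factor of functional labels aligned with
#'   \code{raster$neuron_ids}.
#' @return list: \code{table} (neuron, label, first_frame, first_time_s,
#'   first_trial), \code{ks_time}, \code{ks_trial} (NULL when either
#'   class is empty).
#' @export
recruitment_within_session <- function(raster, trials, labels) {
  ev <- raster$events
  first_frame <- apply(ev, 1L, function(r) {
    w <- which(r == 1L)
    if (length(w)) w[1L] else NA_integer_
  })
  keep <- !is.na(first_frame)
  ff <- first_frame[keep]
  tstart <- trials$start_frame
  first_trial <- pmax(findInterval(ff, tstart), 1L)
  tab <- data.frame(neuron = raster$neuron_ids[keep],
                    label = labels[keep],
                    first_frame = ff,
                    first_time_s = raster$frame_times[ff] -
                      raster$frame_times[1L],
                    first_trial = first_trial)
  ks_of <- function(v) {
    a <- v[tab$label == "splitter"]; b <- v[tab$label %in%
                                              c("stem_pc", "arm_pc")]
    if (length(a) < 3L || length(b) < 3L) return(NULL)
    # "greater": splitter CDF above -> splitters stochastically earlier
    k <- suppressWarnings(stats::ks.test(a, b, alternative = "greater"))
    list(statistic = unname(k$statistic), p = k$p.value,
         n = c(splitter = length(a), place = length(b)))
  }
  list(table = tab, ks_time = ks_of(tab$first_time_s),
       ks_trial = ks_of(tab$first_trial))
}
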