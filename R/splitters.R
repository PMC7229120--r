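# Trajectory-dependent ("splitter") cell analysis on the maze stem.
#
# The unit of analysis is the restricted central stem, cut into ~1 cm
# spatial bins. For each neuron, per-trial per-bin calcium activity counts
# and per-bin occupancy times are accumulated over correct free trials;
# occupancy-normalised tuning curves for left- and right-turn trials are
# compared bin-wise, and significance is assessed by permuting trial turn
# labels.

# Shared per-session accumulation: per-trial per-bin activity counts for
# every neuron plus per-trial per-bin occupancy. Only correct free trials
# enter (the trajectory comparison is defined on correct trials).
stem_count_matrices <- function(raster, trace, trials, geometry,
                                bin_cm = 1, correct_only = TRUE) {
  stopifnot(inherits(raster, "event_raster"),
            inherits(trace, "behavior_trace"),
            inherits(geometry, "maze_geometry"))
  sel <- if (correct_only) which(trials$correct & !trials$forced) else
    which(!trials$forced)
  if (length(sel) == 0L) stop("insufficient trials: no usable trials")
  tt <- trials[sel, , drop = FALSE]
  lo <- geometry$stem_range[1]
  hi <- geometry$stem_range[2]
  n_bins <- max(1L, floor((hi - lo) / bin_cm))
  hi <- lo + n_bins * bin_cm
  dt <- 1 / raster$frame_rate_hz

  n_trials <- nrow(tt)
  frames <- integer(0); f_trial <- integer(0)
  for (k in seq_len(n_trials)) {
    fr <- tt$stem_start[k]:tt$stem_end[k]
    fr <- fr[trace$y[fr] >= lo & trace$y[fr] < hi]
    frames <- c(frames, fr)
    f_trial <- c(f_trial, rep(k, length(fr)))
  }
  f_bin <- pmin(pmax(floor((trace$y[frames] - lo) / bin_cm) + 1L, 1L), n_bins)
  key <- (f_trial - 1L) * n_bins + f_bin

  tab <- tabulate(key, nbins = n_trials * n_bins)
  occ <- matrix(tab * dt, n_trials, n_bins, byrow = TRUE)

  ev <- raster$events[, frames, drop = FALSE]
  n_neurons <- nrow(ev)
  counts <- array(0, dim = c(n_neurons, n_trials, n_bins))
  if (length(frames) && n_neurons > 0L) {
    grp <- rowsum(t(ev), group = key)           # unique keys x neurons
    ukey <- as.integer(rownames(grp))
    tr_i <- (ukey - 1L) %/% n_bins + 1L
    bi <- (ukey - 1L) %% n_bins + 1L
    for (n in seq_len(n_neurons)) {
      m <- matrix(0, n_trials, n_bins)
      m[cbind(tr_i, bi)] <- grp[, n]
      counts[n, , ] <- m
    }
  }
  list(counts = counts, occ = occ, turn = tt$turn,
       bin_edges = seq(lo, hi, by = bin_cm), n_bins = n_bins,
       trial_index = tt$trial, neuron_ids = raster$neuron_ids)
}

#' Stem tuning curves for one neuron
#'
#' Occupancy-normalised event-rate curves along the restricted central
#' stem, computed separately for left- and right-turn correct trials:
#' rate per bin = mean per-trial activity count / mean per-trial occupancy
#' time (equivalently, pooled counts over pooled time). Bins with zero
#' occupancy in either trial type are masked invalid.
#'
#' @param raster an \code{\link{event_raster}}.
#' @param trace the session's \code{behavior_trace} (section-annotated).
#' @param trials a \code{trial_table}.
#' @param neuron neuron id (an entry of \code{raster$neuron_ids}).
#' @param geometry a \code{\link{maze_geometry}}.
#' @param bin_cm stem bin size (cm, default ~1).
#' @param correct_only restrict to correct free trials (default TRUE).
#' @return a \code{stem_tuning} object carrying the curves, per-bin
#'   occupancy, trial-level count/occupancy matrices (used by the
#'   permutation test), and the valid-bin mask.
#' @export
stem_tuning_curves <- function(raster, trace, trials, neuron = NULL,
                               geometry = maze_geometry(), bin_cm = 1,
                               correct_only = TRUE) {
  mats <- stem_count_matrices(raster, trace, trials, geometry, bin_cm,
                              correct_only)
  if (is.null(neuron)) neuron <- raster$neuron_ids[1L]
  n <- match(neuron, raster$neuron_ids)
  if (is.na(n)) stop("neuron ", neuron, " not present in raster")
  stem_tuning_from_matrices(mats$counts[n, , , drop = FALSE], mats, neuron)
}

stem_tuning_from_matrices <- function(counts_n, mats, neuron) {
  counts <- matrix(counts_n, dim(counts_n)[2L], dim(counts_n)[3L])
  turn <- mats$turn
  is_l <- turn == "left"
  if (sum(is_l) < 1L || sum(!is_l) < 1L)
    stop("insufficient trials: need at least one correct trial per direction")
  occ_l <- colSums(mats$occ[is_l, , drop = FALSE])
  occ_r <- colSums(mats$occ[!is_l, , drop = FALSE])
  tc_l <- ifelse(occ_l > 0, colSums(counts[is_l, , drop = FALSE]) / occ_l,
                 NA_real_)
  tc_r <- ifelse(occ_r > 0, colSums(counts[!is_l, , drop = FALSE]) / occ_r,
                 NA_real_)
  structure(list(
    neuron = neuron, bin_edges = mats$bin_edges,
    tc_left = tc_l, tc_right = tc_r,
    occupancy_left = occ_l, occupancy_right = occ_r,
    n_trials_left = sum(is_l), n_trials_right = sum(!is_l),
    n_stem_event_trials = sum(rowSums(counts) > 0),
    valid = occ_l > 0 & occ_r > 0,
    counts = counts, occ = mats$occ, turn = turn
  ), class = "stem_tuning")
}

#' @export
print.stem_tuning <- function(x, ...) {
  cat(sprintf(
    "stem_tuning (neuron %s): %d bins (%d valid), %dL/%dR correct trials,\n",
    x$neuron, length(x$valid), sum(x$valid), x$n_trials_left,
    x$n_trials_right))
  cat(sprintf("  peak rate L %.2f / R %.2f events/s; %d stem-event trials\n",
              max(c(x$tc_left[x$valid], 0)), max(c(x$tc_right[x$valid], 0)),
              x$n_stem_event_trials))
  invisible(x)
}

# Turn-label permutations shared across neurons of a session: a matrix of
# left-indicator columns, one per shuffle, each preserving the session's
# left/right trial counts.
make_label_permutations <- function(turn, n_shuffles, seed) {
  n <- length(turn)
  with_rng(seed, {
    out <- matrix(FALSE, n, n_shuffles)
    for (s in seq_len(n_shuffles)) out[sample.int(n), s] <- turn == "left"
    out
  })
}

# Core of the shuffle test: per-bin fraction of shuffles whose
# |tuning-curve difference| is strictly exceeded by the real difference.
permutation_core <- function(counts, occ, turn, perm_left) {
  is_l <- turn == "left"
  occ_t <- t(occ)                       # bins x trials
  cnt_t <- t(counts)
  real <- abs(colSums(counts[is_l, , drop = FALSE]) /
                colSums(occ[is_l, , drop = FALSE]) -
              colSums(counts[!is_l, , drop = FALSE]) /
                colSums(occ[!is_l, , drop = FALSE]))
  sl <- cnt_t %*% perm_left
  ol <- occ_t %*% perm_left
  sr <- cnt_t %*% (!perm_left)
  or <- occ_t %*% (!perm_left)
  stat <- abs(sl / ol - sr / or)        # NaN where a side has no occupancy
  # strict exceedance with a numerical tie guard: the real statistic and
  # the shuffled ones come from different BLAS paths, so exact ties must
  # not be broken by floating-point noise
  exceeded <- (real - stat) > 1e-9 * (1 + real)
  exceeded[is.na(exceeded)] <- FALSE    # ties/undefined count against
  list(rel_per_bin = rowMeans(exceeded), real_diff = real)
}

#' Trial-label permutation test for trajectory-dependent bins
#'
#' Statistic per stem bin: |left - right| occupancy-normalised rate
#' difference. Each shuffle permutes the turn labels of the correct trials
#' (preserving left/right counts) and recomputes the statistic;
#' \code{rel_per_bin} is the proportion of shuffles strictly exceeded by
#' the real difference (ties count against significance), and a bin is
#' significant when that proportion is strictly above \code{1 - alpha}
#' (a per-bin reliability above 0.95 at defaults).
#'
#' @param tuning a \code{\link{stem_tuning_curves}} result.
#' @param n_shuffles number of label shuffles (default 1000).
#' @param alpha per-bin significance level (default 0.05).
#' @param seed RNG seed for the shuffles.
#' @param perm_left optional precomputed left-indicator matrix from
#'   \code{make_label_permutations} (one label permutation is evaluated at
#'   all bins, and may be shared by all neurons of a session).
#' @return list with \code{sig_bin_mask}, \code{rel_per_bin},
#'   \code{real_diff}, \code{n_sig_bins}.
#' @export
permutation_test <- function(tuning, n_shuffles = 1000L, alpha = 0.05,
                             seed = 1L, perm_left = NULL) {
  stopifnot(inherits(tuning, "stem_tuning"))
  if (tuning$n_trials_left < 2L || tuning$n_trials_right < 2L)
    stop("insufficient trials: need at least 2 correct trials per direction")
  if (is.null(perm_left))
    perm_left <- make_label_permutations(tuning$turn, n_shuffles, seed)
  core <- permutation_core(tuning$counts, tuning$occ, tuning$turn, perm_left)
  rel <- core$rel_per_bin
  # strictly above 1 - alpha: the real difference must exceed more than
  # 950 of 1000 shuffles at defaults, keeping the per-bin level at or
  # below alpha (50/1001 for a continuous statistic)
  sig <- tuning$valid & rel > 1 - alpha
  list(sig_bin_mask = sig, rel_per_bin = rel, real_diff = core$real_diff,
       n_sig_bins = sum(sig))
}

#' Splitter classification rule
#'
#' A neuron is a splitter candidate when at least \code{min_sig_bins} stem
#' bins pass the permutation test and it produced a calcium event on the
#' stem on at least \code{min_stem_event_trials} trials. (The ANOVA
#' covariate confirmation is applied separately; see
#' \code{\link{anova_covariate_check}}.)
#'
#' @param sig_bin_mask logical per-bin significance mask.
#' @param n_stem_event_trials number of trials with at least one stem
#'   event.
#' @param min_sig_bins minimum significant bins (default 3).
#' @param min_stem_event_trials minimum stem-event trials (default 5).
#' @return logical flag.
#' @export
classify_splitter <- function(sig_bin_mask, n_stem_event_trials,
                              min_sig_bins = 3L, min_stem_event_trials = 5L) {
  sum(sig_bin_mask, na.rm = TRUE) >= min_sig_bins &&
    n_stem_event_trials >= min_stem_event_trials
}

#' Trajectory discriminability
#'
#' Sum of |left - right| tuning-curve differences over valid stem bins,
#' divided by the sum of the two curves: 0 for identical curves, 1 for
#' disjoint support.
#'
#' @param tuning a \code{stem_tuning}.
#' @return value in [0, 1], or NA when both curves are identically zero
#'   (undefined; excluded from session means).
#' @export
discriminability <- function(tuning) {
  v <- tuning$valid
  num <- sum(abs(tuning$tc_left[v] - tuning$tc_right[v]))
  den <- sum(tuning$tc_left[v] + tuning$tc_right[v])
  if (!any(v) || den <= 0) return(NA_real_)
  num / den
}

#' Reliability summary
#'
#' Mean and peak over valid stem bins of the per-bin shuffle-exceedance
#' proportion (\code{rel_per_bin} of \code{\link{permutation_test}}).
#'
#' @param rel_per_bin per-bin proportions.
#' @param valid logical valid-bin mask (default all).
#' @return named numeric: \code{mean}, \code{peak}.
#' @export
reliability_summary <- function(rel_per_bin, valid = NULL) {
  if (is.null(valid)) valid <- rep(TRUE, length(rel_per_bin))
  r <- rel_per_bin[valid]
  if (length(r) == 0L) return(c(mean = NA_real_, peak = NA_real_))
  c(mean = mean(r), peak = max(r))
}

#' Left/right tuning-curve decorrelation (1 - Spearman's rho)
#'
#' Computed on the unsmoothed curves over valid bins; 0 for perfectly
#' rank-correlated curves, 2 for perfectly anti-correlated ones. This
#' metric is conservative for rate-scaling splitters (which keep their
#' peak location) and sensitive to field-shift splitters.
#'
#' @param tuning a \code{stem_tuning}.
#' @return 1 - Spearman rank correlation, or NA when either curve has zero
#'   variance over valid bins.
#' @export
tuning_correlation_metric <- function(tuning) {
  v <- tuning$valid
  a <- tuning$tc_left[v]; b <- tuning$tc_right[v]
  if (length(a) < 3L || stats::sd(a) == 0 || stats::sd(b) == 0)
    return(NA_real_)
  1 - stats::cor(a, b, method = "spearman")
}

#' ANOVA confirmation against speed/lateral-position confounds
#'
#' Guards against trajectory-dependence that is secondary to stereotyped
#' kinematics: the stem is divided lengthwise into \code{n_lengthwise_bins}
#' coarse bins; per correct trial and bin, the mean occupancy-normalised
#' transient probability is modelled on trial type, stem bin and their
#' interaction (categorical) plus the animal's speed and lateral position
#' (continuous). A candidate is confirmed when the trial-type main effect
#' or the type x bin interaction is significant (type-II tests) after
#' accounting for the kinematic covariates. Constant covariates are
#' dropped with a warning.
#'
#' @param raster,trace,trials,geometry session inputs as elsewhere.
#' @param neuron neuron id.
#' @param n_lengthwise_bins number of coarse stem bins (default 5).
#' @param alpha significance level (default 0.05).
#' @return list: \code{confirmed}, \code{effects} (term/p table).
#' @export
anova_covariate_check <- function(raster, trace, trials, neuron,
                                  geometry = maze_geometry(),
                                  n_lengthwise_bins = 5L, alpha = 0.05) {
  sel <- which(trials$correct & !trials$forced)
  if (length(sel) < 4L) stop("insufficient trials for the ANOVA check")
  tt <- trials[sel, , drop = FALSE]
  lo <- geometry$stem_range[1]; hi <- geometry$stem_range[2]
  n <- match(neuron, raster$neuron_ids)
  if (is.na(n)) stop("neuron ", neuron, " not present in raster")
  ev <- raster$events[n, ]
  rows <- list()
  width <- (hi - lo) / n_lengthwise_bins
  for (k in seq_len(nrow(tt))) {
    fr <- tt$stem_start[k]:tt$stem_end[k]
    fr <- fr[trace$y[fr] >= lo & trace$y[fr] < hi]
    if (!length(fr)) next
    b <- pmin(floor((trace$y[fr] - lo) / width) + 1L, n_lengthwise_bins)
    for (bb in unique(b)) {
      fb <- fr[b == bb]
      rows[[length(rows) + 1L]] <- data.frame(
        trial = k, turn = tt$turn[k], bin = bb,
        prob = mean(ev[fb]),
        speed = mean(trace$speed[fb]),
        lateral = mean(trace$lateral[fb]))
    }
  }
  d <- do.call(rbind, rows)
  d$turn <- factor(d$turn); d$bin <- factor(d$bin)
  covars <- c("speed", "lateral")
  keep <- vapply(covars, function(v) stats::sd(d[[v]]) > 1e-10, logical(1))
  if (!all(keep))
    warning("dropping constant covariate(s): ",
            paste(covars[!keep], collapse = ", "))
  form <- stats::reformulate(c("turn", "bin", "turn:bin", covars[keep]),
                             response = "prob")
  fit <- stats::lm(form, data = d)
  tab <- tryCatch(car::Anova(fit, type = 2),
                  error = function(e) stats::anova(fit))
  pv <- tab[["Pr(>F)"]]
  terms_ <- rownames(tab)
  p_turn <- pv[terms_ == "turn"]
  p_int <- pv[terms_ == "turn:bin"]
  confirmed <- isTRUE(p_turn < alpha) || isTRUE(p_int < alpha)
  list(confirmed = confirmed,
       effects = data.frame(term = terms_, p = pv))
}

#' Full splitter analysis for every neuron of a session
#'
#' Runs tuning curves, the 1000-shuffle permutation test (each neuron
#' draws its own label permutations, evaluated at every bin), the
#' splitter classification rule,
#' the trajectory metrics, and — for permutation-passing candidates — the
#' ANOVA covariate confirmation.
#'
#' @param raster,trace,trials,geometry session inputs.
#' @param bin_cm stem bin size (cm).
#' @param n_shuffles,alpha permutation-test parameters.
#' @param seed RNG seed for the shuffles.
#' @param min_sig_bins,min_stem_event_trials classification thresholds.
#' @param anova_confirm run the covariate ANOVA on candidates (default
#'   TRUE).
#' @return a \code{splitter_result} data.frame, one row per neuron:
#'   metrics, candidate and final splitter flags, significant-bin counts;
#'   per-bin masks in \code{attr(, "sig_bin_mask")} /
#'   \code{attr(, "rel_per_bin")} (neurons x bins).
#' @export
splitter_analysis <- function(raster, trace, trials,
                              geometry = maze_geometry(), bin_cm = 1,
                              n_shuffles = 1000L, alpha = 0.05, seed = 1L,
                              min_sig_bins = 3L, min_stem_event_trials = 5L,
                              anova_confirm = TRUE) {
  mats <- stem_count_matrices(raster, trace, trials, geometry, bin_cm)
  if (sum(mats$turn == "left") < 2L || sum(mats$turn == "right") < 2L)
    stop("insufficient trials: need at least 2 correct trials per direction")
  n_neurons <- dim(mats$counts)[1L]
  nb <- mats$n_bins
  sig_m <- matrix(FALSE, n_neurons, nb)
  rel_m <- matrix(NA_real_, n_neurons, nb)
  out <- data.frame(neuron = mats$neuron_ids,
                    n_stem_event_trials = integer(n_neurons),
                    n_sig_bins = integer(n_neurons),
                    splitting_extent = NA_real_,
                    discriminability = NA_real_,
                    reliability_mean = NA_real_,
                    reliability_peak = NA_real_,
                    one_minus_rho = NA_real_,
                    candidate = FALSE, anova_confirmed = NA,
                    is_splitter = FALSE)
  for (n in seq_len(n_neurons)) {
    tun <- stem_tuning_from_matrices(mats$counts[n, , , drop = FALSE], mats,
                                     mats$neuron_ids[n])
    # one label-permutation set per neuron, reused across its bins
    pt <- permutation_test(tun, n_shuffles, alpha,
                           seed = derive_seed(seed, 2L, n))
    sig_m[n, ] <- pt$sig_bin_mask
    rel_m[n, ] <- pt$rel_per_bin
    rel <- reliability_summary(pt$rel_per_bin, tun$valid)
    nv <- sum(tun$valid)
    out$n_stem_event_trials[n] <- tun$n_stem_event_trials
    out$n_sig_bins[n] <- pt$n_sig_bins
    out$splitting_extent[n] <- if (nv > 0) pt$n_sig_bins / nv else NA_real_
    out$discriminability[n] <- discriminability(tun)
    out$reliability_mean[n] <- rel[["mean"]]
    out$reliability_peak[n] <- rel[["peak"]]
    out$one_minus_rho[n] <- tuning_correlation_metric(tun)
    out$candidate[n] <- classify_splitter(pt$sig_bin_mask,
                                          tun$n_stem_event_trials,
                                          min_sig_bins,
                                          min_stem_event_trials)
  }
  if (anova_confirm) {
    for (n in which(out$candidate)) {
      chk <- tryCatch(
        anova_covariate_check(raster, trace, trials, out$neuron[n],
                              geometry, alpha = alpha),
        error = function(e) list(confirmed = NA))
      out$anova_confirmed[n] <- chk$confirmed
    }
    out$is_splitter <- out$candidate & !is.na(out$anova_confirmed) &
      out$anova_confirmed
  } else {
    out$is_splitter <- out$candidate
  }
  attr(out, "sig_bin_mask") <- sig_m
  attr(out, "rel_per_bin") <- rel_m
  attr(out, "bin_edges") <- mats$bin_edges
  class(out) <- c("splitter_result", "data.frame")
  out
}

#' Correlate a session-level metric with behavioral performance
#'
#' Pearson correlation between per-session mean trajectory metrics and
#' session performance, either over all sessions or over per-mouse means.
#'
#' @param metric numeric per-session metric values.
#' @param performance numeric per-session performance, same length.
#' @param mouse optional per-session mouse labels (required for
#'   \code{level = "mice"}).
#' @param level "sessions" (each session one observation) or "mice" (one
#'   mean metric and one mean performance per animal).
#' @return list: \code{estimate}, \code{p_value}, \code{n}.
#' @export
correlate_metric_with_performance <- function(metric, performance,
                                              mouse = NULL,
                                              level = c("sessions", "mice")) {
  level <- match.arg(level)
  keep <- is.finite(metric) & is.finite(performance)
  metric <- metric[keep]; performance <- performance[keep]
  if (level == "mice") {
    if (is.null(mouse)) stop("per-mouse correlation requires mouse labels")
    mouse <- mouse[keep]
    metric <- tapply(metric, mouse, mean)
    performance <- tapply(performance, mouse, mean)
  }
  if (length(metric) < 3L)
    stop("insufficient data: need at least 3 paired observations")
  ct <- stats::cor.test(metric, performance, method = "pearson")
  list(estimate = unname(ct$estimate), p_value = ct$p.value,
       n = length(metric))
}
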