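# Linear-discriminant decoding of upcoming turn direction from population
# calcium activity on the center stem.
#
# Each stem time point of a correct trial is one observation: the feature
# vector is the population's binary activity at that frame and the
# response is the trial's upcoming turn. Per repeat, a random half of the
# correct trials (stratified by direction) trains the discriminant and
# the held-out half is predicted; accuracy is aggregated in ~3.3 cm
# spatial bins along the stem and averaged over bins.
#
# Default discriminant: shared diagonal covariance. Stem time points
# vastly outnumber trials, so a pooled full covariance is singular; the
# diagonal variant is the standard remedy. A full-covariance LDA
# (MASS::lda) is available via method = "lda".

# Collect stem-frame features for correct free trials.
decoder_frames <- function(raster, trace, trials, geometry, bin_cm) {
  sel <- which(trials$correct & !trials$forced)
  tt <- trials[sel, , drop = FALSE]
  lo <- geometry$stem_range[1]; hi <- geometry$stem_range[2]
  n_bins <- max(1L, floor((hi - lo) / bin_cm))
  frames <- integer(0); f_trial <- integer(0)
  for (k in seq_len(nrow(tt))) {
    fr <- tt$stem_start[k]:tt$stem_end[k]
    fr <- fr[trace$y[fr] >= lo & trace$y[fr] < lo + n_bins * bin_cm]
    frames <- c(frames, fr)
    f_trial <- c(f_trial, rep(k, length(fr)))
  }
  list(X = t(raster$events[, frames, drop = FALSE]),   # frames x neurons
       trial = f_trial, turn = tt$turn,
       bin = pmin(floor((trace$y[frames] - lo) / bin_cm) + 1L, n_bins),
       n_bins = n_bins, n_trials = nrow(tt))
}

fit_diag_lda <- function(X, y) {
  is_l <- y == "left"
  mu_l <- colMeans(X[is_l, , drop = FALSE])
  mu_r <- colMeans(X[!is_l, , drop = FALSE])
  v <- (colSums(sweep(X[is_l, , drop = FALSE], 2, mu_l)^2) +
          colSums(sweep(X[!is_l, , drop = FALSE], 2, mu_r)^2)) /
    max(nrow(X) - 2L, 1L)
  v <- pmax(v, 1e-6)
  w <- (mu_l - mu_r) / v
  list(w = w, b = -sum(w * (mu_l + mu_r)) / 2 + log(mean(is_l) /
                                                      mean(!is_l)))
}

predict_diag_lda <- function(fit, X) {
  ifelse(as.numeric(X %*% fit$w) + fit$b > 0, "left", "right")
}

#' Linear discriminant decoding of upcoming turn direction
#'
#' @param raster an \code{\link{event_raster}}.
#' @param trace the session \code{behavior_trace}.
#' @param trials a \code{trial_table}; only correct free trials are used.
#' @param geometry a \code{\link{maze_geometry}}.
#' @param train_frac fraction of trials used for training each repeat
#'   (default 0.5).
#' @param n_repeats total number of train/test fits (default 1000).
#' @param bin_cm spatial bin size for accuracy aggregation (default
#'   3.3 cm).
#' @param seed RNG seed for the resampling.
#' @param method "diag" (shared diagonal covariance, default) or "lda"
#'   (MASS full-covariance LDA).
#' @param shuffle_labels if TRUE, trial turn labels are permuted before
#'   every repeat's split (the chance pipeline).
#' @return a \code{decode_result}: per-bin accuracy, \code{mean_accuracy}
#'   (mean over bins), per-trial vote accuracy, repeat count.
#' @export
lda_turn_decoder <- function(raster, trace, trials,
                             geometry = maze_geometry(), train_frac = 0.5,
                             n_repeats = 1000L, bin_cm = 3.3, seed = 1L,
                             method = c("diag", "lda"),
                             shuffle_labels = FALSE) {
  method <- match.arg(method)
  dat <- decoder_frames(raster, trace, trials, geometry, bin_cm)
  turn <- dat$turn
  if (sum(turn == "left") < 2L || sum(turn == "right") < 2L)
    stop("insufficient trials: need at least 2 correct trials per direction")
  with_rng(seed, {
    bin_correct <- numeric(dat$n_bins)
    bin_total <- numeric(dat$n_bins)
    trial_correct <- 0; trial_total <- 0
    for (rep_i in seq_len(n_repeats)) {
      lab <- if (shuffle_labels) sample(turn) else turn
      li <- which(lab == "left"); ri <- which(lab == "right")
      train <- c(sample(li, max(1L, round(train_frac * length(li)))),
                 sample(ri, max(1L, round(train_frac * length(ri)))))
      test <- setdiff(seq_len(dat$n_trials), train)
      tr_rows <- dat$trial %in% train
      te_rows <- which(!tr_rows)
      y_tr <- lab[dat$trial[tr_rows]]
      if (length(unique(y_tr)) < 2L) next   # degenerate split; skip (logged)
      pred <- if (method == "diag") {
        fit <- fit_diag_lda(dat$X[tr_rows, , drop = FALSE], y_tr)
        predict_diag_lda(fit, dat$X[te_rows, , drop = FALSE])
      } else {
        fit <- MASS::lda(dat$X[tr_rows, , drop = FALSE], grouping = y_tr)
        as.character(stats::predict(
          fit, dat$X[te_rows, , drop = FALSE])$class)
      }
      truth <- lab[dat$trial[te_rows]]
      hit <- pred == truth
      bs <- dat$bin[te_rows]
      bin_correct <- bin_correct + tabulate(bs[hit], dat$n_bins)
      bin_total <- bin_total + tabulate(bs, dat$n_bins)
      # per-trial majority vote
      votes <- tapply(pred == "left", dat$trial[te_rows], mean)
      vote_pred <- ifelse(votes > 0.5, "left", "right")
      vt <- lab[as.integer(names(votes))]
      trial_correct <- trial_correct + sum(vote_pred == vt)
      trial_total <- trial_total + length(vt)
    }
    acc <- ifelse(bin_total > 0, bin_correct / bin_total, NA_real_)
    structure(list(
      bin_accuracy = acc,
      mean_accuracy = mean(acc, na.rm = TRUE),
      trial_accuracy = if (trial_total > 0) trial_correct / trial_total
      else NA_real_,
      n_repeats = n_repeats, n_bins = dat$n_bins,
      shuffled = shuffle_labels
    ), class = "decode_result")
  })
}

#' Chance-level decoding accuracy
#'
#' Runs the identical decoding pipeline with trial turn labels shuffled
#' before every split. With balanced classes, chance sits near 0.5 (near
#' the majority-class prior otherwise); it is reported alongside the real
#' accuracy, never subtracted.
#'
#' @inheritParams lda_turn_decoder
#' @return a \code{decode_result} with \code{shuffled = TRUE}.
#' @export
decoder_chance <- function(raster, trace, trials,
                           geometry = maze_geometry(), train_frac = 0.5,
                           n_repeats = 1000L, bin_cm = 3.3, seed = 1L,
                           method = c("diag", "lda")) {
  lda_turn_decoder(raster, trace, trials, geometry, train_frac, n_repeats,
                   bin_cm, seed, method, shuffle_labels = TRUE)
}

#' @export
print.decode_result <- function(x, ...) {
  cat(sprintf(
    "decode_result%s: mean accuracy %.3f over %d stem bins (%d repeats); trial-vote accuracy %.3f\n",
    if (x$shuffled) " (label-shuffled chance)" else "",
    x$mean_accuracy, x$n_bins, x$n_repeats, x$trial_accuracy))
  invisible(x)
}
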