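# Cross-session neuron registration, functional class assignment, and
# class-dependent turnover / stability statistics.

CODING_CLASSES <- c("splitter", "stem_pc", "arm_pc", "stem_npc", "arm_npc")

#' Register neurons between two sessions from ROI centroids
#'
#' Mutual-nearest-neighbour matching on centroid distance, accepting only
#' pairs closer than \code{max_dist_um}. Mutual matching is one-to-one by
#' construction; unmatched neurons are reported separately.
#'
#' @param roi_a,roi_b ROI tables (neuron_id, x_um, y_um, orientation_deg)
#'   for the two sessions, on the same spatial scale.
#' @param max_dist_um maximum accepted centroid distance (default 5 um).
#' @return a \code{neuron_registry} data.frame: neuron_a, neuron_b,
#'   distance_um, d_orientation_deg; unmatched ids in attributes.
#' @export
register_sessions <- function(roi_a, roi_b, max_dist_um = 5) {
  need <- c("neuron_id", "x_um", "y_um", "orientation_deg")
  if (!all(need %in% names(roi_a)) || !all(need %in% names(roi_b)))
    stop("registration error: ROI tables need columns ",
         paste(need, collapse = ", "))
  if (nrow(roi_a) == 0L || nrow(roi_b) == 0L) {
    reg <- data.frame(neuron_a = integer(0), neuron_b = integer(0),
                      distance_um = numeric(0),
                      d_orientation_deg = numeric(0))
  } else {
    dx <- outer(roi_a$x_um, roi_b$x_um, "-")
    dy <- outer(roi_a$y_um, roi_b$y_um, "-")
    dist <- sqrt(dx^2 + dy^2)
    nn_ab <- apply(dist, 1L, which.min)
    nn_ba <- apply(dist, 2L, which.min)
    ia <- seq_len(nrow(roi_a))
    mutual <- nn_ba[nn_ab] == ia & dist[cbind(ia, nn_ab)] <= max_dist_um
    ia <- ia[mutual]; ib <- nn_ab[mutual]
    reg <- data.frame(
      neuron_a = roi_a$neuron_id[ia], neuron_b = roi_b$neuron_id[ib],
      distance_um = dist[cbind(ia, ib)],
      d_orientation_deg = orientation_diff(roi_a$orientation_deg[ia],
                                           roi_b$orientation_deg[ib]))
  }
  attr(reg, "unmatched_a") <- setdiff(roi_a$neuron_id, reg$neuron_a)
  attr(reg, "unmatched_b") <- setdiff(roi_b$neuron_id, reg$neuron_b)
  class(reg) <- c("neuron_registry", "data.frame")
  reg
}

#' @export
print.neuron_registry <- function(x, ...) {
  cat(sprintf(
    "neuron_registry: %d matches (median distance %.2f um); %d/%d unmatched\n",
    nrow(x),
    if (nrow(x)) stats::median(x$distance_um) else NA_real_,
    length(attr(x, "unmatched_a")), length(attr(x, "unmatched_b"))))
  invisible(x)
}

#' Registration quality control from ROI orientations
#'
#' Correctly registered neurons keep the orientation of their major
#' elliptical axis, so orientation changes across a session pair should
#' concentrate near zero. The observed mean |orientation change| over
#' matches is compared to a null built by shuffling neuron identity
#' between the sessions (pairing each matched first-session neuron with a
#' random second-session neuron) \code{n_shuffles} times. The pair passes
#' when the observed mean is significantly smaller than the null.
#'
#' @param registry a \code{\link{register_sessions}} result.
#' @param roi_a,roi_b the ROI tables it was built from.
#' @param n_shuffles identity shuffles (default 1000).
#' @param seed RNG seed.
#' @param alpha significance level (default 0.05).
#' @param min_matches below this the verdict is indeterminate (default
#'   10).
#' @return list: \code{verdict} ("pass", "fail", "indeterminate"),
#'   \code{p_value}, \code{real_mean_deg}, \code{null_mean_deg}.
#' @export
registration_qc <- function(registry, roi_a, roi_b, n_shuffles = 1000L,
                            seed = 1L, alpha = 0.05, min_matches = 10L) {
  if (nrow(registry) < min_matches)
    return(list(verdict = "indeterminate", p_value = NA_real_,
                real_mean_deg = NA_real_, null_mean_deg = NA_real_))
  ori_a <- roi_a$orientation_deg[match(registry$neuron_a, roi_a$neuron_id)]
  ori_b <- roi_b$orientation_deg[match(registry$neuron_b, roi_b$neuron_id)]
  ori_b_all <- roi_b$orientation_deg
  real <- mean(orientation_diff(ori_a, ori_b))
  null_means <- with_rng(seed, {
    vapply(seq_len(n_shuffles), function(s) {
      mean(orientation_diff(
        ori_a, sample(ori_b_all, length(ori_a),
                      replace = length(ori_b_all) < length(ori_a))))
    }, numeric(1))
  })
  p <- mean(null_means <= real)
  list(verdict = if (p < alpha) "pass" else "fail", p_value = p,
       real_mean_deg = real, null_mean_deg = mean(null_means))
}

#' Assign functional coding labels
#'
#' Partitions the session's maze-active neurons into the five functional
#' coding types. Splitter status takes precedence; place cells with no
#' stem calcium activity are return-arm place cells; stem-active place
#' cells failing the splitter criteria are stem place cells; the
#' remainder split into stem/arm non-place cells by stem activity.
#'
#' @param is_splitter,is_place_cell,stem_active logical vectors over the
#'   session's neurons.
#' @return factor of labels (splitter, stem_pc, arm_pc, stem_npc,
#'   arm_npc); every neuron gets exactly one.
#' @export
assign_coding_labels <- function(is_splitter, is_place_cell, stem_active) {
  n <- length(is_splitter)
  stopifnot(length(is_place_cell) == n, length(stem_active) == n)
  lab <- ifelse(is_splitter, "splitter",
         ifelse(is_place_cell & !stem_active, "arm_pc",
         ifelse(is_place_cell, "stem_pc",
         ifelse(stem_active, "stem_npc", "arm_npc"))))
  factor(lab, levels = CODING_CLASSES)
}

#' Per-class stay-active probability for a session pair
#'
#' For each functional class, the probability that a neuron of that class
#' in the first session is active again in the second: the base
#' population is the class's neurons with at least \code{min_events}
#' calcium events (while running) in the first session; a neuron stays
#' active when the registry matches it to a neuron present in the second
#' session. Classes with fewer than \code{min_cells} base neurons are
#' excluded (dropped rows, recorded in \code{attr(, "excluded")}).
#'
#' @param registry \code{\link{register_sessions}} result for the pair.
#' @param labels_a factor of class labels for first-session neurons.
#' @param neurons_a first-session neuron ids (aligned with
#'   \code{labels_a}).
#' @param n_events_a running event counts for those neurons.
#' @param neurons_b ids of neurons present in the second session.
#' @param lag day lag of the pair.
#' @param min_cells minimum base-population size (default 4).
#' @param min_events minimum first-session event count (default 5).
#' @return data.frame: class, n_base, n_stay, probability, lag.
#' @export
stay_active_probability <- function(registry, labels_a, neurons_a,
                                    n_events_a, neurons_b, lag = NA_integer_,
                                    min_cells = 4L, min_events = 5L) {
  matched_a <- registry$neuron_a[registry$neuron_b %in% neurons_b]
  rows <- lapply(CODING_CLASSES, function(cl) {
    base <- neurons_a[labels_a == cl & n_events_a >= min_events]
    data.frame(class = cl, n_base = length(base),
               n_stay = sum(base %in% matched_a),
               probability = if (length(base)) mean(base %in% matched_a)
               else NA_real_,
               lag = lag)
  })
  tab <- do.call(rbind, rows)
  excluded <- tab$class[tab$n_base < min_cells]
  tab <- tab[tab$n_base >= min_cells, , drop = FALSE]
  attr(tab, "excluded") <- as.character(excluded)
  tab
}

#' Event-rate matching across functional classes
#'
#' Matches each class's mean event rate to the reference class (default
#' splitters) by iteratively excluding that class's lowest-rate cells
#' until its mean reaches the reference mean. A class whose mean already
#' meets or exceeds the reference keeps all its cells; the reference
#' class is never touched.
#'
#' @param rates numeric event rates (events/min while running).
#' @param labels factor/character class labels, same length.
#' @param reference_class class to match to (default "splitter").
#' @return logical \code{keep} vector; classes emptied before matching
#'   are recorded in \code{attr(, "failed_classes")}.
#' @export
event_rate_match <- function(rates, labels, reference_class = "splitter") {
  labels <- as.character(labels)
  ref_rates <- rates[labels == reference_class]
  if (length(ref_rates) == 0L)
    stop("reference class has no cells to match to")
  ref_mean <- mean(ref_rates)
  keep <- rep(TRUE, length(rates))
  failed <- character(0)
  for (cl in setdiff(unique(labels), reference_class)) {
    idx <- which(labels == cl)
    ord <- idx[order(rates[idx])]         # ascending: drop lowest first
    drop_n <- 0L
    while (drop_n < length(ord) &&
           mean(rates[ord[(drop_n + 1L):length(ord)]]) < ref_mean)
      drop_n <- drop_n + 1L
    if (drop_n >= length(ord)) {
      failed <- c(failed, cl)
      keep[idx] <- FALSE
    } else if (drop_n > 0L) {
      keep[ord[seq_len(drop_n)]] <- FALSE
    }
  }
  attr(keep, "failed_classes") <- failed
  keep
}

#' Cross-session spatial correlation of smoothed event maps
#'
#' Spearman correlation of each matched neuron's smoothed rate maps over
#' the bins visited in both sessions; neurons with fewer than
#' \code{min_bins} mutually visited bins are skipped.
#'
#' @param maps_a,maps_b named lists of \code{\link{smoothed_rate_map}}
#'   objects (names = neuron ids) for the two sessions.
#' @param registry the pair's \code{neuron_registry}.
#' @param min_bins minimum mutually visited bins (default 10).
#' @return data.frame: neuron_a, neuron_b, rho, n_bins (skipped neurons
#'   carry NA rho and the reason).
#' @export
spatial_correlation_across_sessions <- function(maps_a, maps_b, registry,
                                                min_bins = 10L) {
  rows <- lapply(seq_len(nrow(registry)), function(i) {
    na <- as.character(registry$neuron_a[i])
    nb <- as.character(registry$neuron_b[i])
    ma <- maps_a[[na]]; mb <- maps_b[[nb]]
    if (is.null(ma) || is.null(mb))
      return(data.frame(neuron_a = na, neuron_b = nb, rho = NA_real_,
                        n_bins = 0L, reason = "map missing"))
    both <- ma$visited & mb$visited
    if (sum(both) < min_bins)
      return(data.frame(neuron_a = na, neuron_b = nb, rho = NA_real_,
                        n_bins = sum(both),
                        reason = "too few mutually visited bins"))
    rho <- suppressWarnings(
      stats::cor(ma$rate[both], mb$rate[both], method = "spearman"))
    data.frame(neuron_a = na, neuron_b = nb, rho = rho,
               n_bins = sum(both), reason = NA_character_)
  })
  do.call(rbind, rows)
}

#' Lag-wise class comparison with Holm-Bonferroni correction
#'
#' One-sided paired test per day lag that the splitter statistic exceeds
#' the comparison class's over session pairs (signed-rank by default; a
#' sign test is available), Holm-Bonferroni corrected over the tested
#' lags (those with at least \code{min_pairs} session pairs; at most 15
#' lags considered).
#'
#' @param lag integer day lag of each session pair.
#' @param splitter_stat,other_stat paired per-session-pair statistics.
#' @param min_pairs minimum pairs for a lag to be tested (default 5).
#' @param max_lag largest lag considered (default 15).
#' @param test "signed_rank" (default) or "sign".
#' @param alpha family-wise level (default 0.05).
#' @return data.frame: lag, n_pairs, p, p_holm, significant.
#' @export
lag_comparison_test <- function(lag, splitter_stat, other_stat,
                                min_pairs = 5L, max_lag = 15L,
                                test = c("signed_rank", "sign"),
                                alpha = 0.05) {
  test <- match.arg(test)
  keep <- !is.na(lag) & lag >= 1 & lag <= max_lag &
    is.finite(splitter_stat) & is.finite(other_stat)
  lag <- lag[keep]
  d_s <- splitter_stat[keep]; d_o <- other_stat[keep]
  lags <- sort(unique(lag))
  rows <- lapply(lags, function(l) {
    i <- lag == l
    n <- sum(i)
    if (n < min_pairs) return(NULL)
    p <- if (test == "signed_rank") {
      suppressWarnings(stats::wilcox.test(d_s[i], d_o[i], paired = TRUE,
                                          alternative = "greater"))$p.value
    } else {
      dd <- d_s[i] - d_o[i]
      dd <- dd[dd != 0]
      if (length(dd) == 0L) 1 else
        stats::binom.test(sum(dd > 0), length(dd),
                          alternative = "greater")$p.value
    }
    data.frame(lag = l, n_pairs = n, p = p)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L)
    return(data.frame(lag = integer(0), n_pairs = integer(0), p = numeric(0),
                      p_holm = numeric(0), significant = logical(0)))
  tab <- do.call(rbind, rows)
  tab$p_holm <- stats::p.adjust(tab$p, method = "holm")
  tab$significant <- tab$p_holm < alpha
  tab
}
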