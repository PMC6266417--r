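# samples of the settled window: final `window_s` seconds of the
# `post_s`-second test period after the perturbation
settled_window_idx <- function(trace, window_s = 7, post_s = 20) {
  t <- trace$time_s
  tp <- t[attr(trace, "pert_index")]
  if (t[length(t)] < tp + post_s - 1e-9) {
    stop("trace does not cover the full ", post_s, " s post-perturbation window")
  }
  which(t >= tp + post_s - window_s - 1e-9 & t <= tp + post_s + 1e-9)
}

post_window_idx <- function(trace, post_s = 20) {
  t <- trace$time_s
  ip <- attr(trace, "pert_index")
  which(t >= t[ip] - 1e-9 & t <= t[ip] + post_s + 1e-9)
}

#' Residual-sway threshold of a perturbation trial
#'
#' The maximum excursion of the x channel during the regained-balance phase:
#' the final `window_s` seconds of the `post_s`-second test period after the
#' perturbation. Excursion is measured about the mean of the same window
#' (the settled baseline), so the statistic is invariant to a constant
#' offset in the channel.
#'
#' @param trace A [balance_trace()].
#' @param window_s Length of the regained-balance window, seconds.
#' @param post_s Test period after the perturbation, seconds.
#' @return Threshold in platform units (scalar, >= 0).
#' @export
compute_threshold <- function(trace, window_s = 7, post_s = 20) {
  stopifnot(inherits(trace, "balance_trace"))
  if (window_s > post_s) stop("settled window longer than the test period")
  iw <- settled_window_idx(trace, window_s, post_s)
  if (length(iw) < 2) stop("settled window shorter than ", window_s, " s")
  xw <- trace$x[iw]
  max(abs(xw - mean(xw)))
}

#' Time to regain balance
#'
#' With `mode = "settling"` (default): the time from perturbation onset
#' until the x-excursion peak has decayed permanently inside the threshold
#' band, i.e. the first sample at or after the post-perturbation excursion
#' peak from which `|x - baseline| <= threshold` holds through the end of
#' the test period. A trace that still exceeds the threshold at the last
#' sample gets `time = post_s` and is flagged unsettled. With
#' `mode = "first-crossing"`: the time until the excursion first reaches
#' the threshold value after the perturbation.
#'
#' @param trace A [balance_trace()].
#' @param threshold Threshold from [compute_threshold()].
#' @param mode Settling (permanence) or first-crossing interpretation.
#' @param window_s,post_s Window definition, as in [compute_threshold()].
#' @return Time in seconds, with attributes `settled` (logical) and
#'   `index` (sample index at which balance is regained).
#' @export
compute_time <- function(trace, threshold, mode = c("settling", "first-crossing"),
                         window_s = 7, post_s = 20) {
  stopifnot(inherits(trace, "balance_trace"), threshold >= 0)
  mode <- match.arg(mode)
  iw <- settled_window_idx(trace, window_s, post_s)
  base <- mean(trace$x[iw])
  ip <- post_window_idx(trace, post_s)
  exc <- abs(trace$x[ip] - base)
  t <- trace$time_s[ip]
  settled <- TRUE
  if (mode == "first-crossing") {
    hit <- which(exc >= threshold - 1e-12)
    i_reach <- if (length(hit) > 0) hit[1] else length(exc)
  } else {
    i_peak <- which.max(exc)
    over <- which(exc > threshold + 1e-12)
    over <- over[over >= i_peak]
    if (length(over) == 0) {
      i_reach <- i_peak
    } else if (over[length(over)] == length(exc)) {
      i_reach <- length(exc)
      settled <- FALSE
    } else {
      i_reach <- over[length(over)] + 1L
    }
  }
  out <- t[i_reach] - t[1]
  attr(out, "settled") <- settled
  attr(out, "index") <- ip[i_reach]
  out
}

#' Path length (distance) of a perturbation response
#'
#' Total variation of the chosen channel between the perturbation sample
#' and the sample where balance is regained:
#' `sum(abs(diff(s)))` over the window.
#'
#' @param trace A [balance_trace()].
#' @param settle_index Sample index where balance is regained (the `index`
#'   attribute of [compute_time()]).
#' @param axis `"x"` or `"y"`.
#' @return Distance in platform units.
#' @export
compute_distance <- function(trace, settle_index, axis = c("x", "y")) {
  stopifnot(inherits(trace, "balance_trace"))
  axis <- match.arg(axis)
  ip <- attr(trace, "pert_index")
  if (settle_index <= ip) stop("settle_index must lie after the perturbation")
  idx <- ip:settle_index
  if (length(idx) < 2) stop("fewer than 2 samples between perturbation and threshold")
  s <- trace[[axis]][idx]
  sum(abs(diff(s)))
}

#' Rectified area of a perturbation response
#'
#' Trapezoidal integral of the excursion `|s(t) - baseline|` between the
#' perturbation sample and the sample where balance is regained, where the
#' baseline is the settled-window mean of the channel. Rectification makes
#' oscillation half-waves accumulate instead of cancelling; `signed = TRUE`
#' integrates the raw deviation instead (sensitivity variant).
#'
#' @param trace A [balance_trace()].
#' @param settle_index Sample index where balance is regained.
#' @param axis `"x"` or `"y"`.
#' @param signed Integrate the signed deviation instead of its magnitude.
#' @param window_s,post_s Settled-window definition for the baseline.
#' @return Area in platform units x seconds.
#' @export
compute_area <- function(trace, settle_index, axis = c("x", "y"),
                         signed = FALSE, window_s = 7, post_s = 20) {
  stopifnot(inherits(trace, "balance_trace"))
  axis <- match.arg(axis)
  ip <- attr(trace, "pert_index")
  if (settle_index <= ip) stop("settle_index must lie after the perturbation")
  idx <- ip:settle_index
  if (length(idx) < 2) stop("fewer than 2 samples between perturbation and threshold")
  iw <- settled_window_idx(trace, window_s, post_s)
  base <- mean(trace[[axis]][iw])
  dev <- trace[[axis]][idx] - base
  if (!signed) dev <- abs(dev)
  tt <- trace$time_s[idx]
  sum(diff(tt) * (dev[-1] + dev[-length(dev)]) / 2)
}

#' All four balance metrics of one trial
#'
#' Computes threshold, time, distance (x and y) and area (x and y) for a
#' perturbation trial.
#'
#' @param trace A [balance_trace()].
#' @param settle_mode Interpretation of "reaching the threshold", see
#'   [compute_time()].
#' @param signed_area See [compute_area()].
#' @param window_s,post_s Window definition.
#' @return A one-row tibble of class `balance_metrics` with columns `leg`,
#'   `direction`, `threshold`, `time`, `distance_x`, `distance_y`, `area_x`,
#'   `area_y`, `settled`.
#' @export
balance_metrics <- function(trace, settle_mode = "settling",
                            signed_area = FALSE, window_s = 7, post_s = 20) {
  thr <- compute_threshold(trace, window_s, post_s)
  tm <- compute_time(trace, thr, mode = settle_mode, window_s = window_s,
                     post_s = post_s)
  si <- attr(tm, "index")
  out <- tibble::tibble(
    leg = attr(trace, "leg"), direction = attr(trace, "direction"),
    threshold = thr, time = as.numeric(tm),
    distance_x = compute_distance(trace, si, "x"),
    distance_y = compute_distance(trace, si, "y"),
    area_x = compute_area(trace, si, "x", signed = signed_area,
                          window_s = window_s, post_s = post_s),
    area_y = compute_area(trace, si, "y", signed = signed_area,
                          window_s = window_s, post_s = post_s),
    settled = attr(tm, "settled")
  )
  class(out) <- c("balance_metrics", class(out))
  out
}

#' Aggregate trial metrics to legs and subject
#'
#' Each leg must have its medial and its lateral trial; each metric is
#' averaged over the two trials per leg, and the subject value is the mean
#' of the two leg values.
#'
#' @param metrics A tibble of trial rows as returned by [balance_metrics()]
#'   (rows may be bound together), with `leg` and `direction` columns.
#' @return List with `trials`, `legs` (one row per leg) and `subject`
#'   (one row) tibbles.
#' @export
aggregate_trials <- function(metrics) {
  need <- expand.grid(leg = c("left", "right"),
                      direction = c("medial", "lateral"),
                      stringsAsFactors = FALSE)
  have <- unique(metrics[, c("leg", "direction")])
  miss <- need[!paste(need$leg, need$direction) %in%
                 paste(have$leg, have$direction), ]
  if (nrow(miss) > 0) {
    stop("missing trial(s): ",
         paste(sprintf("(%s, %s)", miss$leg, miss$direction), collapse = ", "))
  }
  vars <- c("threshold", "time", "distance_x", "distance_y", "area_x", "area_y")
  legs <- do.call(rbind, lapply(c("left", "right"), function(l) {
    m <- metrics[metrics$leg == l, vars]
    cbind(tibble::tibble(leg = l), tibble::as_tibble(as.list(colMeans(m))))
  }))
  legs <- tibble::as_tibble(legs)
  subject <- tibble::as_tibble(as.list(colMeans(legs[, vars])))
  list(trials = metrics, legs = legs, subject = subject)
}
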