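#' Root mean square of successive differences
#'
#' The time-domain heart-rate-variability index
#' `sqrt(mean((x[i+1] - x[i])^2))` over the n-1 successive interval
#' pairs, in milliseconds.
#'
#' @param intervals numeric vector of interbeat intervals (ms), length
#'   >= 2, or an [ibi_series()].
#' @return RMSSD in ms.
#' @export
rmssd <- function(intervals) {
  if (inherits(intervals, "ibi_series")) intervals <- intervals$intervals
  if (length(intervals) < 2) {
    stop("RMSSD needs at least 2 intervals", call. = FALSE)
  }
  sqrt(mean(diff(intervals)^2))
}

## contiguous spans (seconds of day) during which the behaviour stays in
## `states`; events are half-open and non-overlapping
behavior_spans <- function(events, states, tol = 1e-6) {
  ev <- events[events$behavior %in% states, , drop = FALSE]
  if (nrow(ev) == 0) return(data.frame(start = numeric(), end = numeric()))
  ev <- ev[order(ev$start), , drop = FALSE]
  s <- ev$start[1]; e <- ev$end[1]
  out <- list()
  if (nrow(ev) > 1) {
    for (i in 2:nrow(ev)) {
      if (ev$start[i] <= e + tol) {
        e <- max(e, ev$end[i])
      } else {
        out[[length(out) + 1L]] <- c(s, e)
        s <- ev$start[i]; e <- ev$end[i]
      }
    }
  }
  out[[length(out) + 1L]] <- c(s, e)
  data.frame(start = vapply(out, `[`, 0, 1), end = vapply(out, `[`, 0, 2))
}

## intervals of `series` whose onset falls in [t0, t0 + len_s) seconds of day
window_excerpt <- function(series, t0, len_s = 300) {
  clock_onset <- start_seconds(series) + onset(series)
  series$intervals[clock_onset >= t0 & clock_onset < t0 + len_s]
}

## does the series cover [t0, t0 + len_s] in clock seconds?
covers_window <- function(series, t0, len_s = 300) {
  s0 <- start_seconds(series)
  s1 <- s0 + sum(series$intervals) / 1000
  s0 <= t0 + 1e-9 && s1 >= t0 + len_s - 1e-9
}

## QC verdict for the 5-min excerpt starting at clock second t0.
## With precomputed grid verdicts (from qc_session), the excerpt passes
## iff every overlapping grid window was accepted; otherwise QC is run on
## the excerpt itself.  Returns RMSSD (corrected scale) or NULL.
qc_window_rmssd <- function(series, t0, qc, qc_windows = NULL, len_s = 300) {
  if (!covers_window(series, t0, len_s)) return(NULL)
  if (!is.null(qc_windows)) {
    g0 <- start_seconds(series) + qc_windows$start_s
    g1 <- g0 + len_s
    hit <- which(g1 > t0 & g0 < t0 + len_s)
    if (length(hit) == 0 || !all(qc_windows$accepted[hit])) return(NULL)
    x <- window_excerpt(series, t0, len_s)
    if (length(x) < 2) return(NULL)
    return(rmssd(x))
  }
  x <- window_excerpt(series, t0, len_s)
  if (length(x) < 2) return(NULL)
  res <- ibi_qc(x, qc)
  if (!res$report$accepted || length(res$intervals) < 2) return(NULL)
  rmssd(res$intervals)
}

#' Select the 5-min analysis window for a behavioural state
#'
#' Finds the earliest 5-min span inside the scheduled clock window
#' (activity: noon-3 p.m., qualifying behaviours feeding/locomotion;
#' rest: 9 p.m.-midnight, qualifying behaviour lying) during which the
#' qualifying behaviour is continuous for the full 5 min and the
#' interbeat-interval excerpt passes window QC.  Candidate starts are
#' each qualifying span's start, then `step_s` steps within the span;
#' absence of any qualifying window is a legitimate outcome (`NULL`),
#' mirroring the missing-data mechanism of the study.
#'
#' @param series an [ibi_series()] covering (part of) the scheduled
#'   window; raw, or corrected when `qc_windows` is supplied.
#' @param events behaviour events of the same cow-day (seconds of day).
#' @param state `"active"` or `"rest"`.
#' @param schedule an [obs_schedule()].
#' @param qc QC constants, see [herd_config()].
#' @param qc_windows optional grid-window QC table from [qc_session()]
#'   (then `series` should be the corrected series).
#' @param step_s candidate start-time step within a span, seconds.
#' @return `NULL`, or a list with `t0` (window start, s of day), `rmssd`
#'   (ms) and `state`.
#' @export
select_state_window <- function(series, events, state,
                                schedule = default_schedule(),
                                qc = herd_config()$qc, qc_windows = NULL,
                                step_s = 60) {
  state <- match.arg(state, c("active", "rest"))
  win <- if (state == "active") schedule$activity_window else schedule$rest_window
  states <- if (state == "active") c("feeding", "locomotion") else "lying"
  w0 <- win[1] * 3600; w1 <- win[2] * 3600
  spans <- behavior_spans(events, states)
  spans$start <- pmax(spans$start, w0)
  spans$end <- pmin(spans$end, w1)
  spans <- spans[spans$end - spans$start >= 300 - 1e-9, , drop = FALSE]
  for (i in seq_len(nrow(spans))) {
    t0s <- seq(spans$start[i], spans$end[i] - 300, by = step_s)
    for (t0 in t0s) {
      r <- qc_window_rmssd(series, t0, qc, qc_windows)
      if (!is.null(r)) {
        return(list(t0 = t0, rmssd = r, state = state))
      }
    }
  }
  NULL
}

#' Pair near/far robot-proximity windows for a lying cow
#'
#' For each robot route pass (in order), the near window is the 5 min
#' centred on the pass's distance minimum (2.5 min before to 2.5 min
#' after) and the far window the 5 min centred on its maximum.  A window
#' qualifies only when it lies wholly inside the proximity schedule
#' window (an extremum within 2.5 min of the boundary discards that
#' window), the cow is lying throughout, and the interbeat excerpt
#' passes QC.  Near and far may come from the same pass but must not
#' overlap — an overlapping far window is taken from the next pass.  The
#' first pass yielding a complete pair wins; ties between equal extrema
#' resolve to the earliest time.
#'
#' @inheritParams select_state_window
#' @param distance data.frame with `time` (s of day, 1-s sampling),
#'   `distance` (m) and `pass` (route-pass index), as produced by
#'   [gen_robot_distance()] or [read_distance_csv()].
#' @return `NULL`, or a list with `near_t0`, `far_t0` (window starts),
#'   `near_time`, `far_time` (extremum times), `near_rmssd`, `far_rmssd`
#'   (ms) and `pass`.
#' @export
pair_proximity_windows <- function(series, events, distance,
                                   schedule = default_schedule(),
                                   qc = herd_config()$qc,
                                   qc_windows = NULL) {
  w0 <- schedule$proximity_window[1] * 3600
  w1 <- schedule$proximity_window[2] * 3600
  lying <- behavior_spans(events, "lying")
  ok_lying <- function(t0) {
    any(lying$start <= t0 + 1e-9 & lying$end >= t0 + 300 - 1e-9)
  }
  try_window <- function(t_ext) {
    t0 <- t_ext - 150
    if (t0 < w0 - 1e-9 || t0 + 300 > w1 + 1e-9) return(NULL)
    if (!ok_lying(t0)) return(NULL)
    r <- qc_window_rmssd(series, t0, qc, qc_windows)
    if (is.null(r)) NULL else list(t0 = t0, time = t_ext, rmssd = r)
  }
  passes <- sort(unique(distance$pass))
  ext_of <- function(p, which) {
    d <- distance[distance$pass == p, ]
    i <- if (which == "min") which.min(d$distance) else which.max(d$distance)
    d$time[i]                            # which.min/max: earliest tie wins
  }
  for (pi in seq_along(passes)) {
    p <- passes[pi]
    near <- try_window(ext_of(p, "min"))
    if (is.null(near)) next
    far <- try_window(ext_of(p, "max"))
    if (!is.null(far) &&
        interval_overlap(near$t0, near$t0 + 300, far$t0, far$t0 + 300) > 0) {
      far <- NULL
      if (pi < length(passes)) far <- try_window(ext_of(passes[pi + 1], "max"))
    }
    if (!is.null(far)) {
      return(list(near_t0 = near$t0, far_t0 = far$t0,
                  near_time = near$time, far_time = far$time,
                  near_rmssd = near$rmssd, far_rmssd = far$rmssd,
                  pass = p))
    }
  }
  NULL
}
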