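#' Observation and measurement schedule
#'
#' The daily clock schedule of the study: three behavioural observation
#' windows totalling 14 h, the activity window used for RMSSD during
#' physical activity, the rest window used for RMSSD at rest, and the
#' window within which robot-proximity pairs are selected.  All intervals
#' are half-open `[start, end)` in decimal hours of a timezone-naive
#' local day, so "to midnight" is `end = 24` without double counting.
#'
#' @param behavior_windows list of numeric length-2 vectors, decimal hours.
#' @param activity_window,rest_window,proximity_window numeric length-2
#'   vectors, decimal hours.
#' @return An object of class `obs_schedule`.
#' @examples
#' sch <- default_schedule()
#' total_observation_minutes(sch)  # 840
#' @export
obs_schedule <- function(behavior_windows = list(c(0, 4), c(10, 15), c(19, 24)),
                         activity_window = c(12, 15),
                         rest_window = c(21, 24),
                         proximity_window = c(10, 15)) {
  check_win <- function(w, nm) {
    if (!is.numeric(w) || length(w) != 2 || any(is.na(w)) ||
        w[1] < 0 || w[2] > 24 || w[2] <= w[1]) {
      stop("invalid clock window '", nm, "': need 0 <= start < end <= 24",
           call. = FALSE)
    }
    as.numeric(w)
  }
  behavior_windows <- lapply(seq_along(behavior_windows), function(i) {
    check_win(behavior_windows[[i]], paste0("behavior_windows[", i, "]"))
  })
  if (length(behavior_windows) > 1) {
    starts <- vapply(behavior_windows, `[`, 0, 1)
    ord <- order(starts)
    bw <- behavior_windows[ord]
    for (i in seq_len(length(bw) - 1)) {
      if (bw[[i + 1]][1] < bw[[i]][2]) {
        stop("behavior windows overlap: [", bw[[i]][1], ", ", bw[[i]][2],
             ") and [", bw[[i + 1]][1], ", ", bw[[i + 1]][2], ")",
             call. = FALSE)
      }
    }
    behavior_windows <- bw
  }
  structure(
    list(behavior_windows = behavior_windows,
         activity_window = check_win(activity_window, "activity_window"),
         rest_window = check_win(rest_window, "rest_window"),
         proximity_window = check_win(proximity_window, "proximity_window")),
    class = "obs_schedule")
}

#' @rdname obs_schedule
#' @export
default_schedule <- function() obs_schedule()

#' Total scheduled observation time
#'
#' Sum of the behavioural observation window durations, in minutes.
#' The study schedule (midnight-4 a.m., 10 a.m.-3 p.m., 7 p.m.-midnight)
#' gives 840 min = 14 h.
#'
#' @param schedule an [obs_schedule()].
#' @return minutes (numeric scalar).
#' @export
total_observation_minutes <- function(schedule) {
  stopifnot(inherits(schedule, "obs_schedule"))
  if (length(schedule$behavior_windows) == 0) return(0)
  sum(vapply(schedule$behavior_windows, function(w) (w[2] - w[1]) * 60, 0))
}

#' @export
print.obs_schedule <- function(x, ...) {
  fmt <- function(w) sprintf("%05.2f-%05.2f h", w[1], w[2])
  cat("Observation schedule (half-open clock intervals)\n")
  cat("  behavior: ", paste(vapply(x$behavior_windows, fmt, ""),
                            collapse = ", "),
      sprintf("  (%g min total)\n", total_observation_minutes(x)))
  cat("  activity: ", fmt(x$activity_window), "\n")
  cat("  rest:     ", fmt(x$rest_window), "\n")
  cat("  proximity:", fmt(x$proximity_window), "\n")
  invisible(x)
}

## intersection length of [a1,a2) with [b1,b2), same units
interval_overlap <- function(a1, a2, b1, b2) {
  pmax(0, pmin(a2, b2) - pmax(a1, b1))
}
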