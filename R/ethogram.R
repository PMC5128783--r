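#' Compute a per-cow-day time budget
#'
#' Occupancy per ethogram behaviour over the scheduled observation
#' windows, in minutes: each event is clipped to the windows (events
#' crossing a window boundary are clipped, not dropped) and time falling
#' into exclusion intervals (milking, measurement handling) is
#' subtracted.  `standing_total` is derived as standing in the cubicle
#' plus standing in the walking area; `other` is the observed time not
#' covered by the five ethogram states, so the components always
#' partition the observed day.
#'
#' @param events behaviour events of one cow-day (data.frame with
#'   `behavior`, `start`, `end` in seconds of day; optionally `cow`,
#'   `farm`, `period`, `day` labels, carried through).
#' @param schedule an [obs_schedule()].
#' @param exclusions list of numeric length-2 clock windows (decimal
#'   hours, half-open) to exclude.
#' @return one-row data.frame: labels, minutes per behaviour,
#'   `standing_total`, `other`, and `observed` (total observed minutes).
#' @export
compute_time_budget <- function(events, schedule = default_schedule(),
                                exclusions = list()) {
  stopifnot(inherits(schedule, "obs_schedule"))
  wins <- lapply(schedule$behavior_windows, function(w) w * 3600)
  excl <- lapply(exclusions, function(w) w * 3600)
  credit <- function(s, e) {             # vectorized over events
    tot <- 0
    for (w in wins) {
      ov <- interval_overlap(s, e, w[1], w[2])
      cs <- pmax(s, w[1]); ce <- pmin(e, w[2])
      cut <- numeric(length(ov))
      for (x in excl) cut <- cut + interval_overlap(cs, ce, x[1], x[2])
      tot <- tot + sum(ov) - sum(cut[ov > 0])
    }
    tot / 60
  }
  beh <- setdiff(.behaviors, "other")
  mins <- vapply(beh, function(b) {
    idx <- events$behavior == b
    if (!any(idx)) return(0)
    credit(events$start[idx], events$end[idx])
  }, 0)
  observed <- total_observation_minutes(schedule) -
    sum(vapply(excl, function(x) {
      sum(vapply(wins, function(w) {
        interval_overlap(w[1], w[2], x[1], x[2])
      }, 0))
    }, 0)) / 60
  out <- data.frame(
    cow = events$cow[1] %||% NA, farm = events$farm[1] %||% NA,
    period = events$period[1] %||% NA, day = events$day[1] %||% NA,
    lying = mins[["lying"]], feeding = mins[["feeding"]],
    standing_cubicle = mins[["standing_cubicle"]],
    standing_walkway = mins[["standing_walkway"]],
    locomotion = mins[["locomotion"]],
    stringsAsFactors = FALSE)
  out$standing_total <- out$standing_cubicle + out$standing_walkway
  out$other <- observed - sum(mins)
  out$observed <- observed
  if (out$other < -1e-6) {
    stop("events exceed the observable time; overlapping log?", call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Time budgets for a whole behaviour log
#'
#' Applies [compute_time_budget()] per cow-day group of a multi-animal
#' event log.
#'
#' @param events behaviour events (several cow-days), as from
#'   [read_behavior_csv()] or [gen_behavior_log()].
#' @inheritParams compute_time_budget
#' @return data.frame, one row per farm-cow-period-day.
#' @export
budgets_from_log <- function(events, schedule = default_schedule(),
                             exclusions = list()) {
  if (is.null(events$period)) events$period <- "B"
  if (is.null(events$day)) events$day <- 1L
  key <- paste(events$farm, events$cow, events$period, events$day,
               sep = "\r")
  out <- lapply(unique(key), function(k) {
    compute_time_budget(events[key == k, , drop = FALSE], schedule,
                        exclusions)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
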