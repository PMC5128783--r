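#' Detect erroneous interbeat intervals
#'
#' Sequential (left-to-right) screen of successive interbeat intervals:
#' interval i is flagged as erroneous when it deviates from the running
#' reference by more than `threshold` (default 20% greater or smaller).
#' The reference is the corrected value of the preceding interval — a
#' flagged interval does not update it — so one artifact does not cascade
#' into flags on its normal successors.  The first interval is never
#' flagged.
#'
#' @param intervals numeric vector of interval durations (ms), length >= 2,
#'   or an [ibi_series()].
#' @param threshold relative deviation triggering a flag (default 0.20).
#' @return logical vector of flags, same length as the series.
#' @export
detect_errors <- function(intervals, threshold = 0.20) {
  if (inherits(intervals, "ibi_series")) intervals <- intervals$intervals
  n <- length(intervals)
  if (n < 2) stop("need at least 2 intervals to screen", call. = FALSE)
  stopifnot(threshold > 0, threshold < 1)
  flags <- logical(n)
  ref <- intervals[1]
  for (i in 2:n) {
    if (abs(intervals[i] - ref) > threshold * ref) {
      flags[i] <- TRUE
    } else {
      ref <- intervals[i]
    }
  }
  flags
}

## runs of consecutive TRUE values -> data.frame(start, end, length)
flag_runs <- function(flags) {
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep],
             length = r$lengths[keep])
}

## median of the `k` most recent unflagged intervals before position i,
## falling back to the median of all unflagged intervals, then the series
local_median <- function(intervals, flags, i, k = 5L) {
  prev <- which(!flags[seq_len(i - 1L)])
  if (length(prev) >= 1L) {
    return(stats::median(intervals[utils::tail(prev, k)]))
  }
  unf <- intervals[!flags]
  if (length(unf)) stats::median(unf) else stats::median(intervals)
}

#' Classify flagged intervals into the five error types
#'
#' Each maximal run of consecutive flags is typed against a robust local
#' baseline (median of the most recent unflagged intervals):
#' a run of two flags that straddles the baseline (one wide, one narrow)
#' and sums to about twice it is a boundary-shift error (type 2/3); a run
#' of two flags both well below the baseline that sum to about one
#' baseline interval is a spurious extra beat (type 5); a single flag far
#' above the baseline is a missed beat (type 4); any other single flag is
#' a lone deviating value (type 1).  Runs of three or more flags are left
#' untyped — such windows are rejected outright rather than corrected.
#'
#' @param intervals numeric vector (ms) or [ibi_series()].
#' @param flags logical flags from [detect_errors()].
#' @param qc QC constants, see [herd_config()] (`threshold`,
#'   `type4_factor`, `type5_factor`, `median_window`).
#' @return data.frame with one row per interval: `index`, `flagged`,
#'   `error_type` in `none`, `1`, `2/3`, `4`, `5`, `untyped`, and `run`
#'   (run id, 0 for unflagged).
#' @export
classify_errors <- function(intervals, flags, qc = herd_config()$qc) {
  if (inherits(intervals, "ibi_series")) intervals <- intervals$intervals
  stopifnot(length(flags) == length(intervals))
  ann <- data.frame(index = seq_along(intervals), flagged = flags,
                    error_type = ifelse(flags, "untyped", "none"),
                    run = 0L, stringsAsFactors = FALSE)
  runs <- flag_runs(flags)
  thr <- qc$threshold
  for (r in seq_len(nrow(runs))) {
    i <- runs$start[r]; j <- runs$end[r]
    ann$run[i:j] <- r
    if (runs$length[r] >= 3L) next    # untyped: window will be rejected
    m <- local_median(intervals, flags, i, qc$median_window)
    if (runs$length[r] == 2L) {
      x1 <- intervals[i]; x2 <- intervals[j]
      straddle <- (x1 > m && x2 < m) || (x1 < m && x2 > m)
      if (straddle && abs(x1 + x2 - 2 * m) <= thr * 2 * m) {
        ann$error_type[i:j] <- "2/3"
      } else if (x1 < qc$type5_factor * m && x2 < qc$type5_factor * m &&
                 abs(x1 + x2 - m) <= thr * m) {
        ann$error_type[i:j] <- "5"
      }                               # else: untyped pair
    } else {                          # single flag
      if (intervals[i] > qc$type4_factor * m) {
        ann$error_type[i] <- "4"
      } else {
        ann$error_type[i] <- "1"
      }
    }
  }
  ann
}

#' Correct a typed interbeat-interval series
#'
#' Applies the prescribed correction per typed error run: a lone
#' deviating interval (type 1) is replaced by linear interpolation
#' between its flanking unflagged intervals (their mean); a
#' boundary-shift pair (type 2/3) is merged and halved; a missed-beat
#' interval (type 4) is split into two halves; a spurious-beat pair
#' (type 5) is merged into one interval.  Types 2-5 conserve the summed
#' duration exactly.  Flagged intervals at the series boundary and
#' untyped runs are dropped rather than corrected; dropping is recorded.
#'
#' @inheritParams classify_errors
#' @param annotation data.frame from [classify_errors()].
#' @param window_id label carried into the report.
#' @return list with `intervals` (corrected numeric vector), `report`
#'   (one-row data.frame, see [accept_window()]), and `annotation` with a
#'   `correction` column (`none`, `interpolate`, `merge_halve`, `split`,
#'   `merge`, `drop`).
#' @export
correct_series <- function(intervals, annotation, qc = herd_config()$qc,
                           window_id = "w") {
  if (inherits(intervals, "ibi_series")) intervals <- intervals$intervals
  n <- length(intervals)
  if (nrow(annotation) != n || !all(annotation$index == seq_len(n))) {
    stop("annotation does not match the series", call. = FALSE)
  }
  flags <- annotation$flagged
  if (any(annotation$error_type != "none" & !flags)) {
    stop("inconsistent annotation: typed but unflagged interval",
         call. = FALSE)
  }
  runs <- flag_runs(flags)
  annotation$correction <- "none"
  out <- vector("list", n)
  for (i in which(!flags)) out[[i]] <- intervals[i]
  for (r in seq_len(nrow(runs))) {
    i <- runs$start[r]; j <- runs$end[r]
    type <- annotation$error_type[i]
    at_boundary <- i == 1L || j == n
    if (at_boundary || type == "untyped") {
      annotation$correction[i:j] <- "drop"
      next                                   # out[[..]] stays NULL
    }
    if (type == "1") {
      prev <- max(which(!flags[seq_len(i - 1L)]))
      nxt <- j + min(which(!flags[(j + 1L):n]))
      out[[i]] <- (intervals[prev] + intervals[nxt]) / 2
      annotation$correction[i] <- "interpolate"
    } else if (type == "2/3") {
      h <- (intervals[i] + intervals[j]) / 2
      out[[i]] <- h; out[[j]] <- h
      annotation$correction[i:j] <- "merge_halve"
    } else if (type == "4") {
      out[[i]] <- rep(intervals[i] / 2, 2)
      annotation$correction[i] <- "split"
    } else if (type == "5") {
      out[[i]] <- intervals[i] + intervals[j]
      annotation$correction[i:j] <- "merge"
    }
  }
  corrected <- unlist(out)
  report <- data.frame(
    window = window_id,
    total = n,
    flagged = sum(flags),
    error_rate = sum(flags) / n,
    max_run = if (nrow(runs)) max(runs$length) else 0L,
    stringsAsFactors = FALSE)
  report$accepted <- accept_window(report, qc)
  list(intervals = corrected, report = report, annotation = annotation)
}

#' Accept or reject a 5-min analysis window
#'
#' A window is used only when its corrected error rate (flagged intervals
#' over total intervals) is below `max_error_rate` (default 5%) and it
#' contains no run of `max_consecutive` (default 3) or more erroneous
#' intervals.
#'
#' @param report one-row data.frame with `total`, `flagged`, `max_run`
#'   (from [correct_series()] or [qc_session()]).
#' @param qc QC constants, see [herd_config()].
#' @return logical.
#' @export
accept_window <- function(report, qc = herd_config()$qc) {
  (report$flagged / report$total) < qc$max_error_rate &
    report$max_run < qc$max_consecutive
}

#' Run detection, classification and correction in one step
#'
#' @param intervals numeric vector (ms) or [ibi_series()].
#' @param qc QC constants.
#' @param window_id label for the report.
#' @return as [correct_series()].
#' @export
ibi_qc <- function(intervals, qc = herd_config()$qc, window_id = "w") {
  if (inherits(intervals, "ibi_series")) intervals <- intervals$intervals
  flags <- detect_errors(intervals, qc$threshold)
  ann <- classify_errors(intervals, flags, qc)
  correct_series(intervals, ann, qc, window_id)
}

#' QC a whole session on a fixed 5-min grid
#'
#' Detects, classifies and corrects over the full session, then reports
#' acceptance per consecutive 5-min grid window (anchored at the session
#' start): intervals are assigned to grid windows by onset, flag counts
#' and maximal flag runs are computed per window on the pre-correction
#' series, and the QC verdict applies the usual thresholds.
#'
#' @param series an [ibi_series()].
#' @param qc QC constants.
#' @param window_s grid window length in seconds (default 300).
#' @return list: `series` (corrected [ibi_series()]), `windows`
#'   (data.frame: window id, start_s, total, flagged, error_rate,
#'   max_run, accepted), `annotation`.
#' @export
qc_session <- function(series, qc = herd_config()$qc, window_s = 300) {
  stopifnot(inherits(series, "ibi_series"))
  x <- series$intervals
  flags <- detect_errors(x, qc$threshold)
  ann <- classify_errors(x, flags, qc)
  cor <- correct_series(x, ann, qc, window_id = series$session)
  ons <- onset(series)
  win <- floor(ons / window_s)
  ids <- sort(unique(win))
  rows <- lapply(ids, function(w) {
    idx <- which(win == w)
    fr <- flag_runs(flags[idx])
    data.frame(window = sprintf("%s_w%03d", series$session, w),
               start_s = w * window_s, total = length(idx),
               flagged = sum(flags[idx]),
               error_rate = sum(flags[idx]) / length(idx),
               max_run = if (nrow(fr)) max(fr$length) else 0L,
               stringsAsFactors = FALSE)
  })
  windows <- do.call(rbind, rows)
  windows$accepted <- accept_window(windows, qc)
  corrected <- ibi_series(cor$intervals, start = series$start,
                          cow = series$cow, session = series$session)
  list(series = corrected, windows = windows, annotation = cor$annotation)
}
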