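#' Interbeat-interval series
#'
#' A timestamped sequence of interbeat (RR) intervals for one cow-session.
#' `onset(x)` gives each interval's onset in seconds since the session
#' start (the onset of interval i is the cumulative sum of the preceding
#' intervals), so intervals can be matched against clock windows.
#'
#' @param intervals numeric vector of interval durations, ms, all > 0.
#' @param start session start, POSIXct or ISO-8601 string (timezone-naive,
#'   parsed as UTC).
#' @param cow,session identifying labels.
#' @return object of class `ibi_series`.
#' @export
ibi_series <- function(intervals, start, cow = "cow", session = "session") {
  intervals <- as.numeric(intervals)
  if (length(intervals) == 0) stop("no intervals", call. = FALSE)
  if (anyNA(intervals) || any(intervals <= 0)) {
    stop("intervals must all be positive numbers", call. = FALSE)
  }
  if (is.character(start)) start <- parse_iso_time(start)
  stopifnot(inherits(start, "POSIXct"), length(start) == 1L)
  structure(list(cow = as.character(cow), session = as.character(session),
                 start = start, intervals = intervals),
            class = "ibi_series")
}

parse_iso_time <- function(s) {
  s <- sub("T", " ", s, fixed = TRUE)
  t <- as.POSIXct(s, tz = "UTC",
                  tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M"))
  if (is.na(t)) stop("cannot parse ISO timestamp: ", s, call. = FALSE)
  t
}

#' @rdname ibi_series
#' @param x an `ibi_series`.
#' @export
onset <- function(x) {
  stopifnot(inherits(x, "ibi_series"))
  cumsum(c(0, x$intervals[-length(x$intervals)])) / 1000
}

#' @export
length.ibi_series <- function(x) length(x$intervals)

#' @export
print.ibi_series <- function(x, ...) {
  cat(sprintf("ibi_series: cow %s, session %s, start %s\n  %d intervals, %.3f s, mean IBI %.1f ms\n",
              x$cow, x$session, format(x$start, "%Y-%m-%d %H:%M:%S"),
              length(x$intervals), sum(x$intervals) / 1000,
              mean(x$intervals)))
  invisible(x)
}

## clock seconds-of-day of the session start
start_seconds <- function(x) {
  as.numeric(x$start) - as.numeric(as.POSIXct(format(x$start, "%Y-%m-%d"),
                                              tz = "UTC"))
}

#' Read / write the plain-text IBI format
#'
#' Line 1 is a header `cow,session,start-ISO-timestamp`; every following
#' line is one interval duration in milliseconds.  This simple dialect
#' stands in for the proprietary download format of telemetric heart-rate
#' monitors and round-trips byte-identically through
#' `write_ibi_file(read_ibi_file(f))`.
#'
#' @param path file path.
#' @return `read_ibi_file`: an [ibi_series()].
#' @export
read_ibi_file <- function(path) {
  if (!file.exists(path)) stop("IBI file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || !nzchar(lines[1])) {
    stop("format error in ", path, ": missing header line", call. = FALSE)
  }
  hdr <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  if (length(hdr) != 3) {
    stop("format error in ", path,
         ": header must be 'cow,session,start-timestamp'", call. = FALSE)
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (length(body) == 0) stop("no intervals in ", path, call. = FALSE)
  vals <- suppressWarnings(as.numeric(body))
  bad <- which(is.na(vals) | vals <= 0)
  if (length(bad)) {
    stop("parse error in ", path, " line ", bad[1] + 1L,
         ": interval must be a positive number, got '", body[bad[1]], "'",
         call. = FALSE)
  }
  ibi_series(vals, start = hdr[3], cow = hdr[1], session = hdr[2])
}

#' @rdname read_ibi_file
#' @param series an [ibi_series()].
#' @return `write_ibi_file`: the path, invisibly.
#' @export
write_ibi_file <- function(series, path) {
  stopifnot(inherits(series, "ibi_series"))
  hdr <- paste(series$cow, series$session,
               format(series$start, "%Y-%m-%dT%H:%M:%S"), sep = ",")
  vals <- format(series$intervals, digits = 15, scientific = FALSE,
                 trim = TRUE)
  writeLines(c(hdr, vals), path)
  invisible(path)
}

.behaviors <- c("lying", "standing_cubicle", "standing_walkway",
                "feeding", "locomotion", "other")

## "HH:MM[:SS]" (24:00 allowed) or numeric hours -> seconds of day
parse_clock <- function(s) {
  if (is.numeric(s)) return(s * 3600)
  out <- vapply(s, function(si) {
    p <- strsplit(si, ":", fixed = TRUE)[[1]]
    if (!length(p) %in% 2:3 || anyNA(suppressWarnings(as.numeric(p)))) {
      stop("cannot parse clock time '", si, "' (want HH:MM[:SS])",
           call. = FALSE)
    }
    p <- as.numeric(p)
    sec <- p[1] * 3600 + p[2] * 60 + if (length(p) == 3) p[3] else 0
    if (sec < 0 || sec > 86400) {
      stop("clock time out of range: ", si, call. = FALSE)
    }
    sec
  }, 0, USE.NAMES = FALSE)
  out
}

format_clock <- function(sec) {
  h <- sec %/% 3600; m <- (sec %% 3600) %/% 60; s <- sec %% 60
  ifelse(abs(s - round(s)) < 5e-4,
         sprintf("%02d:%02d:%02d", h, m, round(s)),
         sprintf("%02d:%02d:%06.3f", h, m, s))   # keep sub-second bouts
}

#' Read a behavioural event log
#'
#' CSV with columns `cow, farm, behavior, start, end` (and optionally
#' `day`); `start`/`end` are clock times `HH:MM[:SS]` within one observed
#' day, half-open.  Behaviours must belong to the ethogram (lying,
#' standing_cubicle, standing_walkway, feeding, locomotion, other); the
#' states are mutually exclusive, so overlapping events for one cow-day
#' are an error.
#'
#' @param path CSV path.
#' @return data.frame sorted by cow then start, with `start`/`end` in
#'   seconds of day and `duration_min` in minutes.
#' @export
read_behavior_csv <- function(path) {
  if (!file.exists(path)) stop("behavior file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cow", "farm", "behavior", "start", "end")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("behavior CSV lacks columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (is.null(df$day)) df$day <- 1L
  bad <- setdiff(unique(df$behavior), .behaviors)
  if (length(bad)) {
    stop("unknown behavior label(s) ", paste(sQuote(bad), collapse = ", "),
         "; allowed: ", paste(.behaviors, collapse = ", "), call. = FALSE)
  }
  df$start <- parse_clock(df$start)
  df$end <- parse_clock(df$end)
  if (any(df$end <= df$start)) {
    i <- which(df$end <= df$start)[1]
    stop("event end must exceed start (row ", i, ")", call. = FALSE)
  }
  df <- df[order(df$cow, df$day, df$start), , drop = FALSE]
  rownames(df) <- NULL
  ## overlap check per cow-day (and per period when the log spans periods)
  key <- paste(df$farm, df$cow, df$period %||% "", df$day, sep = "\r")
  for (k in unique(key)) {
    idx <- which(key == k)
    if (length(idx) > 1) {
      s <- df$start[idx]; e <- df$end[idx]
      ov <- which(s[-1] < e[-length(e)])
      if (length(ov)) {
        i <- idx[ov[1]]; j <- idx[ov[1] + 1]
        stop(sprintf(
          "overlapping events for cow %s (day %s): %s %s-%s and %s %s-%s",
          df$cow[i], df$day[i], df$behavior[i], format_clock(df$start[i]),
          format_clock(df$end[i]), df$behavior[j], format_clock(df$start[j]),
          format_clock(df$end[j])), call. = FALSE)
      }
    }
  }
  df$duration_min <- (df$end - df$start) / 60
  df
}

#' @rdname read_behavior_csv
#' @param events data.frame as returned by `read_behavior_csv`.
#' @export
write_behavior_csv <- function(events, path) {
  cols <- intersect(c("cow", "farm", "period", "day", "behavior", "start", "end"),
                    names(events))
  out <- events[cols]
  out$start <- format_clock(out$start)
  out$end <- format_clock(out$end)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a robot-cow distance series
#'
#' CSV with columns `farm, cow, day, time, distance` (`time` seconds of
#' day at 1-s sampling, `distance` metres) and optionally `pass` (robot
#' route-pass index).
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_distance_csv <- function(path) {
  if (!file.exists(path)) stop("distance file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("farm", "cow", "day", "time", "distance")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("distance CSV lacks columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (any(df$distance < 0)) stop("negative distances", call. = FALSE)
  df
}

#' Read a cortisol-metabolite sample table
#'
#' CSV with columns `farm, cow, period, day, value`; `value` is the
#' 11,17-DOA concentration (unitless here), one row per fecal sample.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_cortisol_csv <- function(path) {
  if (!file.exists(path)) stop("cortisol file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("farm", "cow", "period", "day", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("cortisol CSV lacks columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (any(!is.finite(df$value) | df$value <= 0)) {
    stop("cortisol values must be positive", call. = FALSE)
  }
  df
}
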