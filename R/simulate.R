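#' Simulate a full study and write the pipeline input files
#'
#' Generates the complete synthetic study implied by the configuration —
#' per-cow latent values for every response, artifact-contaminated IBI
#' sessions for the activity, rest and proximity windows on the HRV
#' measurement days, behaviour event logs over the observation windows,
#' robot-distance series, and cortisol samples — and writes them in the
#' package's plain-text formats:
#' `cohort.csv`, `ibi/<cow>_<period>d<day>_<session>.txt`,
#' `behavior.csv`, `distance.csv`, `cortisol.csv`.
#'
#' Every stochastic draw is derived from `seed` through labelled
#' substreams, so a run is a pure function of (config, seed).
#'
#' @param config a [herd_config()].
#' @param dir output directory (created if needed).
#' @param seed integer master seed (default from the config).
#' @param proximity also generate proximity-window sessions and the
#'   robot-distance series (the bulkiest outputs).
#' @return invisibly, a named list of the files written.
#' @export
simulate_study <- function(config = herd_config(), dir, seed = config$seed,
                           proximity = TRUE) {
  stopifnot(inherits(config, "herd_config"))
  dir.create(file.path(dir, "ibi"), recursive = TRUE, showWarnings = FALSE)
  tr <- config$truth
  sched <- config$schedule
  responses <- names(tr$period_means)
  behaviors <- intersect(responses, setdiff(.behaviors, "other"))

  ## latent truth and day values
  cohorts <- lapply(responses, function(r) gen_cohort(config, r, seed))
  names(cohorts) <- responses
  dayvals <- lapply(responses, function(r) {
    gen_day_values(cohorts[[r]], config, r, days = tr$hrv_days, seed = seed)
  })
  names(dayvals) <- responses
  cohort_long <- do.call(rbind, lapply(responses, function(r) {
    cbind(cohorts[[r]], response = r)
  }))
  utils::write.csv(cohort_long, file.path(dir, "cohort.csv"),
                   row.names = FALSE, quote = FALSE)

  key_cols <- c("farm", "cow", "period", "day")
  frame <- dayvals[[1]][key_cols]
  base_date <- as.Date("2013-01-06")
  day_date <- function(period, day) {
    base_date + (match(period, config$periods) - 1L) * 7L + day
  }
  session_start <- function(period, day, clock_h) {
    paste0(format(day_date(period, day)), "T", format_clock(clock_h * 3600))
  }
  value_of <- function(r, i) {
    dv <- dayvals[[r]]
    dv$value[match(paste(frame$farm[i], frame$cow[i], frame$period[i],
                         frame$day[i]),
                   paste(dv$farm, dv$cow, dv$period, dv$day))]
  }

  ## behaviour logs
  total_min <- total_observation_minutes(sched)
  beh_rows <- lapply(seq_len(nrow(frame)), function(i) {
    budgets <- vapply(behaviors, function(r) value_of(r, i), 0)
    budgets <- pmax(budgets, 0.5)
    if (sum(budgets) > 0.98 * total_min) {
      budgets <- budgets * 0.98 * total_min / sum(budgets)
    }
    gen_behavior_log(
      budgets, sched,
      seed = substream_seed(seed, paste0("beh_", paste(frame[i, ], collapse = "_"))),
      bout_means = tr$bout_means, cow = frame$cow[i], farm = frame$farm[i],
      period = frame$period[i], day = frame$day[i])
  })
  behavior <- do.call(rbind, beh_rows)
  write_behavior_csv(behavior, file.path(dir, "behavior.csv"))

  ## IBI sessions (activity, rest, proximity) with artifacts
  sessions <- list(active = list(win = sched$activity_window,
                                 resp = "rmssd_active"),
                   rest = list(win = sched$rest_window,
                               resp = "rmssd_rest"))
  if (proximity) {
    sessions$prox <- list(win = sched$proximity_window, resp = "rmssd_rest")
  }
  n_files <- 0L
  for (i in seq_len(nrow(frame))) {
    for (sn in names(sessions)) {
      ss <- sessions[[sn]]
      lab <- sprintf("%s_%sd%d_%s", frame$cow[i], frame$period[i],
                     frame$day[i], sn)
      clean <- gen_ibi(
        true_rmssd = value_of(ss$resp, i), mean_ibi = tr$mean_ibi,
        duration_s = (ss$win[2] - ss$win[1]) * 3600,
        seed = substream_seed(seed, paste0("ibi_", lab)),
        start = session_start(frame$period[i], frame$day[i], ss$win[1]),
        cow = frame$cow[i], session = lab)
      dirty <- inject_artifacts(clean, tr$artifact,
                                seed = substream_seed(seed, paste0("art_", lab)))
      write_ibi_file(dirty$series, file.path(dir, "ibi", paste0(lab, ".txt")))
      n_files <- n_files + 1L
    }
  }

  ## robot distance series
  if (proximity) {
    cows <- unique(frame[c("farm", "cow")])
    dd <- list()
    for (j in seq_len(nrow(cows))) {
      pos_seed <- substream_seed(seed, paste0("pos_", cows$cow[j]))
      set.seed(pos_seed)
      pen <- tr$pen
      cow_pos <- c(stats::runif(1, 0.15 * pen[["width"]], 0.85 * pen[["width"]]),
                   stats::runif(1, 0.15 * pen[["height"]], 0.85 * pen[["height"]]))
      for (i in which(frame$farm == cows$farm[j] & frame$cow == cows$cow[j])) {
        dd[[length(dd) + 1L]] <- cbind(
          gen_robot_distance(
            sched, speed = tr$robot_speed[[frame$farm[i]]],
            pen = pen, cow_pos = cow_pos, farm = frame$farm[i],
            cow = frame$cow[i], day = frame$day[i]),
          period = frame$period[i])
      }
    }
    utils::write.csv(do.call(rbind, dd), file.path(dir, "distance.csv"),
                     row.names = FALSE, quote = FALSE)
  }

  ## cortisol samples: three per cow-period
  co <- cohorts$cortisol
  cort <- do.call(rbind, lapply(seq_len(nrow(co)), function(i) {
    v <- gen_cortisol(co$latent[i], cv = tr$cortisol_cv,
                      days = tr$cortisol_days,
                      seed = substream_seed(seed, paste0(
                        "cort_", co$cow[i], "_", co$period[i])))
    data.frame(farm = co$farm[i], cow = co$cow[i], period = co$period[i],
               day = as.integer(names(v)), value = as.numeric(v),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(cort, file.path(dir, "cortisol.csv"),
                   row.names = FALSE, quote = FALSE)

  files <- list(cohort = file.path(dir, "cohort.csv"),
                behavior = file.path(dir, "behavior.csv"),
                cortisol = file.path(dir, "cortisol.csv"),
                ibi_dir = file.path(dir, "ibi"))
  if (proximity) files$distance <- file.path(dir, "distance.csv")
  message(sprintf("simulate: %d cows, %d cow-days, %d IBI sessions, %d behaviour events",
                  nrow(unique(frame[c("farm", "cow")])), nrow(frame),
                  n_files, nrow(behavior)))
  invisible(files)
}
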