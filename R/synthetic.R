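#' Generate per-cow, per-period latent true values
#'
#' Draws the latent (noise-free) value of one response for every cow and
#' period as `period mean + farm effect + cow-within-farm effect +
#' cow x period effect`, the effects independent zero-mean Gaussians with
#' the configured standard deviations.  Latents of positive-valued
#' responses are truncated at a small positive floor
#' (`latent_floor_frac` of the period mean; RMSSD responses additionally
#' at `rmssd_floor` ms so the double-log transform stays defined).
#'
#' @param config a [herd_config()].
#' @param response one of the responses named in `config$truth$period_means`.
#' @param seed integer seed.
#' @return data.frame `farm`, `cow`, `period`, `latent`, one row per
#'   cow-period (periods in study order).
#' @export
gen_cohort <- function(config, response, seed = config$seed) {
  tr <- config$truth
  means <- tr$period_means[[response]]
  if (is.null(means)) stop("unknown response: ", response, call. = FALSE)
  sds <- tr$sds[[response]]
  if (any(sds < 0)) stop("negative sd for response ", response, call. = FALSE)
  if (any(means <= 0)) stop("period means must be positive", call. = FALSE)
  set.seed(substream_seed(seed, paste0("cohort_", response)))
  nf <- config$n_farms; nc <- config$n_cows_per_farm
  periods <- config$periods
  farm_eff <- stats::rnorm(nf, 0, sds[["farm"]])
  cow_eff <- stats::rnorm(nf * nc, 0, sds[["cow"]])
  cp_eff <- stats::rnorm(nf * nc * 4L, 0, sds[["cow_period"]])
  grid <- expand.grid(period = periods, cow_i = seq_len(nc),
                      farm = seq_len(nf), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$farm, grid$cow_i), ]
  cow_id <- (grid$farm - 1L) * nc + grid$cow_i
  lat <- means[grid$period] + farm_eff[grid$farm] + cow_eff[cow_id] +
    cp_eff[(cow_id - 1L) * 4L + match(grid$period, periods)]
  floor_v <- tr$latent_floor_frac * means[grid$period]
  if (grepl("^rmssd", response)) floor_v <- pmax(floor_v, tr$rmssd_floor)
  out <- data.frame(farm = grid$farm,
                    cow = sprintf("f%dc%02d", grid$farm, grid$cow_i),
                    period = grid$period,
                    latent = pmax(lat, floor_v),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Add day-level replicate values to a cohort
#'
#' Each measurement day's true value varies around the cow-period latent
#' with a small day-to-day standard deviation (`day_cv` of the period
#' mean, default 5%), making day a non-degenerate replicate.
#'
#' @inheritParams gen_cohort
#' @param cohort output of [gen_cohort()].
#' @param days integer vector of day labels within each period.
#' @return data.frame `farm`, `cow`, `period`, `day`, `value`.
#' @export
gen_day_values <- function(cohort, config, response, days = config$truth$hrv_days,
                           seed = config$seed) {
  tr <- config$truth
  means <- tr$period_means[[response]]
  set.seed(substream_seed(seed, paste0("day_", response)))
  out <- cohort[rep(seq_len(nrow(cohort)), each = length(days)), ]
  out$day <- rep(days, nrow(cohort))
  day_sd <- tr$day_cv * means[out$period]
  floor_v <- tr$latent_floor_frac * means[out$period]
  if (grepl("^rmssd", response)) floor_v <- pmax(floor_v, tr$rmssd_floor)
  out$value <- pmax(out$latent + stats::rnorm(nrow(out), 0, day_sd), floor_v)
  out$latent <- NULL
  rownames(out) <- NULL
  out
}

## one draw routine: Gaussian truncated to (lo, hi) by rejection
rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= lo | x >= hi)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= lo | x[bad] >= hi]
  }
  x
}

#' Generate a clean interbeat-interval series with known RMSSD
#'
#' Intervals are i.i.d. Gaussian with mean `mean_ibi` and standard
#' deviation `true_rmssd / sqrt(2)` — so the expected mean squared
#' successive difference is exactly `true_rmssd^2` — truncated to
#' `(0.5, 1.5) * mean_ibi`.  Intervals are appended until the cumulative
#' duration reaches `duration_s`.
#'
#' @param true_rmssd target RMSSD, ms (> 0).
#' @param mean_ibi mean interbeat interval, ms (> 0).
#' @param duration_s requested minimum duration, seconds (>= 300 for an
#'   analysis window; shorter series are allowed for testing).
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param start,cow,session passed to [ibi_series()].
#' @return an [ibi_series()].
#' @export
gen_ibi <- function(true_rmssd, mean_ibi = 750, duration_s = 300,
                    seed = NULL, start = "2013-03-05T12:00:00",
                    cow = "cow", session = "sim") {
  if (true_rmssd < 0 || mean_ibi <= 0 || duration_s <= 0) {
    stop("true_rmssd must be >= 0 and mean_ibi, duration_s > 0",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  sd <- true_rmssd / sqrt(2)
  need_ms <- duration_s * 1000
  n0 <- ceiling(need_ms / mean_ibi) + 5L
  x <- rtruncnorm(n0, mean_ibi, sd, 0.5 * mean_ibi, 1.5 * mean_ibi)
  while (sum(x) < need_ms) {
    x <- c(x, rtruncnorm(ceiling(n0 * 0.1) + 5L, mean_ibi, sd,
                         0.5 * mean_ibi, 1.5 * mean_ibi))
  }
  n <- which(cumsum(x) >= need_ms)[1]
  ibi_series(x[seq_len(n)], start = start, cow = cow, session = session)
}

#' Inject recording artifacts into a clean IBI series
#'
#' Plants the four artifact mechanisms that the five-type correction
#' procedure is designed to undo, at non-adjacent sites chosen uniformly:
#' \describe{
#'   \item{missed_beat}{two adjacent intervals replaced by their sum (an
#'     over-wide, type-4-correctable interval); conserves duration.}
#'   \item{spurious_beat}{one interval split at a uniform(0.3, 0.7)
#'     fraction into two narrow intervals (type-5 pattern); conserves
#'     duration.}
#'   \item{jitter}{one beat boundary displaced by `jitter_frac` of the
#'     local interval, widening one interval and narrowing its neighbour
#'     (type-2/3 pattern); conserves duration.}
#'   \item{outlier}{one interval multiplied by a factor outside
#'     `[0.8, 1.25]` (type-1 pattern); this mechanism alone does not
#'     conserve duration, since a lone misread value has no compensating
#'     neighbour.}
#' }
#'
#' @param series an [ibi_series()] or numeric vector (ms).
#' @param artifact named list of per-interval site rates
#'   (`missed_beat`, `spurious_beat`, `jitter`, `outlier`) and
#'   `jitter_frac`; see [default_truth()].
#' @param seed integer seed, or `NULL`.
#' @return list: `series` (same type as input), `truth` (data.frame
#'   `index` — first affected index in the contaminated series —,
#'   `mechanism`, `span`).
#' @export
inject_artifacts <- function(series, artifact = default_truth()$artifact,
                             seed = NULL) {
  is_series <- inherits(series, "ibi_series")
  x <- if (is_series) series$intervals else as.numeric(series)
  n <- length(x)
  if (!is.null(seed)) set.seed(as.integer(seed))
  mechs <- c("missed_beat", "spurious_beat", "jitter", "outlier")
  rates <- vapply(mechs, function(m) artifact[[m]] %||% 0, 0)
  if (any(rates < 0)) stop("artifact rates must be >= 0", call. = FALSE)
  counts <- vapply(rates, function(r) stats::rbinom(1L, n, r), 0L)
  total <- sum(counts)
  if (total == 0L) {
    return(list(series = series,
                truth = data.frame(index = integer(), mechanism = character(),
                                   span = integer(), stringsAsFactors = FALSE)))
  }
  ## choose non-adjacent sites (gap >= 3) away from the series boundary
  candidates <- sample(seq(3L, n - 3L))
  sites <- integer(0)
  for (s in candidates) {
    if (length(sites) == total) break
    if (all(abs(sites - s) >= 3L)) sites <- c(sites, s)
  }
  if (length(sites) < total) {
    stop("requested contamination exceeds feasible non-adjacent sites",
         call. = FALSE)
  }
  mech_of <- sample(rep(mechs, counts))
  ord <- order(sites, decreasing = TRUE)   # apply right-to-left
  sites <- sites[ord]; mech_of <- mech_of[ord]
  truth <- data.frame(index = integer(), mechanism = character(),
                      span = integer(), stringsAsFactors = FALSE)
  jf <- artifact$jitter_frac %||% 0.35
  for (k in seq_along(sites)) {
    i <- sites[k]; m <- mech_of[k]
    delta <- 0L
    if (m == "missed_beat") {
      x <- c(x[seq_len(i - 1L)], x[i] + x[i + 1L], x[seq.int(i + 2L, length(x))])
      delta <- -1L; span <- 1L
    } else if (m == "spurious_beat") {
      u <- stats::runif(1, 0.3, 0.7)
      x <- c(x[seq_len(i - 1L)], u * x[i], (1 - u) * x[i],
             x[seq.int(i + 1L, length(x))])
      delta <- 1L; span <- 2L
    } else if (m == "jitter") {
      d <- sample(c(-1, 1), 1) * jf * x[i]
      if (x[i + 1L] - d <= 0) d <- -d
      x[i] <- x[i] + d
      x[i + 1L] <- x[i + 1L] - d
      span <- 2L
    } else {                             # outlier
      f <- if (stats::runif(1) < 0.5) stats::runif(1, 0.50, 0.75)
           else stats::runif(1, 1.30, 1.60)
      x[i] <- f * x[i]
      span <- 1L
    }
    if (nrow(truth)) truth$index <- truth$index + delta
    truth <- rbind(data.frame(index = i, mechanism = m, span = span,
                              stringsAsFactors = FALSE), truth)
  }
  truth <- truth[order(truth$index), ]
  rownames(truth) <- NULL
  out <- if (is_series) {
    ibi_series(x, start = series$start, cow = series$cow,
               session = series$session)
  } else x
  list(series = out, truth = truth)
}

#' Simulate one cow-day behaviour log
#'
#' Stationary alternating-renewal simulation over the behavioural
#' observation windows: bout durations are exponential with
#' behaviour-specific means, states are mutually exclusive, and each
#' window is started in the stationary regime (initial state drawn with
#' the occupancy probabilities, initial residual duration exponential by
#' memorylessness), so the expected per-behaviour occupancy equals the
#' latent budget exactly at any window length.
#'
#' @param budgets named numeric, minutes per observed day for (a subset
#'   of) lying, standing_cubicle, standing_walkway, feeding, locomotion;
#'   the remainder of the schedule is labelled `other`.
#' @param schedule an [obs_schedule()].
#' @param seed integer seed, or `NULL`.
#' @param bout_means named numeric, mean bout duration (min) per
#'   behaviour including `other`.
#' @param cow,farm,period,day labels attached to the events.
#' @return events data.frame (`cow`, `farm`, `period`, `day`, `behavior`,
#'   `start`, `end` in seconds of day, `duration_min`).
#' @export
gen_behavior_log <- function(budgets, schedule = default_schedule(),
                             seed = NULL,
                             bout_means = default_truth()$bout_means,
                             cow = "cow", farm = 1L, period = "B", day = 1L) {
  total <- total_observation_minutes(schedule)
  if (any(budgets < 0)) stop("budgets must be >= 0", call. = FALSE)
  if (sum(budgets) > total + 1e-9) {
    stop("budgets sum to ", round(sum(budgets), 2), " min > ", total,
         " min observable", call. = FALSE)
  }
  bad <- setdiff(names(budgets), setdiff(.behaviors, "other"))
  if (length(bad)) stop("unknown behavior in budgets: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  pi_k <- c(budgets, other = total - sum(budgets)) / total
  pi_k <- pi_k[pi_k > 0]
  m_k <- vapply(names(pi_k), function(b) bout_means[[b]] %||% 10, 0) * 60
  sel <- pi_k / m_k                      # renewal selection weights
  sel <- sel / sum(sel)
  states <- names(pi_k)
  mean_bout <- sum(sel * m_k)            # expected selected bout, s
  st_all <- character(0); s_all <- numeric(0); e_all <- numeric(0)
  for (w in schedule$behavior_windows) {
    t0 <- w[1] * 3600; t1 <- w[2] * 3600
    len <- t1 - t0
    ## stationary start: state by occupancy, residual duration exponential
    ks <- sample(states, 1, prob = pi_k)
    ds <- stats::rexp(1, rate = 1 / m_k[[ks]])
    while (sum(ds) < len) {              # batch renewal draws until covered
      nb <- ceiling((len - sum(ds)) / mean_bout * 1.3) + 10L
      knew <- sample(states, nb, replace = TRUE, prob = sel)
      ks <- c(ks, knew)
      ds <- c(ds, stats::rexp(nb, rate = 1 / m_k[knew]))
    }
    ends <- cumsum(ds)
    keep <- seq_len(which(ends >= len)[1])
    starts <- t0 + c(0, ends[keep[-length(keep)]])
    ends <- t0 + pmin(ends[keep], len)
    st_all <- c(st_all, ks[keep])
    s_all <- c(s_all, starts); e_all <- c(e_all, ends)
  }
  ev <- data.frame(cow = cow, farm = farm, period = period, day = day,
                   behavior = st_all, start = s_all, end = e_all,
                   duration_min = (e_all - s_all) / 60,
                   stringsAsFactors = FALSE)
  ev
}

#' Simulate a robot-scraper pass pattern and per-cow distance series
#'
#' The robot traverses the perimeter of a rectangular pen at constant
#' speed throughout the proximity window; the cow rests at a fixed
#' position and its distance to the robot is sampled at 1 s.  Each
#' traversal of the loop is one route pass.
#'
#' @param schedule an [obs_schedule()] (uses `proximity_window`).
#' @param speed robot working speed, m/min (> 0).
#' @param seed integer seed used to draw the cow position when
#'   `cow_pos` is `NULL`.
#' @param pen named numeric `c(width, height)`, metres.
#' @param cow_pos numeric length 2, metres, or `NULL` to draw uniformly
#'   inside the pen (away from the walls).
#' @param farm,cow,day labels.
#' @return data.frame `farm`, `cow`, `day`, `time` (s of day),
#'   `distance` (m), `pass`.
#' @export
gen_robot_distance <- function(schedule = default_schedule(), speed = 4.0,
                               seed = NULL, pen = c(width = 30, height = 12),
                               cow_pos = NULL, farm = 1L, cow = "cow",
                               day = 1L) {
  if (speed <= 0) stop("speed must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  W <- pen[["width"]]; H <- pen[["height"]]
  P <- 2 * (W + H)
  if (is.null(cow_pos)) {
    cow_pos <- c(stats::runif(1, 0.15 * W, 0.85 * W),
                 stats::runif(1, 0.15 * H, 0.85 * H))
  }
  t0 <- schedule$proximity_window[1] * 3600
  t1 <- schedule$proximity_window[2] * 3600
  tt <- seq(t0, t1 - 1, by = 1)
  s <- (speed / 60) * (tt - t0)          # arc length along the loop, m
  pass <- floor(s / P)
  sp <- s %% P
  x <- ifelse(sp < W, sp,
              ifelse(sp < W + H, W,
                     ifelse(sp < 2 * W + H, W - (sp - W - H), 0)))
  y <- ifelse(sp < W, 0,
              ifelse(sp < W + H, sp - W,
                     ifelse(sp < 2 * W + H, H, H - (sp - 2 * W - H))))
  data.frame(farm = farm, cow = cow, day = day, time = tt,
             distance = sqrt((x - cow_pos[1])^2 + (y - cow_pos[2])^2),
             pass = pass, stringsAsFactors = FALSE)
}

#' Simulate fecal cortisol-metabolite samples
#'
#' Samples are log-normal with median equal to the latent concentration
#' and log-scale standard deviation `log(1 + cv)`; by default three
#' samples per cow-period (collection days 2, 3 and 5).
#'
#' @param latent latent concentration (> 0).
#' @param cv residual coefficient of variation (> 0).
#' @param days sample-day labels (one sample per day).
#' @param seed integer seed, or `NULL`.
#' @return numeric vector named by day.
#' @export
gen_cortisol <- function(latent, cv = default_truth()$cortisol_cv,
                         days = default_truth()$cortisol_days, seed = NULL) {
  if (latent <= 0) stop("latent concentration must be positive", call. = FALSE)
  if (cv < 0) stop("cv must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  v <- stats::rlnorm(length(days), meanlog = log(latent),
                     sdlog = log(1 + cv))
  names(v) <- days
  v
}
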