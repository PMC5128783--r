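#' Response transforms
#'
#' The transforms used before mixed-model fitting: `double_log` =
#' `log(log(x))` (HRV responses), `log` (cortisol metabolites), `sqrt`
#' (standing behaviours), `identity`.  Domain violations report the
#' offending observation.
#'
#' @param values numeric vector.
#' @param kind one of `double_log`, `log`, `sqrt`, `identity`.
#' @return transformed numeric vector.
#' @export
apply_transform <- function(values, kind = c("identity", "log",
                                             "double_log", "sqrt")) {
  kind <- match.arg(kind)
  bad_at <- function(ok, need) {
    if (!all(ok)) {
      i <- which(!ok)[1]
      stop(kind, " transform needs values ", need, "; observation ", i,
           " is ", values[i], call. = FALSE)
    }
  }
  switch(kind,
         identity = values,
         log = { bad_at(values > 0, "> 0"); log(values) },
         double_log = { bad_at(values > 1, "> 1"); log(log(values)) },
         sqrt = { bad_at(values >= 0, ">= 0"); sqrt(values) })
}

all_period_pairs <- function(periods) {
  t(utils::combn(periods, 2))
}

#' Period-contrast analysis of one response
#'
#' The study's primary model: transform the response per the configured
#' map, fit the mixed model `value ~ period` with random intercepts for
#' farm, cow-within-farm and cow x period, remove observations with
#' standardized residuals outside the 99% normal interval and refit
#' once, then report all six pairwise period contrasts (Satterthwaite
#' t-tests, on the transformed scale) together with per-period raw-scale
#' arithmetic means and SEMs of the analyzed observations.
#'
#' @param records data.frame with columns `farm`, `cow`, `period`,
#'   `value` (and usually `day`).
#' @param response response name (selects the transform).
#' @param config a [herd_config()].
#' @return object of class `period_analysis`: list with `response`,
#'   `transform`, `fit`, `contrasts` (6 rows), `means` (4 rows),
#'   `removed`.
#' @export
run_period_analysis <- function(records, response, config = herd_config()) {
  stopifnot(all(c("farm", "cow", "period", "value") %in% names(records)))
  kind <- config$transform_map[[response]] %||% "identity"
  dat <- records
  dat$period <- factor(dat$period, levels = config$periods)
  if (anyNA(dat$period)) stop("record periods outside the configured labels",
                              call. = FALSE)
  dat$value_t <- apply_transform(dat$value, kind)
  fit0 <- herd_lmm(value_t ~ period, dat,
                   random = c("farm", "farm:cow", "farm:cow:period"))
  fit <- remove_outliers_refit(fit0)
  pairs <- all_period_pairs(config$periods)
  contrasts <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs[i, 1]; b <- pairs[i, 2]
    satterthwaite_contrast(
      fit, list(data.frame(period = a), data.frame(period = b)),
      label = paste(a, "vs", b))
  }))
  kept <- if (length(fit$removed)) dat[-fit$removed, ] else dat
  means <- do.call(rbind, lapply(config$periods, function(p) {
    v <- kept$value[kept$period == p]
    data.frame(period = p, n = length(v), mean = mean(v),
               sem = stats::sd(v) / sqrt(length(v)),
               stringsAsFactors = FALSE)
  }))
  structure(list(response = response, transform = kind, fit = fit,
                 contrasts = contrasts, means = means,
                 removed = fit$removed),
            class = "period_analysis")
}

#' @export
print.period_analysis <- function(x, ...) {
  cat(sprintf("Period analysis of %s (transform: %s; %d obs, %d removed)\n",
              x$response, x$transform, x$fit$n, length(x$removed)))
  m <- x$means
  cat("  raw-scale period means (mean +/- SEM):\n")
  for (i in seq_len(nrow(m))) {
    cat(sprintf("    %-3s %8.2f +/- %.2f  (n = %d)\n", m$period[i],
                m$mean[i], m$sem[i], m$n[i]))
  }
  cat("  pairwise contrasts (transformed scale, Satterthwaite):\n")
  ct <- x$contrasts
  for (i in seq_len(nrow(ct))) {
    cat(sprintf("    %-9s est %8.4f  se %.4f  t %6.2f  df %6.1f  P = %.3f\n",
                ct$contrast[i], ct$estimate[i], ct$se[i], ct$t[i],
                ct$df[i], ct$p[i]))
  }
  invisible(x)
}

#' Robot-proximity analysis of lying-cow HRV
#'
#' Reshapes near/far window pairs to one row per 5-min window, applies
#' the double-log transform, and fits `value ~ position * period` (test
#' periods only) with the standard random structure.  Reports the
#' near-vs-far contrast within each test period.
#'
#' @param pairs data.frame with `farm`, `cow`, `period`, `day`,
#'   `near_rmssd`, `far_rmssd`.
#' @param config a [herd_config()].
#' @return object of class `proximity_analysis` with `fit`, `contrasts`
#'   (one near-vs-far row per test period) and `means` (raw-scale means
#'   by period x position).
#' @export
run_proximity_analysis <- function(pairs, config = herd_config()) {
  stopifnot(all(c("farm", "cow", "period", "near_rmssd", "far_rmssd")
                %in% names(pairs)))
  test_periods <- setdiff(unique(as.character(pairs$period)), NA)
  test_periods <- config$periods[config$periods %in% test_periods]
  long <- rbind(
    data.frame(pairs[c("farm", "cow", "period")], position = "near",
               value = pairs$near_rmssd, stringsAsFactors = FALSE),
    data.frame(pairs[c("farm", "cow", "period")], position = "far",
               value = pairs$far_rmssd, stringsAsFactors = FALSE))
  long$period <- factor(long$period, levels = test_periods)
  long$position <- factor(long$position, levels = c("far", "near"))
  long$value_t <- apply_transform(long$value, "double_log")
  fit <- herd_lmm(value_t ~ position * period, long,
                  random = c("farm", "farm:cow", "farm:cow:period"))
  fit <- remove_outliers_refit(fit)
  contrasts <- do.call(rbind, lapply(test_periods, function(p) {
    satterthwaite_contrast(
      fit, list(data.frame(position = "near", period = p),
                data.frame(position = "far", period = p)),
      label = paste0("near vs far (", p, ")"))
  }))
  kept <- if (length(fit$removed)) long[-fit$removed, ] else long
  means <- stats::aggregate(value ~ period + position, kept, mean)
  structure(list(fit = fit, contrasts = contrasts, means = means,
                 removed = fit$removed),
            class = "proximity_analysis")
}

#' @export
print.proximity_analysis <- function(x, ...) {
  cat(sprintf("Robot-proximity analysis (double-log RMSSD; %d windows, %d removed)\n",
              x$fit$n, length(x$removed)))
  ct <- x$contrasts
  for (i in seq_len(nrow(ct))) {
    cat(sprintf("  %-18s est %8.4f  se %.4f  t %6.2f  df %6.1f  P = %.3f\n",
                ct$contrast[i], ct$estimate[i], ct$se[i], ct$t[i],
                ct$df[i], ct$p[i]))
  }
  invisible(x)
}
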