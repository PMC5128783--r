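# shared fixtures; everything is generated in code

# a config whose generator has no between-animal variation
zero_var_config <- function() {
  herd_config(truth = list(sds = lapply(default_truth()$sds, function(s) s * 0),
                           day_cv = 0))
}

# small study for pipeline smoke tests: 2 farms x 3 cows, compressed
# clock windows so IBI sessions stay short
tiny_config <- function(seed = 20130107L) {
  herd_config(
    seed = seed, n_farms = 2L, n_cows_per_farm = 3L,
    schedule = obs_schedule(
      behavior_windows = list(c(10, 10.6), c(12, 12.6), c(21, 21.6)),
      activity_window = c(12, 12.6), rest_window = c(21, 21.6),
      proximity_window = c(10, 10.6)),
    truth = list(bout_means = c(lying = 8, feeding = 4,
                                standing_cubicle = 2, standing_walkway = 2,
                                locomotion = 1, other = 2),
                 period_means = list(
                   lying = c(B = 40, T1 = 42, T2 = 45, T3 = 45),
                   feeding = c(B = 15, T1 = 16, T2 = 18, T3 = 18),
                   standing_cubicle = c(B = 12, T1 = 11, T2 = 9, T3 = 11),
                   standing_walkway = c(B = 9, T1 = 9, T2 = 8, T3 = 7),
                   locomotion = c(B = 10, T1 = 11, T2 = 10, T3 = 9)),
                 sds = list(lying = c(farm = 2, cow = 4, cow_period = 3),
                            feeding = c(farm = 1, cow = 2, cow_period = 1.5),
                            standing_cubicle = c(farm = 1, cow = 2, cow_period = 1),
                            standing_walkway = c(farm = 1, cow = 1.5, cow_period = 1),
                            locomotion = c(farm = 1, cow = 2, cow_period = 1))))
}

# balanced one-way random-intercept data with known ANOVA closed form
balanced_oneway <- function(a = 8, n = 6, mu = 10, sd_b = 2, sd_e = 1,
                            seed = 1) {
  set.seed(seed)
  g <- factor(rep(seq_len(a), each = n))
  b <- rnorm(a, 0, sd_b)
  data.frame(g = g, value_t = mu + b[as.integer(g)] + rnorm(a * n, 0, sd_e))
}

# record-level study generator used by the statistical tests: one value
# per cow-period-day with the configured random-effect structure
gen_records <- function(config, response, seed) {
  co <- gen_cohort(config, response, seed = seed)
  gen_day_values(co, config, response, seed = seed)
}

quiet_lmm <- function(...) suppressWarnings(suppressMessages(herd_lmm(...)))
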