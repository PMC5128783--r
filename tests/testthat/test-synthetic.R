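test_that("cohort generator reproduces the random-effect structure", {
  cfg0 <- zero_var_config()
  co <- gen_cohort(cfg0, "lying", seed = 1)
  expect_equal(nrow(co), 3 * 12 * 4)
  means <- default_truth()$period_means$lying
  expect_equal(co$latent, unname(means[co$period]))   # degenerate variance

  cfg <- herd_config()
  expect_identical(gen_cohort(cfg, "rmssd_rest", seed = 5),
                   gen_cohort(cfg, "rmssd_rest", seed = 5))
  expect_error(gen_cohort(herd_config(truth = list(
    sds = list(lying = c(farm = -1, cow = 1, cow_period = 1)))), "lying"),
    "negative sd")
  expect_error(gen_cohort(cfg, "grooming"), "unknown response")
})

test_that("farm-effect dispersion matches the configured sd (Monte-Carlo)", {
  ## isolate the farm effect: no cow or cow x period variation
  cfg <- herd_config(
    n_cows_per_farm = 1L,
    truth = list(sds = list(lying = c(farm = 12, cow = 0, cow_period = 0))))
  eff <- vapply(1:10000, function(s) {
    co <- gen_cohort(cfg, "lying", seed = s)
    co$latent[1] - default_truth()$period_means$lying[["B"]]
  }, 0)
  expect_lt(abs(sd(eff) / 12 - 1), 0.02)
})

test_that("gen_ibi hits the requested RMSSD and duration", {
  ## law of large numbers at 1e6 intervals
  s <- gen_ibi(6.83, 750, duration_s = 750 * 1e6 / 1000, seed = 1)
  expect_gt(length(s), 1e6 - 10)
  expect_lt(abs(rmssd(s) / 6.83 - 1), 0.01)
  expect_lt(abs(mean(s$intervals) - 750), 1)

  s2 <- gen_ibi(9.02, 750, 300, seed = 2)
  expect_gte(sum(s2$intervals) / 1000, 300)
  expect_true(all(s2$intervals > 375 & s2$intervals < 1125))

  ## vanishing variability limit
  s0 <- gen_ibi(1e-9, 750, 60, seed = 3)
  expect_lt(rmssd(s0), 1e-8)
  expect_error(gen_ibi(-1, 750, 300), "true_rmssd")
  expect_error(gen_ibi(5, 0, 300), "true_rmssd must be >= 0 and mean_ibi")
})

test_that("artifact injection follows the stated mechanisms", {
  clean <- gen_ibi(7, 750, 300, seed = 10)
  none <- list(missed_beat = 0, spurious_beat = 0, jitter = 0, outlier = 0)

  ## all rates zero: identity
  out <- inject_artifacts(clean, none, seed = 1)
  expect_identical(out$series$intervals, clean$intervals)
  expect_equal(nrow(out$truth), 0)

  ## missed beat replaces two adjacent intervals by their sum
  spec_mb <- modifyList(none, list(missed_beat = 0.01))
  out <- inject_artifacts(clean, spec_mb, seed = 2)
  expect_gt(nrow(out$truth), 0)
  expect_equal(length(out$series$intervals),
               length(clean$intervals) - nrow(out$truth))
  i <- out$truth$index[1]
  expect_gt(out$series$intervals[i], 1.5 * 750)      # the merged wide beat
  expect_equal(sum(out$series$intervals), sum(clean$intervals),
               tolerance = 1e-12)

  ## duration is conserved to machine precision by every mechanism
  ## except the lone outlier (which has no compensating neighbour)
  for (mech in c("missed_beat", "spurious_beat", "jitter")) {
    spec1 <- modifyList(none, setNames(list(0.02), mech))
    out <- inject_artifacts(clean, spec1, seed = 3)
    expect_equal(sum(out$series$intervals), sum(clean$intervals),
                 tolerance = 1e-12, label = mech)
  }
  spec_out <- modifyList(none, list(outlier = 0.02))
  out <- inject_artifacts(clean, spec_out, seed = 4)
  expect_false(isTRUE(all.equal(sum(out$series$intervals),
                                sum(clean$intervals), tolerance = 1e-9)))

  ## infeasible contamination requests error out
  short <- gen_ibi(7, 750, 8, seed = 5)
  expect_error(
    inject_artifacts(short, modifyList(none, list(jitter = 0.9)), seed = 6),
    "non-adjacent")
})

test_that("behavior generator partitions the observed day exactly", {
  sch <- default_schedule()
  one <- gen_behavior_log(c(lying = 840), sch, seed = 1)
  expect_true(all(one$behavior == "lying"))
  expect_equal(sum(one$duration_min), 840)

  b <- c(lying = 320, feeding = 124, standing_cubicle = 99,
         standing_walkway = 71, locomotion = 155)
  ev <- gen_behavior_log(b, sch, seed = 2)
  expect_equal(sum(ev$duration_min), 840)             # partition incl. other
  expect_true(all(ev$end > ev$start))
  expect_identical(gen_behavior_log(b, sch, seed = 9),
                   gen_behavior_log(b, sch, seed = 9))
  expect_error(gen_behavior_log(c(lying = 900), sch), "> 840")
  expect_error(gen_behavior_log(c(lying = -5), sch), ">= 0")
})

test_that("behavior occupancy is an unbiased estimate of the latent budget", {
  sch <- default_schedule()
  b <- c(lying = 320.77, feeding = 123.83, standing_cubicle = 98.59,
         standing_walkway = 71.26, locomotion = 155)
  set.seed(77)
  m <- vapply(1:400, function(i) {
    bud <- compute_time_budget(gen_behavior_log(b, sch), sch)
    c(bud$lying, bud$feeding)
  }, c(0, 0))
  se_l <- sd(m[1, ]) / 20; se_f <- sd(m[2, ]) / 20
  expect_lt(abs(mean(m[1, ]) - 320.77), 4 * se_l)
  expect_lt(abs(mean(m[2, ]) - 123.83), 4 * se_f)
})

test_that("robot distance series has the promised geometry", {
  sch <- default_schedule()
  ## cow on the path: minimum distance 0
  d0 <- gen_robot_distance(sch, speed = 4, pen = c(width = 10, height = 10),
                           cow_pos = c(0, 0))
  expect_equal(min(d0$distance), 0)

  ## 40-m loop at 4 m/min: one pass takes 10 min
  expect_equal(sum(d0$pass == 0), 600)
  expect_equal(d0$pass[601], 1)

  ## unique extrema within every complete pass
  d <- gen_robot_distance(sch, speed = 4, seed = 42)
  for (p in unique(d$pass)) {
    dd <- d[d$pass == p, ]
    if (nrow(dd) < 2 * (2 * (30 + 12)) * 60 / 4 / 2) next  # incomplete last pass
    expect_equal(sum(dd$distance == min(dd$distance)), 1)
    expect_equal(sum(dd$distance == max(dd$distance)), 1)
  }
  expect_error(gen_robot_distance(sch, speed = 0), "positive")
})

test_that("cortisol sampler is log-normal around the latent median", {
  v <- gen_cortisol(15.36, cv = 1e-12, seed = 1)
  expect_equal(unname(v), rep(15.36, 3), tolerance = 1e-6)
  expect_equal(names(v), c("2", "3", "5"))

  big <- gen_cortisol(15.36, cv = 0.2, days = seq_len(20000), seed = 3)
  expect_true(all(big > 0))
  expect_lt(abs(median(big) / 15.36 - 1), 0.01)
  expect_error(gen_cortisol(-2), "positive")
})

test_that("day-level replicates stay near the cow-period latent", {
  cfg <- herd_config()
  co <- gen_cohort(cfg, "rmssd_active", seed = 3)
  dv <- gen_day_values(co, cfg, "rmssd_active", seed = 3)
  expect_equal(nrow(dv), 2 * nrow(co))
  expect_true(all(dv$value >= 1.5))     # floor keeps double-log defined
  merged <- merge(dv, co, by = c("farm", "cow", "period"))
  ## day noise is 5% of the period mean, so deviations are small
  expect_lt(max(abs(merged$value - merged$latent)), 5 * 0.05 * 9.02)
})
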