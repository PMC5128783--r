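test_that("transforms and their domains", {
  expect_equal(apply_transform(exp(exp(1)), "double_log"), 1)
  expect_equal(apply_transform(1, "log"), 0)
  expect_equal(apply_transform(4, "sqrt"), 2)
  expect_equal(apply_transform(c(3, 7), "identity"), c(3, 7))
  expect_error(apply_transform(c(2, 0.9), "double_log"), "observation 2")
  expect_error(apply_transform(-1, "log"), "> 0")
  expect_error(apply_transform(-1, "sqrt"), ">= 0")
})

test_that("REML matches the closed-form ANOVA estimators on balanced one-way data", {
  d <- balanced_oneway(a = 8, n = 6, mu = 10, sd_b = 2, sd_e = 1, seed = 3)
  a <- 8; n <- 6
  gm <- mean(d$value_t)
  gmeans <- tapply(d$value_t, d$g, mean)
  msb <- n * sum((gmeans - gm)^2) / (a - 1)
  msw <- sum((d$value_t - gmeans[d$g])^2) / (a * (n - 1))
  stopifnot(msb > msw)                  # interior optimum; REML = ANOVA
  fit <- quiet_lmm(value_t ~ 1, d, random = "g")
  expect_equal(unname(fit$beta), gm, tolerance = 1e-6)
  expect_equal(unname(fit$varcomp[["residual"]]), msw, tolerance = 1e-6)
  expect_equal(unname(fit$varcomp[["g"]]), (msb - msw) / n, tolerance = 1e-5)
})

test_that("restricted likelihood is maximal at the fitted variance components", {
  cfg <- herd_config()
  dv <- gen_records(cfg, "rmssd_rest", seed = 8)
  dv$value_t <- apply_transform(dv$value, "double_log")
  fit <- quiet_lmm(value_t ~ period, dv)
  nll <- herdstress:::reml_nll
  at_hat <- nll(fit$varcomp, fit$y, fit$X, fit$Zs)
  set.seed(99)
  for (i in 1:100) {
    th <- fit$varcomp * exp(runif(4, -0.4, 0.4))
    th <- pmax(th, 1e-10)
    expect_gte(nll(th, fit$y, fit$X, fit$Zs), at_hat - 1e-6)
  }
})

test_that("zero generating variances collapse to OLS, with df -> N - p", {
  cfg0 <- zero_var_config()
  dv <- gen_records(cfg0, "lying", seed = 2)
  set.seed(5)                 # a draw whose REML solution is on the boundary
  dv$value_t <- dv$value + rnorm(nrow(dv), 0, 5)   # pure residual noise
  fit <- quiet_lmm(value_t ~ period, dv)
  expect_lt(max(fit$varcomp[1:3]), 1e-6)
  ols <- lm(value_t ~ period, dv)
  expect_equal(unname(fit$beta), unname(coef(ols)), tolerance = 1e-6)
  ct <- satterthwaite_contrast(
    fit, list(data.frame(period = "B"), data.frame(period = "T1")))
  expect_equal(ct$df, nrow(dv) - 4, tolerance = 1)
})

test_that("a zero contrast on symmetric data gives p = 1", {
  d <- data.frame(farm = rep(1:2, each = 8),
                  cow = rep(sprintf("c%d", 1:4), each = 4),
                  period = rep(c("B", "T1"), 8),
                  value_t = rep(c(3, 5, 5, 3), 4))   # identical level means
  fit <- quiet_lmm(value_t ~ period, d, random = c("farm", "farm:cow"))
  ct <- satterthwaite_contrast(
    fit, list(data.frame(period = "B"), data.frame(period = "T1")))
  expect_equal(ct$estimate, 0, tolerance = 1e-10)
  expect_equal(ct$p, 1, tolerance = 1e-8)
})

test_that("df shrinks as the cow x period variance share grows", {
  make <- function(cp_sd, seed) {
    cfg <- herd_config(truth = list(
      sds = list(lying = c(farm = 5, cow = 10, cow_period = cp_sd))))
    dv <- gen_records(cfg, "lying", seed = seed)
    dv$value_t <- dv$value
    fit <- quiet_lmm(value_t ~ period, dv)
    satterthwaite_contrast(
      fit, list(data.frame(period = "B"), data.frame(period = "T1")))$df
  }
  ## Monte-Carlo comparison: estimated df are noisy per draw, so compare
  ## the means over 5 simulated studies per variance regime
  lo <- mean(vapply(1:5, function(s) make(0, 100 + s), 0))
  hi <- mean(vapply(1:5, function(s) make(60, 100 + s), 0))
  expect_lt(hi, lo)
})

test_that("outlier handling: single pass at the 99% normal bound", {
  cfg <- herd_config()
  dv <- gen_records(cfg, "lying", seed = 21)
  dv$value_t <- dv$value
  fit <- quiet_lmm(value_t ~ period, dv)

  ## planted 10-sigma observation is the one removed
  dvp <- dv
  marg_sd <- sqrt(sum(fit$varcomp))
  dvp$value_t[100] <- dvp$value_t[100] + 10 * marg_sd
  fitp <- quiet_lmm(value_t ~ period, dvp)
  ref <- suppressWarnings(suppressMessages(remove_outliers_refit(fitp)))
  expect_true(100 %in% ref$removed)
  expect_lte(length(ref$removed), 3)
  expect_equal(ref$n + length(ref$removed), nrow(dvp))

  ## clean Gaussian data: expected removal rate ~ 1%
  set.seed(5)
  removed <- 0; total <- 0
  for (i in 1:30) {
    d <- gen_records(cfg, "rmssd_rest", seed = 700 + i)
    d$value_t <- apply_transform(d$value, "double_log")
    f <- quiet_lmm(value_t ~ period, d)
    r <- suppressWarnings(suppressMessages(remove_outliers_refit(f)))
    removed <- removed + length(r$removed); total <- total + f$n
  }
  expect_lt(removed / total, 0.025)     # binomial slack around the 1% rate

  ## no outliers: the refit is the fit
  d0 <- gen_records(zero_var_config(), "lying", seed = 3)
  d0$value_t <- 100 + seq_len(nrow(d0)) %% 5   # bounded, no 2.58-sigma tail
  f0 <- quiet_lmm(value_t ~ period, d0)
  r0 <- suppressWarnings(remove_outliers_refit(f0))
  expect_length(r0$removed, 0)
  expect_identical(r0$beta, f0$beta)
})

test_that("REML estimates are invariant to row permutation", {
  cfg <- herd_config()
  dv <- gen_records(cfg, "feeding", seed = 31)
  dv$value_t <- dv$value
  fit1 <- quiet_lmm(value_t ~ period, dv)
  set.seed(7)
  fit2 <- quiet_lmm(value_t ~ period, dv[sample(nrow(dv)), ])
  expect_equal(fit1$beta, fit2$beta, tolerance = 1e-6)
  expect_equal(fit1$varcomp, fit2$varcomp, tolerance = 1e-5)
})

test_that("period analysis emits 6 contrasts, 4 means, and full accounting", {
  cfg <- herd_config()
  dv <- gen_records(cfg, "cortisol", seed = 17)
  names(dv)[names(dv) == "value"] <- "value"
  pa <- suppressWarnings(suppressMessages(
    run_period_analysis(dv, "cortisol", cfg)))
  expect_s3_class(pa, "period_analysis")
  expect_equal(nrow(pa$contrasts), 6)
  expect_equal(nrow(pa$means), 4)
  expect_equal(pa$transform, "log")
  expect_equal(pa$fit$n + length(pa$removed), nrow(dv))
  expect_true(all(pa$contrasts$p > 0 & pa$contrasts$p <= 1))
  expect_true(all(pa$contrasts$df > 0))
  expect_true(all(pa$fit$varcomp >= 0))
  expect_output(print(pa), "raw-scale period means")
})

test_that("the study's B-to-T1 HRV drop is detected with the right sign", {
  cfg <- herd_config()
  neg <- 0; sig <- 0
  for (s in 1:10) {
    dv <- gen_records(cfg, "rmssd_active", seed = 1200 + s)
    pa <- suppressWarnings(suppressMessages(
      run_period_analysis(dv, "rmssd_active", cfg)))
    ct <- pa$contrasts[pa$contrasts$contrast == "B vs T1", ]
    ## estimate is B minus T1 on the transformed scale: positive when T1 < B
    if (ct$estimate > 0) neg <- neg + 1
    if (ct$p < 0.05) sig <- sig + 1
  }
  expect_gte(neg, 9)
  expect_gte(sig, 8)
})

test_that("proximity analysis tests near-vs-far within each test period", {
  make_pairs <- function(t1_boost = 1, seed = 1) {
    set.seed(seed)
    grid <- expand.grid(farm = 1:3, cow_i = 1:12, period = c("T1", "T2", "T3"),
                        day = 1:2, KEEP.OUT.ATTRS = FALSE)
    grid$cow <- sprintf("f%dc%02d", grid$farm, grid$cow_i)
    cow_eff <- rnorm(36, 0, 0.6)
    base <- 9 + cow_eff[match(grid$cow, unique(grid$cow))] +
      rnorm(nrow(grid), 0, 0.45)
    near <- base * ifelse(grid$period == "T1", t1_boost, 1) +
      rnorm(nrow(grid), 0, 0.3)
    far <- base + rnorm(nrow(grid), 0, 0.3)
    data.frame(grid[c("farm", "cow", "period", "day")],
               near_rmssd = pmax(near, 2), far_rmssd = pmax(far, 2))
  }

  ## null generator: contrasts centred on zero
  pr0 <- suppressWarnings(suppressMessages(
    run_proximity_analysis(make_pairs(1, seed = 2), herd_config())))
  expect_equal(nrow(pr0$contrasts), 3)
  expect_true(all(abs(pr0$contrasts$t) < 3))

  ## effect planted in T1 only is found there and only there
  pr1 <- suppressWarnings(suppressMessages(
    run_proximity_analysis(make_pairs(1.12, seed = 3), herd_config())))
  p <- pr1$contrasts$p
  names(p) <- pr1$contrasts$contrast
  expect_lt(p[["near vs far (T1)"]], 0.01)
  expect_gt(min(p[["near vs far (T2)"]], p[["near vs far (T3)"]]), 0.05)
})
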