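test_that("20% rule flags against the corrected predecessor", {
  expect_equal(detect_errors(c(800, 1000, 810)), c(FALSE, TRUE, FALSE))
  expect_equal(detect_errors(c(800, 900, 810)), c(FALSE, FALSE, FALSE))
  expect_equal(detect_errors(rep(800, 50)), rep(FALSE, 50))
  expect_error(detect_errors(800), "at least 2")

  ## the flagged interval does not poison the reference: 810 is compared
  ## to 800 (the corrected predecessor), not to the erroneous 1000
  expect_equal(detect_errors(c(800, 1000, 810, 805)),
               c(FALSE, TRUE, FALSE, FALSE))
})

test_that("detector never flags a series whose successive ratios stay in band", {
  for (s in 1:10) {
    set.seed(s)
    x <- numeric(200)
    x[1] <- 800
    for (i in 2:200) x[i] <- x[i - 1] * runif(1, 0.85, 1.15)
    expect_false(any(detect_errors(x, threshold = 0.20)))
  }
})

test_that("error runs are classified into the five types", {
  qc <- herd_config()$qc
  base <- rep(800, 6)

  x <- c(base, 1000, 620, 810)          # wide-then-narrow pair, sum ~ 2*median
  ann <- classify_errors(x, detect_errors(x), qc)
  expect_equal(ann$error_type[7:8], c("2/3", "2/3"))

  x <- c(base, 1620, 800)               # lone markedly wide interval
  ann <- classify_errors(x, detect_errors(x), qc)
  expect_equal(ann$error_type[7], "4")

  x <- c(base, 400, 410, 800)           # two narrow, sum ~ median
  ann <- classify_errors(x, detect_errors(x), qc)
  expect_equal(ann$error_type[7:8], c("5", "5"))

  x <- c(base, 1000, 800)               # lone moderate deviation
  ann <- classify_errors(x, detect_errors(x), qc)
  expect_equal(ann$error_type[7], "1")

  x <- c(base, 1400, 1400, 1400, 800)   # run of 3+: untyped, window rejected
  ann <- classify_errors(x, detect_errors(x), qc)
  expect_equal(ann$error_type[7:9], rep("untyped", 3))
})

test_that("corrections reproduce the hand-worked arithmetic", {
  run <- function(x) ibi_qc(x, herd_config()$qc)

  r <- run(c(800, 1000, 620, 810))      # merge and halve
  expect_equal(r$intervals, c(800, 810, 810, 810))

  r <- run(c(800, 800, 800, 1620, 800, 800))  # split the missed beat
  expect_equal(r$intervals, c(800, 800, 800, 810, 810, 800, 800))

  r <- run(c(800, 800, 800, 400, 410, 800, 800))  # merge the spurious beat
  expect_equal(r$intervals, c(800, 800, 800, 810, 800, 800))

  ## type 1: linear interpolation = mean of flanking unflagged intervals
  r <- run(c(800, 820, 1000, 840, 810))
  expect_equal(r$intervals, c(800, 820, 830, 840, 810))
  expect_equal(r$annotation$correction[3], "interpolate")
})

test_that("types 2-5 conserve summed duration; boundary flags are dropped", {
  x23 <- c(800, 810, 1000, 620, 805, 795)
  r <- ibi_qc(x23)
  expect_identical(sum(r$intervals), sum(x23))
  x4 <- c(800, 810, 1620, 805, 795)
  r <- ibi_qc(x4)
  expect_identical(sum(r$intervals), sum(x4))
  x5 <- c(800, 810, 400, 410, 805, 795)
  r <- ibi_qc(x5)
  expect_identical(sum(r$intervals), sum(x5))

  ## type 1 changes duration by exactly the gap between the outlier and
  ## its interpolated replacement (here 1000 -> 830)
  x1 <- c(800, 820, 1000, 840, 810)
  r <- ibi_qc(x1)
  expect_equal(sum(x1) - sum(r$intervals), 1000 - 830)

  ## trailing flagged interval is dropped, not corrected
  xb <- c(800, 810, 805, 1300)
  r <- ibi_qc(xb)
  expect_equal(r$intervals, c(800, 810, 805))
  expect_equal(r$annotation$correction[4], "drop")
})

test_that("annotation consistency is enforced", {
  x <- c(800, 1000, 620, 810)
  ann <- classify_errors(x, detect_errors(x))
  ann$flagged[2] <- FALSE               # typed but unflagged
  expect_error(correct_series(x, ann), "inconsistent")
  expect_error(correct_series(x, ann[1:2, ]), "match")
})

test_that("window acceptance applies the 5% and 3-consecutive thresholds", {
  qc <- herd_config()$qc
  rep_ok <- data.frame(total = 400, flagged = 10, max_run = 2)
  expect_true(accept_window(rep_ok, qc))            # 2.5% < 5%
  rep_rate <- data.frame(total = 400, flagged = 25, max_run = 2)
  expect_false(accept_window(rep_rate, qc))         # 6.25%
  rep_run <- data.frame(total = 400, flagged = 3, max_run = 3)
  expect_false(accept_window(rep_run, qc))          # 3-run rejects at 0.75%
  rep_edge <- data.frame(total = 400, flagged = 20, max_run = 2)
  expect_false(accept_window(rep_edge, qc))         # exactly 5% is rejected
})

test_that("correction is idempotent on accepted windows", {
  for (s in 1:20) {
    clean <- gen_ibi(7, 750, 300, seed = 300 + s)
    dirty <- inject_artifacts(clean, seed = 400 + s)
    first <- ibi_qc(dirty$series)
    if (!first$report$accepted) next
    second <- ibi_qc(first$intervals)
    types2 <- second$annotation$error_type
    expect_false(any(types2 %in% c("2/3", "4", "5")),
                 label = sprintf("no structural errors after correction (seed %d)", s))
  }
})

test_that("correction round trip recovers the clean RMSSD (reduced MC)", {
  ## 200 replicates here; the 1,000-replicate run lives in the acceptance suite
  ratio <- vapply(1:200, function(s) {
    clean <- gen_ibi(6.83, 750, 300, seed = 5000 + s)
    dirty <- inject_artifacts(clean, seed = 6000 + s)
    res <- ibi_qc(dirty$series)
    if (!res$report$accepted) return(NA_real_)
    rmssd(res$intervals) / rmssd(clean)
  }, 0)
  ratio <- ratio[!is.na(ratio)]
  expect_gt(length(ratio), 150)
  expect_lt(abs(mean(ratio) - 1), 0.05)
})

test_that("session-level QC grids windows and reports counts", {
  s <- gen_ibi(7, 750, 900, seed = 9, session = "sess")
  res <- qc_session(s, herd_config()$qc)
  expect_equal(nrow(res$windows), 3)
  expect_equal(res$windows$start_s, c(0, 300, 600))
  expect_true(all(res$windows$total > 350))
  expect_true(all(res$windows$accepted))       # clean series passes everywhere
  expect_equal(sum(res$windows$flagged), 0)

  ## heavy contamination in one region rejects that window only
  x <- s$intervals
  x[420:426] <- x[420:426] * 2                 # long run inside window 2
  s2 <- ibi_series(x, start = s$start, cow = s$cow, session = s$session)
  res2 <- qc_session(s2, herd_config()$qc)
  expect_false(res2$windows$accepted[2])
  expect_true(res2$windows$accepted[1])
})
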