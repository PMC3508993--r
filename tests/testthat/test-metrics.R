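flat_trace <- function(v = 0, n = 200, dt = 0.5, lum = 10) {
  erg_trace(rep(v, n), dt_ms = dt, luminance_cdsm2 = lum)
}

test_that("trace averaging is the pointwise mean and enforces five repeats", {
  tr <- erg_trace(sin(seq(0, 3, length.out = 120)) * 50, dt_ms = 0.25,
                  luminance_cdsm2 = 377.23)
  avg <- average_traces(rep(list(tr), 5))
  expect_equal(avg$voltage_uV, tr$voltage_uV)
  zero <- erg_trace(rep(0, 120), dt_ms = 0.25, luminance_cdsm2 = 377.23)
  dbl <- erg_trace(tr$voltage_uV * 2, dt_ms = 0.25,
                   luminance_cdsm2 = 377.23)
  avg2 <- average_traces(list(tr, zero, dbl, zero, dbl))
  expect_equal(avg2$voltage_uV, tr$voltage_uV)  # (1+0+2+0+2)/5 = 1
  expect_error(average_traces(rep(list(tr), 4)), "expected 5")
  short <- erg_trace(rep(0, 60), dt_ms = 0.25, luminance_cdsm2 = 377.23)
  expect_error(average_traces(list(tr, tr, tr, tr, short)), "share")
})

test_that("b-wave amplitude is baseline-to-peak and shift invariant", {
  expect_equal(bwave_amplitude(flat_trace(0)), 0)
  v <- rep(-5, 200)
  v[100] <- 115  # peak after the stimulus at t0 = 20 ms
  tr <- erg_trace(v, dt_ms = 0.5, luminance_cdsm2 = 377.23)
  expect_equal(bwave_amplitude(tr), 120)
  shifted <- erg_trace(v + 33.3, dt_ms = 0.5, luminance_cdsm2 = 377.23)
  expect_equal(bwave_amplitude(shifted), 120)
  # the average of identical traces has the single-trace amplitude
  expect_equal(bwave_amplitude(average_traces(rep(list(tr), 5))), 120)
  expect_error(erg_trace(v, t0_ms = 5, baseline_ms = 20), "baseline")
})

test_that("acuity threshold is the highest frequency with a monotone run of >70% success", {
  lv <- c(0.087, 0.2, 0.3, 0.4, 0.55)
  expect_equal(
    perception_threshold(lv, successes = c(18, 16, 15, 12, 10),
                         trials = rep(20, 5)),
    0.3)  # 15/20 = 0.75 > 0.70 strictly; 12/20 fails
  # exactly 70% does not pass (strict criterion)
  expect_equal(
    perception_threshold(lv, successes = c(18, 14, 15, 12, 10),
                         trials = rep(20, 5)),
    0.087)
  expect_true(is.na(
    perception_threshold(lv, successes = rep(14, 5), trials = rep(20, 5))))
  expect_error(perception_threshold(c(0.1, 0.3, 0.2), c(1, 1, 1),
                                    c(2, 2, 2)), "monotone")
})

test_that("contrast threshold walks from high contrast toward the lowest passing level", {
  lv <- c(1, 3, 7, 15, 30, 60, 90)
  succ <- c(10, 12, 15, 16, 17, 18, 18)
  thr <- perception_threshold(lv, succ, rep(20, 7),
                              direction = "lowest_passing")
  expect_equal(thr, 7)  # 15/20 passes at 7%, 12/20 fails at 3%
})

test_that("raising the criterion never lowers sensitivity (acuity threshold monotone)", {
  set.seed(5)
  lv <- seq(0.1, 0.5, length.out = 6)
  for (i in 1:20) {
    succ <- sort(sample(10:20, 6, replace = TRUE), decreasing = TRUE)
    t1 <- perception_threshold(lv, succ, rep(20, 6), criterion = 0.6)
    t2 <- perception_threshold(lv, succ, rep(20, 6), criterion = 0.8)
    if (is.na(t2)) next
    expect_lte(t2, t1)
  }
})

test_that("delta-delta-Ct relative quantification follows its closed form", {
  r <- ddct_rq(c(20.0, 20.2, 19.8), c(18.0, 18.0, 18.0),
               calibrator_dct = 2)
  expect_equal(r$dct, 2)
  expect_equal(r$ddct, 0)
  expect_equal(r$rq, 1)
  expect_false(r$flagged)
  r2 <- ddct_rq(c(19, 19, 19), c(18, 18, 18), calibrator_dct = 2)
  expect_equal(r2$rq, 2)  # ddCt = -1
  # shifting all target Cts by -1 doubles Rq exactly
  base <- ddct_rq(c(21, 21.3, 20.7), c(17, 17, 17), calibrator_dct = 1.5)
  shifted <- ddct_rq(c(21, 21.3, 20.7) - 1, c(17, 17, 17),
                     calibrator_dct = 1.5)
  expect_equal(shifted$rq, 2 * base$rq)
  flagged <- ddct_rq(c(19, 20.5, 19), c(18, 18, 18), calibrator_dct = 0)
  expect_true(flagged$flagged)
  expect_error(ddct_rq(c(19, 19), c(18, 18, 18), 0), "replicates")
})

test_that("ddct_table normalizes the treated group to the calibrator group", {
  ct <- rbind(
    data.frame(sample = c("s1", "s2"), group = "ST", gene = "BDNF",
               ct1 = c(24, 25), ct2 = c(24, 25), ct3 = c(24, 25)),
    data.frame(sample = c("e1", "e2"), group = "EE", gene = "BDNF",
               ct1 = c(23, 23), ct2 = c(23, 23), ct3 = c(23, 23)),
    data.frame(sample = c("s1", "s2", "e1", "e2"), group = rep(c("ST", "EE"),
               each = 2), gene = "GAPDH", ct1 = 18, ct2 = 18, ct3 = 18))
  out <- ddct_table(ct)
  st <- out[out$group == "ST", ]
  expect_equal(mean(log2(st$rq)), 0)  # calibrator group centers at Rq 1
  ee <- out[out$group == "EE", ]
  # EE dCt = 5 vs calibrator 6.5 -> Rq = 2^1.5
  expect_equal(ee$rq, rep(2^1.5, 2))
})

test_that("densitometry normalization and group comparison behave as ratios", {
  expect_equal(densitometry_normalize(3, 3), 1)
  expect_equal(densitometry_normalize(c(2, 4), c(1, 2)), c(2, 2))
  k <- 17.3
  expect_equal(densitometry_normalize(2 * k, 1 * k),
               densitometry_normalize(2, 1))
  expect_error(densitometry_normalize(1, 0), "positive")
  expect_equal(group_percent_difference(1.35, 1.00), 35)
})

test_that("ERG CSV reader round-trips a uniformly sampled trace", {
  tf <- withr::local_tempfile(fileext = ".csv")
  t_ms <- seq(0, 99.5, 0.5)
  write.csv(data.frame(time_ms = t_ms, voltage_uV = sin(t_ms)), tf,
            row.names = FALSE)
  tr <- read_erg_csv(tf, luminance_cdsm2 = 0.09)
  expect_equal(tr$dt_ms, 0.5)
  expect_equal(length(tr$voltage_uV), 200)
  bad <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(time_ms = c(0, 1, 3), voltage_uV = 0:2), bad,
            row.names = FALSE)
  expect_error(read_erg_csv(bad), "uniform")
})
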