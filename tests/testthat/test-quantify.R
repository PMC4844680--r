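test_that("nuclear enrichment is the nuc-cyt difference with NA propagation", {
  expect_equal(nuclear_enrichment(c(100, 150), c(100, 100)), c(0, 50))
  expect_equal(nuclear_enrichment(c(1, NA, 3), c(1, 1, 1)), c(0, NA, 2))
})

test_that("basal level averages the first two post-stimulus frames", {
  times <- seq(0, 10, 2)
  expect_equal(basal_level(c(5, 7, 9, 9, 9, 9), times, 0), 6)
  expect_equal(basal_level(rep(4, 6), times, 0), 4)
  # on a 35 s grid the rule picks the frames at 0 and 0.583 min
  t35 <- seq(0, 5, 35 / 60)
  v <- seq_along(t35)
  expect_equal(basal_level(v, t35, 0), mean(v[1:2]))
  # stimulus mid-movie: first two frames at/after it
  expect_equal(basal_level(c(1, 1, 10, 20, 30, 30), times, 4), 15)
  expect_error(basal_level(c(1, 2), c(0, 2), 2), "two frames")
})

test_that("three-point moving average truncates its window at the ends", {
  expect_equal(moving_average3(c(0, 3, 0)), c(1.5, 1, 1.5))
  expect_equal(moving_average3(rep(2, 5)), rep(2, 5))
  # interior impulse attenuated threefold
  x <- c(0, 0, 6, 0, 0)
  expect_equal(moving_average3(x)[3], 2)
  expect_error(moving_average3(c(1, 2)), "3 frames")
})

test_that("corrected enrichment subtracts basal from the smoothed trace", {
  expect_equal(corrected_enrichment(rep(7, 4), 3), rep(4, 4))
})

test_that("expression output is the max of the corrected trace, NA-safe", {
  expect_equal(expression_output(c(0, 1, 3, 2)), 3)
  expect_equal(expression_output(c(-4, -2, -7)), -2)
  expect_equal(expression_output(c(NA, 1, NA)), 1)
  expect_true(is.na(expression_output(c(NA_real_, NA_real_))))
})

test_that("expression threshold is the 99th percentile of controls", {
  expect_equal(expression_threshold(rep(3, 25)), 3)
  set.seed(1)
  x <- rnorm(1e5)
  expect_equal(expression_threshold(x), qnorm(0.99), tolerance = 0.02)
  # self-classification rate ~1%
  expect_equal(mean(x >= expression_threshold(x)), 0.01, tolerance = 0.002)
  expect_error(expression_threshold(rnorm(10)), "20 control")
})

test_that("time to threshold is the first crossing time or NA", {
  times <- c(0, 2, 4, 6)
  expect_equal(time_to_threshold(c(0, 1, 3, 2), times, 2), 4)
  expect_true(is.na(time_to_threshold(c(0, 1, 1, 1), times, 2)))
  expect_equal(time_to_threshold(c(5, 1, 1, 1), times, 2), 0)
})

test_that("time to half-max works on the raw trace with earliest-tie rule", {
  times <- c(0, 2, 4, 6)
  expect_equal(time_to_half_max(c(0, 2, 4, 4), times), 2)
  expect_equal(time_to_half_max(seq(0, 10, length.out = 4), times,
                                basal = 0), 4)
  expect_equal(time_to_half_max(c(9, 0, 0, 0), times), 0)
  expect_true(is.na(time_to_half_max(c(0, -1, -2, -1), times)))
})

test_that("hog1 signalling output integrates the basal-subtracted ratio", {
  times <- c(0, 2, 4, 6)
  pop <- c(1, 1.5, 1.5, 1)
  m <- hog1_metrics(nuc_mean = 100 * pop, cyt_mean = rep(100, 4),
                    times = times, population_ratio = pop,
                    window = c(0, 6))
  # trapezoid of (0, .5, .5, 0) over 2-min spacing
  expect_equal(m$signaling_output, 2.0)
  # flat ratio integrates to zero
  m0 <- hog1_metrics(rep(100, 4), rep(100, 4), times, rep(1, 4),
                     window = c(0, 6))
  expect_equal(m0$signaling_output, 0)
  # zero cytoplasm gives a missing ratio, not Inf
  mz <- hog1_metrics(c(100, 100, 100, 100), c(100, 0, 100, 100), times,
                     pop, window = c(0, 6))
  expect_true(is.na(mz$ratio[2]))
})

test_that("the activity window tracks the population pulse", {
  times <- seq(0, 40, 2)
  pop <- 1 + pmax(0, 0.6 * (exp(-(times) / 8) - exp(-times / 0.7)))
  w <- dpstr:::hog1_activity_window(pop, times, delta_frac = 0.05)
  expect_lt(w[1], 4)
  expect_gt(w[2], 15)
  expect_lt(w[2], 40)
})

test_that("pp7 site statistic: top-20 mean minus nuclear mean", {
  expect_equal(pp7_site_intensity(rep(10, 100)), 0)
  px <- c(rep(10, 99), 110)
  expect_equal(pp7_site_intensity(px), 4)  # top20 = 15, mean = 11
  expect_equal(pp7_site_intensity(px + 7), 4)  # shift invariant
  expect_error(pp7_site_intensity(rep(1, 19)), "at least 20")
})

test_that("promoter delay requires both reporters expressing", {
  expect_equal(promoter_delay(10, 11.5), 1.5)
  expect_equal(promoter_delay(10, 10), 0)
  expect_true(is.na(promoter_delay(10, NA)))
  expect_true(is.na(promoter_delay(10, 12, expressing_b = FALSE)))
})

test_that("half-life fit recovers noiseless exponentials to high precision", {
  t <- seq(0, 20, 1)
  fit <- halflife_from_chase(100 * 2^(-t / 2), t, arrest_time = 0)
  expect_equal(fit$halflife, 2, tolerance = 1e-8)
  for (h in c(0.5, 3, 17)) {
    f <- halflife_from_chase(50 * 2^(-t / h), t, arrest_time = 0)
    expect_equal(f$halflife, h, tolerance = 1e-6)
  }
  expect_equal(unname(coef(fit)["halflife"]), fit$halflife)
})

test_that("non-decaying chase traces yield NA with a diagnostic", {
  t <- 0:10
  f <- halflife_from_chase(exp(0.1 * t), t, arrest_time = 0)
  expect_true(is.na(f$halflife))
  expect_match(f$diagnostic, "decay")
})

test_that("expression_metrics errors on a missing required column", {
  df <- data.frame(track_id = 1, time_min = 0, channel = "a",
                   nuc_mean = 1)
  expect_error(expression_metrics(df, "a"), "cyt_mean")
})

test_that("expression_metrics reproduces the manual chain on a known trace", {
  times <- seq(0, 12, 2)
  nuc <- c(105, 104, 110, 130, 150, 140, 120)
  cyt <- rep(100, 7)
  df <- data.frame(track_id = 1L, time_min = times, channel = "x",
                   nuc_mean = nuc, cyt_mean = cyt)
  m <- expression_metrics(df, "x", stimulus_time = 0, threshold = 10)
  enr <- nuc - cyt
  bas <- mean(enr[1:2])
  cor <- moving_average3(enr) - bas
  expect_equal(m$expression_output, max(cor))
  expect_equal(m$time_to_threshold, times[which(cor >= 10)[1]])
  expect_equal(m$time_to_half_max,
               times[which(enr - bas >= max(enr - bas) / 2)[1]])
  expect_true(m$expressing)
})
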