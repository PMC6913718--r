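test_that("single events are accepted or rejected by the accuracy rule", {
  st <- new_baseline_state(300)
  st <- update_baseline(st, list(hr_bpm = 70, accuracy = 2L), min_accuracy = 1)
  expect_equal(st$n_valid, 1L)
  st2 <- update_baseline(st, list(hr_bpm = 70, accuracy = 0L), min_accuracy = 1)
  expect_equal(st2$n_valid, 1L)  # rejected, state unchanged
  expect_equal(st2$mean, st$mean)
})

test_that("accumulation completes at exactly the target and then refuses updates", {
  ev <- make_events(seq(0, 399000, 1000), hr_bpm = rnorm(400, 70, 4))
  st <- accumulate_baseline(new_baseline_state(300), ev)
  expect_true(baseline_complete(st))
  expect_equal(st$n_valid, 300L)
  expect_error(update_baseline(st, list(hr_bpm = 70, accuracy = 3L)),
               "complete")
  # interleaved rejected samples never count toward completion
  set.seed(21)
  ev2 <- make_events(seq(0, 799000, 1000), hr_bpm = rnorm(800, 70, 4),
                     accuracy = rep(c(0L, 3L), 400))
  st2 <- accumulate_baseline(new_baseline_state(300), ev2)
  expect_equal(st2$n_valid, 300L)
  # the accepted multiset is exactly the first 300 accuracy-3 samples
  expect_equal(st2$mean, mean(ev2$hr_bpm[ev2$accuracy == 3L][1:300]),
               tolerance = 1e-12)
})

test_that("zero-variance samples force the SD floor", {
  ev <- make_events(seq(0, 299000, 1000), hr_bpm = 70)
  b <- finalize_baseline(accumulate_baseline(new_baseline_state(300), ev),
                         sd_floor = 1.0)
  expect_equal(b$mean_hr, 70)
  expect_equal(b$sd_hr, 1.0)
  expect_false(b$overridden)
})

test_that("finalized mean and SD match a brute-force recomputation", {
  set.seed(42)
  hr <- rnorm(300, 72, 6)
  ev <- make_events(seq(0, 299000, 1000), hr)
  b <- finalize_baseline(accumulate_baseline(new_baseline_state(300), ev))
  expect_equal(b$mean_hr, sum(hr) / 300, tolerance = 1e-9)
  expect_equal(b$sd_hr, sqrt(sum((hr - mean(hr))^2) / 299), tolerance = 1e-9)
})

test_that("alternating 60/80 gives mean 70 and the closed-form sample SD", {
  ev <- make_events(seq(0, 299000, 1000), rep(c(60, 80), 150))
  b <- finalize_baseline(accumulate_baseline(new_baseline_state(300), ev))
  expect_equal(b$mean_hr, 70)
  expect_equal(b$sd_hr, sqrt(300 * 100 / 299), tolerance = 1e-12)
})

test_that("finalize depends only on the accepted multiset, not its order", {
  set.seed(7)
  hr <- rnorm(300, 68, 5)
  ev1 <- make_events(seq(0, 299000, 1000), hr)
  ev2 <- make_events(seq(0, 299000, 1000), sample(hr))
  b1 <- finalize_baseline(accumulate_baseline(new_baseline_state(300), ev1))
  b2 <- finalize_baseline(accumulate_baseline(new_baseline_state(300), ev2))
  expect_equal(b1$mean_hr, b2$mean_hr, tolerance = 1e-9)
  expect_equal(b1$sd_hr, b2$sd_hr, tolerance = 1e-9)
})

test_that("finalizing an incomplete state reports the shortfall", {
  ev <- make_events(seq(0, 199000, 1000), rnorm(200, 70, 4))
  st <- accumulate_baseline(new_baseline_state(300), ev)
  expect_error(finalize_baseline(st), "100 more", class = "pcea_data_error")
})

test_that("manual override replaces the values and marks the baseline", {
  ev <- make_events(seq(0, 299000, 1000), rnorm(300, 72, 6))
  b <- finalize_baseline(accumulate_baseline(new_baseline_state(300), ev))
  o <- override_baseline(b, 65, 8)
  expect_equal(o$mean_hr, 65)
  expect_equal(o$sd_hr, 8)
  expect_true(o$overridden)
  expect_equal(o$n, b$n)
  expect_error(override_baseline(b, 65, 0))
  expect_error(override_baseline(b, -1, 8))
  # classification follows the overridden values, not the measured ones
  hr <- 65 + 2.5 * 8
  expect_equal(classify_level(hr, o), 3L)
  expect_equal(classify_level(hr, b),
               oracle_level(hr, b$mean_hr, b$sd_hr, 1))
})

test_that("calibrate_baseline uses the first target_n valid samples", {
  set.seed(5)
  ev <- make_events(seq(0, 499000, 1000), rnorm(500, 75, 5),
                    accuracy = sample(c(0L, 3L), 500, TRUE, prob = c(0.2, 0.8)))
  cfg <- engine_config()
  b <- calibrate_baseline(ev, cfg)
  keep <- ev$hr_bpm[ev$accuracy >= 1][1:300]
  expect_equal(b$mean_hr, mean(keep), tolerance = 1e-12)
  expect_equal(b$sd_hr, sd(keep), tolerance = 1e-12)
  expect_error(calibrate_baseline(ev[1:100, ], cfg), "missing",
               class = "pcea_data_error")
})

test_that("baselines persist through JSON round-trip", {
  b <- ref_baseline(71.25, 5.5)
  path <- withr::local_tempfile(fileext = ".json")
  write_baseline(b, path)
  expect_equal(read_baseline(path), b)
})

test_that("parameter recovery stays within CLT and chi-square bounds", {
  # i.i.d. streams (no autocorrelation, no episodes, no dropout)
  mu <- 72; sigma <- 6; n <- 300
  alpha <- 1e-4
  lo <- sigma * sqrt(qchisq(alpha / 2, n - 1) / (n - 1))
  hi <- sigma * sqrt(qchisq(1 - alpha / 2, n - 1) / (n - 1))
  for (s in 1:100) {
    sim <- simulate_stream(sim_spec(duration_s = n, mu_hr = mu,
                                    sigma_hr = sigma, ar_coef = 0,
                                    dropout_rate = 0, seed = s))
    b <- calibrate_baseline(sim$events, engine_config())
    expect_lt(abs(b$mean_hr - mu), 4 * sigma / sqrt(n))
    expect_gt(b$sd_hr, lo)
    expect_lt(b$sd_hr, hi)
  }
})

test_that("tidy and glance summarise a baseline", {
  b <- ref_baseline(70, 5)
  td <- tidy(b)
  expect_equal(td$term, c("mean_hr", "sd_hr"))
  expect_equal(td$estimate, c(70, 5))
  gl <- glance(b)
  expect_true(gl$overridden)
  expect_equal(gl$sd_floor, 1)
})
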