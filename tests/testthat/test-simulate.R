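test_that("zero dropout gives all accuracy 3; dropout marks with -1 or 0", {
  sim <- simulate_stream(sim_spec(duration_s = 120, dropout_rate = 0, seed = 1L))
  expect_true(all(sim$events$accuracy == 3L))
  noisy <- simulate_stream(sim_spec(duration_s = 2000, dropout_rate = 0.3,
                                    seed = 2L))
  expect_true(all(noisy$events$accuracy %in% c(-1L, 0L, 3L)))
  frac <- mean(noisy$events$accuracy < 1L)
  expect_gt(frac, 0.25); expect_lt(frac, 0.35)
  # dropout samples still carry plausible heart-rate values
  expect_true(all(is.finite(noisy$events$hr_bpm)))
})

test_that("identical spec and seed reproduce the stream exactly", {
  spec <- sim_spec(duration_s = 300, dropout_rate = 0.1, seed = 77L,
                   episodes = tibble::tibble(start_s = 60, end_s = 120,
                                             delta_bpm = 12, shape = "step"),
                   movement = tibble::tibble(start_s = 200, end_s = 250,
                                             intensity = "light"))
  s1 <- simulate_stream(spec)
  s2 <- simulate_stream(spec)
  expect_identical(s1$events, s2$events)
  expect_identical(s1$accel, s2$accel)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_stream(sim_spec(duration_s = 300, dropout_rate = 0.1,
                                 seed = 78L))
  expect_false(identical(s1$events$hr_bpm, s3$events$hr_bpm))
})

test_that("clean-sample mean honours the CLT bound across 100 seeds", {
  mu <- 72; sigma <- 6
  for (s in 1:100) {
    sim <- simulate_stream(sim_spec(duration_s = 600, mu_hr = mu,
                                    sigma_hr = sigma, ar_coef = 0,
                                    dropout_rate = 0, seed = 2000L + s))
    expect_lt(abs(mean(sim$events$hr_bpm) - mu), 4 * sigma / sqrt(600))
  }
})

test_that("a +3 sigma step episode classifies to level 4 under normal sensitivity", {
  mu <- 72; sigma <- 6
  sim <- simulate_stream(sim_spec(duration_s = 600, mu_hr = mu,
                                  sigma_hr = sigma, ar_coef = 0,
                                  dropout_rate = 0, seed = 9L,
                                  episodes = tibble::tibble(
                                    start_s = 200, end_s = 440,
                                    delta_bpm = 3 * sigma, shape = "step")))
  b <- ref_baseline(mu, sigma)
  inside <- sim$events$timestamp >= 200e3 & sim$events$timestamp < 440e3
  expect_equal(classify_level(mean(sim$events$hr_bpm[inside]), b), 4L)
})

test_that("modal emitted level during a step episode recovers floor(a)+1", {
  mu <- 72; sigma <- 6
  b <- ref_baseline(mu, sigma)
  for (a in c(1.2, 2.5, 3.7)) {
    sim <- simulate_stream(sim_spec(duration_s = 600, mu_hr = mu,
                                    sigma_hr = sigma, ar_coef = 0.5,
                                    dropout_rate = 0, seed = round(100 * a),
                                    episodes = tibble::tibble(
                                      start_s = 120, end_s = 480,
                                      delta_bpm = a * sigma, shape = "step")))
    win <- evaluate_windows(sim$events, b, engine_config())
    ep <- win[win$timestamp >= 130e3 & win$timestamp < 480e3, ]
    modal <- as.integer(names(which.max(table(ep$level_effective))))
    expect_equal(modal, floor(a) + 1)
  }
})

test_that("activity ground truth is recovered on at least 99% of windows", {
  sim <- simulate_stream(sim_spec(
    duration_s = 1200, seed = 21L, dropout_rate = 0,
    movement = tibble::tibble(start_s = c(120, 400, 800),
                              end_s = c(240, 600, 1000),
                              intensity = c("light", "vigorous", "vigorous"))))
  b <- ref_baseline(72, 6)
  win <- evaluate_windows(sim$events, b, engine_config(), sim$accel)
  # ground-truth label per window = label of the samples it covers (modal)
  t0 <- min(sim$truth$timestamp)
  idx <- floor((sim$truth$timestamp - t0) / 10000) + 1
  truth_win <- vapply(seq_len(nrow(win)), function(k) {
    labs <- sim$truth$activity[idx == k]
    names(which.max(table(labs)))
  }, character(1))
  expect_gte(mean(win$activity == truth_win), 0.99)
})

test_that("spec validation rejects out-of-range parameters", {
  expect_error(sim_spec(duration_s = -5))
  expect_error(sim_spec(duration_s = 60, ar_coef = 1))
  expect_error(sim_spec(duration_s = 60, dropout_rate = 1.5))
  expect_error(sim_spec(duration_s = 60,
                        episodes = tibble::tibble(start_s = 10, end_s = 90,
                                                  delta_bpm = 5, shape = "step")))
  expect_error(sim_spec(duration_s = 60,
                        movement = tibble::tibble(start_s = 0, end_s = 30,
                                                  intensity = "sprinting")))
})

test_that("sim specs load from YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "duration_s: 120", "mu_hr: 70", "sigma_hr: 5", "ar_coef: 0.8",
    "dropout_rate: 0.1", "seed: 42",
    "episodes:", "  - start_s: 30", "    end_s: 60", "    delta_bpm: 10",
    "    shape: step"), path)
  spec <- read_sim_spec(path)
  expect_equal(spec$mu_hr, 70)
  expect_equal(nrow(spec$episodes), 1L)
  sim <- simulate_stream(spec)
  expect_equal(nrow(sim$events), 120L)
})

test_that("fixtures behave as their scenarios promise", {
  dir <- withr::local_tempdir()
  # calm day: the initial level and nothing else
  fx <- make_fixture("calm_day", file.path(dir, "calm"))
  run <- run_stream(read_event_log(fx[["events"]]), read_baseline(fx[["baseline"]]),
                    engine_config(), read_accel_log(fx[["accel"]]))
  expect_equal(nrow(run), 1L)
  expect_equal(run$level[1], 1L)
  # ramp: strictly ascending through the levels while the ramp lasts
  fx <- make_fixture("ramp", file.path(dir, "ramp"))
  rrun <- run_stream(read_event_log(fx[["events"]]), read_baseline(fx[["baseline"]]))
  up <- rrun[rrun$timestamp < 480e3, ]
  expect_equal(up$level, sort(up$level))
  expect_equal(sort(unique(up$level)), 1:5)
  # exercise: changes recorded, zero notifications during vigorous spans
  fx <- make_fixture("exercise", file.path(dir, "ex"))
  events <- read_event_log(fx[["events"]])
  accel <- read_accel_log(fx[["accel"]])
  xrun <- run_stream(events, read_baseline(fx[["baseline"]]), engine_config(),
                     accel)
  vig <- xrun$activity == "vigorous"
  expect_gt(sum(vig), 0)
  notes <- notify_policy(xrun, engine_config())
  expect_equal(nrow(notes[notes$timestamp %in% xrun$timestamp[vig], ]), 0L)
})
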