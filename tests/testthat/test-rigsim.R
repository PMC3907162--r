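assoc_plan <- function() {
  set.seed(1)
  plan_trial(task_spec("ASSOCIATION"))
}

score_trace <- function(gaze, window_deg = 2, image_deg = 4) {
  cal <- dac_calibration()
  cfg <- monitor_config(
    window = c(deg_to_dac(cal, -window_deg, 0)[1],
               deg_to_dac(cal, window_deg, 0)[1],
               deg_to_dac(cal, 0, -window_deg)[2],
               deg_to_dac(cal, 0, window_deg)[2]),
    t_acquire_steps = 500 * 1000, t_initial_fix_steps = 300 * 1000,
    t_reward_fix_steps = 500 * 1000, reward_steps = 50000)
  half <- image_deg / 2
  test_win <- c(2048 - 100 * half, 2048 + 100 * half,
                2048 - 100 * half, 2048 + 100 * half)
  dac <- data.frame(t_us = gaze$t_us, x = round(100 * gaze$x + 2048),
                    y = round(100 * gaze$y + 2048))
  run_trial(dac, cfg, test_win)
}

test_that("deterministic compliance and refusal policies score as expected", {
  plan <- assoc_plan()
  g <- generate_gaze(plan, subject_policy(1, 1, 1), seed = 2)
  expect_identical(score_trace(g)$outcome, "REWARDED")
  g0 <- generate_gaze(plan, subject_policy(0, 1, 1), seed = 2)
  expect_identical(score_trace(g0)$outcome, "FAIL_ACQUIRE")
  gh <- generate_gaze(plan, subject_policy(1, 0, 1), seed = 2)
  expect_identical(score_trace(gh)$outcome, "FAIL_HOLD")
  gt <- generate_gaze(plan, subject_policy(1, 1, 0), seed = 2)
  expect_identical(score_trace(gt)$outcome, "FAIL_TEST")
})

test_that("compliance draws drive outcome rates binomially", {
  plan <- assoc_plan()
  pol <- subject_policy(0.8, 0.9, 1.0)
  set.seed(31)
  outcomes <- replicate(200, score_trace(generate_gaze(plan, pol))$outcome)
  frac <- mean(outcomes == "REWARDED")
  expect_lt(abs(frac - 0.72), 3 * sqrt(0.72 * 0.28 / 200))
})

test_that("Poisson spike generation matches its rate specification", {
  m0 <- neuron_model("AUDITORY_ONSET", baseline_hz = 0, response_hz = 0)
  expect_identical(generate_spikes(m0, numeric(0), 1e6, seed = 1),
                   numeric(0))
  # homogeneous 50 Hz for 10 s: count within 3 sqrt(500) of 500
  mh <- neuron_model("AUDITORY_ONSET", baseline_hz = 50, response_hz = 0)
  st <- generate_spikes(mh, numeric(0), 10e6, seed = 4)
  expect_lt(abs(length(st) - 500), 3 * sqrt(500))
  expect_true(all(diff(st) > 0))
  # timestamps live on the 0.1 ms grid
  expect_true(all(st %% 100 == 0))
})

test_that("onset responses carry no rate mass before their latency", {
  m <- neuron_model("AUDITORY_ONSET", baseline_hz = 0, response_hz = 200,
                    latency_ms = 21)
  ev <- seq(0.5, 19.5) * 1e6
  st <- generate_spikes(m, ev, 20e6, seed = 6)
  expect_gt(length(st), 50)
  rel_ms <- sapply(st, function(s) min((s - ev)[s - ev >= 0]) / 1000)
  expect_true(all(rel_ms >= 21))
})

test_that("windowed spike counts pass a chi-square goodness-of-fit test", {
  mh <- neuron_model("AUDITORY_ONSET", baseline_hz = 50, response_hz = 0)
  st <- generate_spikes(mh, numeric(0), 100e6, seed = 12)
  # 100 windows of 1 s, expected 50 counts each
  counts <- tabulate(findInterval(st, seq(0, 100e6, by = 1e6),
                                  rightmost.closed = TRUE), nbins = 100)
  stat <- sum((counts - 50)^2 / 50)
  expect_gt(stats::pchisq(stat, df = 99, lower.tail = FALSE), 0.01)
})

test_that("scan traces respect the configured main sequence", {
  sm <- saccade_model(d0_ms = 20, k_ms_per_deg = 2)
  g <- generate_scan_trace(200, sm = sm, seed = 9)
  sac <- detect_saccades(g)
  expect_gte(nrow(sac), 190)
  dur_ms <- (sac$t_offset_us - sac$t_onset_us) / 1000
  slope <- unname(coef(lm(dur_ms ~ sac$amplitude))[2])
  expect_lt(abs(slope - 2) / 2, 0.1)
})

test_that("recordings have the stated channel layout and re-extractable spikes", {
  set.seed(21)
  dur <- 5e6
  g <- gaze_stream(seq(0, dur, by = 1000),
                   rep(0, dur / 1000 + 1), rep(0, dur / 1000 + 1))
  mh <- neuron_model("AUDITORY_ONSET", baseline_hz = 20, response_hz = 0)
  st <- generate_spikes(mh, numeric(0), dur)
  events <- data.frame(t_us = c(1e6, 3e6), label = "test_on")
  rec <- record_session(g, list(unit1 = st), events, dur, snr = 10)
  expect_identical(nrow(rec$eye), as.integer(dur / 1000 + 1))
  expect_identical(length(rec$neural), as.integer(dur / 1e6 * 25000))
  expect_identical(rec$spike_grid_ms, 0.1)
  # threshold re-extraction recovers >= 99% of generator timestamps
  ext <- extract_spikes_threshold(rec)
  hit <- sapply(st, function(s) any(abs(ext - s) <= 500))
  expect_gte(mean(hit), 0.99)
  expect_error(record_session(g, list(u = c(2e6, 1e6)), events, dur),
               "strictly increasing")
  expect_error(record_session(g, list(u = st), events, dur,
                              neural_rate_hz = 30000), "25000 or 50000")
})

test_that("identical seeds reproduce recordings byte-for-byte", {
  mk <- function() {
    set.seed(99)
    plan <- plan_trial(task_spec("ASSOCIATION"))
    g <- generate_gaze(plan, subject_policy(1, 1, 1))
    dur <- max(g$t_us)
    m <- neuron_model("AUDITORY_ONSET", alignment = "test_on")
    st <- generate_spikes(m, c(1e6), dur)
    record_session(g, list(unit1 = st),
                   data.frame(t_us = 1e6, label = "test_on"), dur)
  }
  expect_identical(rig_hash(mk()), rig_hash(mk()))
})

test_that("recordings round-trip through the plain-text bundle", {
  set.seed(13)
  dur <- 1e6
  g <- gaze_stream(seq(0, dur, by = 1000),
                   stats::rnorm(1001), stats::rnorm(1001))
  st <- generate_spikes(neuron_model(baseline_hz = 30, response_hz = 0),
                        numeric(0), dur)
  rec <- record_session(g, list(unit1 = st),
                        data.frame(t_us = 5e5, label = "reward"), dur)
  dir <- tempfile("rec")
  save_recording(rec, dir)
  back <- load_recording(dir)
  expect_equal(back$spikes$unit1, rec$spikes$unit1)
  expect_equal(back$neural, rec$neural, tolerance = 1e-6)
  expect_equal(back$eye$x, rec$eye$x, tolerance = 1e-6)
  expect_identical(back$neural_rate_hz, rec$neural_rate_hz)
})
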