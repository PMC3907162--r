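test_that("the saccade detector finds constructed movements and no phantoms", {
  # constant-position trace: no events
  flat <- gaze_stream(seq(0, 1e6, by = 1000), rep(0, 1001), rep(3, 1001))
  expect_identical(nrow(detect_saccades(flat)), 0L)
  # one 10-degree rightward saccade
  g1 <- generate_scan_trace(1, amp_range = c(10, 10), jitter_deg = 0.02,
                            seed = 18)
  tru <- attr(g1, "saccades")
  # force a rightward movement by rotating truth into the detector check:
  s1 <- detect_saccades(g1)
  expect_identical(nrow(s1), 1L)
  expect_lt(abs(s1$amplitude - 10), 0.5)
  ang_err <- abs(((s1$angle - tru$angle + 180) %% 360) - 180)
  expect_lt(ang_err, 5)
  # two saccades well apart arrive in order
  g2 <- generate_scan_trace(2, fix_ms = c(500, 500), seed = 19)
  s2 <- detect_saccades(g2)
  expect_identical(nrow(s2), 2L)
  expect_lt(s2$t_onset_us[1], s2$t_onset_us[2])
})

test_that("detection achieves >= 95% hits and <= 5% false alarms", {
  g <- generate_scan_trace(100, jitter_deg = 0.3, seed = 23)
  tru <- attr(g, "saccades")
  sac <- detect_saccades(g)
  hits <- vapply(tru$t_onset_ms, function(t0)
    any(abs(sac$t_onset_us / 1000 - t0) < 25), logical(1))
  fa <- vapply(sac$t_onset_us / 1000, function(t0)
    !any(abs(tru$t_onset_ms - t0) < 25), logical(1))
  expect_gte(mean(hits), 0.95)
  expect_lte(mean(fa), 0.05)
})

test_that("PSTH counts conserve spikes and normalize to rate", {
  ev <- c(1, 2, 3) * 1e6
  expect_identical(build_psth(numeric(0), ev)$counts, rep(0L, 40))
  expect_error(build_psth(numeric(0), numeric(0)), "alignment")
  set.seed(41)
  for (k in 1:20) {
    st <- sort(stats::runif(stats::rpois(1, 300), 0, 4e6))
    align <- sort(stats::runif(sample(1:5, 1), 1e6, 3e6))
    ps <- build_psth(st, align, bin_ms = 10, window_ms = c(-100, 300))
    inwin <- sum(vapply(align, function(a) {
      rel <- (st - a) / 1000
      sum(rel >= -100 & rel < 300)
    }, numeric(1)))
    expect_identical(sum(ps$counts), as.integer(inwin))
    expect_equal(ps$rate_hz,
                 ps$counts / (ps$n_trials * ps$bin_ms / 1000))
    expect_identical(sum(lengths(ps$raster)), as.integer(
      sum(vapply(align, function(a) sum(abs((st - a) / 1000 - 100) <= 200),
                 numeric(1)))))
  }
})

test_that("a 40-repeat PSTH of a 50 Hz neuron calibrates to 0.5 per bin", {
  mh <- neuron_model("AUDITORY_ONSET", baseline_hz = 50, response_hz = 0)
  st <- generate_spikes(mh, numeric(0), 45e6, seed = 51)
  align <- seq(1, 40) * 1e6
  ps <- build_psth(st, align, bin_ms = 10, window_ms = c(-100, 300))
  per_bin_trial <- sum(ps$counts) / (length(ps$counts) * ps$n_trials)
  se <- sqrt(sum(ps$counts)) / (length(ps$counts) * ps$n_trials)
  expect_lt(abs(per_bin_trial - 0.5), 3 * se)
})

test_that("spike density integrates to the mean per-trial count", {
  ev <- 1e6
  zero <- spike_density(numeric(0), ev)
  expect_true(all(zero$rate_hz == 0))
  # single spike at the event: peak at 0, unit integral
  one <- spike_density(ev, ev, sd_ms = 10, window_ms = c(-100, 100))
  expect_equal(one$t_ms[which.max(one$rate_hz)], 0)
  expect_equal(sum(one$rate_hz) * 1 / 1000, 1, tolerance = 1e-3)
  # general case: with every spike > 8 kernel SDs inside the window edges,
  # the windowed integral equals the mean per-trial count to 1e-6 relative
  set.seed(61)
  align <- seq(1, 20) * 1e6
  st <- sort(unlist(lapply(align, function(a)
    a + stats::runif(stats::rpois(1, 40), -150, 350) * 1000)))
  den <- spike_density(st, align, sd_ms = 5, window_ms = c(-200, 400))
  expect_equal(sum(den$rate_hz) / 1000, length(st) / 20, tolerance = 1e-6)
  # 20 trials of 50 Hz: mean level within 3 SE of 50 spikes/s
  mh <- neuron_model("AUDITORY_ONSET", baseline_hz = 50, response_hz = 0)
  st50 <- generate_spikes(mh, numeric(0), 21e6, seed = 62)
  d50 <- spike_density(st50, align, sd_ms = 10, window_ms = c(-100, 300))
  mid <- d50$t_ms >= -50 & d50$t_ms <= 250
  n_mid <- sum(vapply(align, function(a)
    sum(abs((st50 - a) / 1000 - 100) <= 150), numeric(1)))
  se <- sqrt(n_mid) / (20 * 0.3)
  expect_lt(abs(mean(d50$rate_hz[mid]) - 50), 3 * se)
})

test_that("first-peak latency finds step onsets and reports no-response", {
  # constructed clean step at +20 ms over 40 trials
  ev <- seq(1, 40) * 1e6
  st <- sort(unlist(lapply(ev, function(e) e + seq(21, 99, by = 2) * 1000)))
  ps <- build_psth(st, ev, bin_ms = 10)
  lat <- first_peak_latency(ps)
  expect_lt(abs(lat - 20), 5)
  # flat PSTH: distinct "no response", not zero
  set.seed(71)
  flat <- build_psth(sort(stats::runif(400, 0, 41e6)), ev)
  res <- first_peak_latency(flat)
  expect_true(is.na(res))
  expect_true(attr(res, "no_response"))
  expect_error(first_peak_latency(ps, baseline_ms = c(0, 50)), "precede")
})

test_that("latency recovery over synthetic onset neurons is unbiased", {
  set.seed(7)
  errs <- vapply(1:6, function(i) {
    L <- stats::runif(1, 15, 30)
    m <- neuron_model("AUDITORY_ONSET", baseline_hz = 5, response_hz = 80,
                      latency_ms = L)
    ev <- seq(1, 40) * 1e6
    ps <- build_psth(generate_spikes(m, ev, 41e6), ev, bin_ms = 10)
    first_peak_latency(ps) - L
  }, numeric(1))
  expect_lt(mean(abs(errs)), 5)
})

test_that("preferred-vector estimation recovers tuning and flags flatness", {
  g <- generate_scan_trace(150, seed = 3)
  tru <- attr(g, "saccades")
  sac <- data.frame(t_onset_us = tru$t_onset_ms * 1000,
                    amplitude = tru$amplitude, angle = tru$angle)
  dur <- max(tru$t_offset_ms) * 1000 + 1e6
  m <- neuron_model("SC_BUILDUP_BURST", baseline_hz = 10,
                    response_hz = 150, alignment = "saccade")
  # von Mises direction gain peaked at 137 degrees
  gains <- exp(4 * (cos((tru$angle - 137) * pi / 180) - 1))
  st <- generate_spikes(m, tru$t_onset_ms * 1000, dur, gains = gains,
                        seed = 30)
  pv <- preferred_vector(st, sac, burst_ms = c(0, 20))
  expect_true(pv$reliable)
  err <- min(abs(pv$angle - 137), 360 - abs(pv$angle - 137))
  expect_lt(err, 10)
  # direction-independent neuron: flat map, unreliable angle,
  # preferred amplitude near the mean saccade amplitude
  st_flat <- generate_spikes(m, tru$t_onset_ms * 1000, dur, seed = 31)
  pv_flat <- preferred_vector(st_flat, sac, burst_ms = c(0, 20))
  expect_false(pv_flat$reliable)
  expect_lt(abs(pv_flat$amplitude - mean(sac$amplitude)), 3)
  # degenerate inputs
  expect_error(preferred_vector(numeric(0), sac), "insufficient activity")
  expect_error(preferred_vector(st, sac[1:10, ]), "20 saccades")
  narrow <- sac; narrow$angle <- stats::runif(nrow(sac), 10, 40)
  expect_error(preferred_vector(st, narrow), "span")
})
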