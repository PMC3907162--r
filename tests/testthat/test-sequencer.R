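# window in counts: center (2048, 2048), half-width 200
win <- c(1848, 2248, 1848, 2248)

# step trace: piecewise-constant positions given as (ms, x, y) breakpoints
step_trace <- function(..., total_ms = 1500) {
  bp <- list(...)
  t_us <- seq(0, total_ms * 1000, by = 1000)
  x <- numeric(length(t_us)); y <- numeric(length(t_us))
  for (b in bp) {
    idx <- t_us >= b[1] * 1000
    x[idx] <- b[2]; y[idx] <- b[3]
  }
  data.frame(t_us = t_us, x = x, y = y)
}

test_that("window containment is inclusive at the edges, NA is outside", {
  expect_true(in_window(2048, 2048, win))
  expect_true(in_window(2248, 2048, win))     # exactly on x_hi
  expect_true(in_window(1848, 1848, win))     # corner
  expect_false(in_window(2249, 2048, win))    # one count out
  expect_false(in_window(NA, 2048, win))
  expect_identical(in_window(c(2048, 0), c(2048, 0), win), c(TRUE, FALSE))
})

test_that("acquisition is stamped at the first in-window sample", {
  g <- step_trace(c(0, 0, 0), c(150, 2048, 2048))
  r <- monitor_acquire(g, win, 0, 500 * 1000)
  expect_identical(r$state, "SUCCESS")
  expect_identical(r$t_event, 150 * 1000)
  # never entering: failure exactly at the deadline
  g2 <- step_trace(c(0, 0, 0))
  r2 <- monitor_acquire(g2, win, 0, 500 * 1000)
  expect_identical(r2$state, "FAILURE")
  expect_identical(r2$t_event, 500 * 1000)
  # entering exactly at the deadline counts (boundary inclusive)
  g3 <- step_trace(c(0, 0, 0), c(500, 2048, 2048))
  r3 <- monitor_acquire(g3, win, 0, 500 * 1000)
  expect_identical(r3$state, "SUCCESS")
  expect_identical(r3$t_event, 500 * 1000)
  expect_error(monitor_acquire(g3[0, ], win, 0, 1000), "empty")
})

test_that("hold fails at the first excursion, zero-duration holds succeed", {
  g <- step_trace(c(0, 2048, 2048), c(200, 0, 0))
  r <- monitor_hold(g, win, 0, 300 * 1000)
  expect_identical(r$state, "FAILURE")
  expect_identical(r$t_event, 200 * 1000)
  r0 <- monitor_hold(g, win, 0, 0)
  expect_identical(r0$state, "SUCCESS")
  expect_identical(r0$t_event, 0)
  g2 <- step_trace(c(0, 2048, 2048))
  r2 <- monitor_hold(g2, win, 0, 300 * 1000)
  expect_identical(r2$state, "SUCCESS")
  expect_identical(r2$t_event, 300 * 1000)
})

test_that("run_trial chains the three sections and rewards only full compliance", {
  cfg <- oracle_monitor_cfg()
  test_win <- c(2448, 2848, 1848, 2248)   # image window right of fixation
  # compliant: acquire at 100, hold, saccade into the image, hold for reward
  g <- step_trace(c(0, 0, 0), c(100, 2048, 2048), c(400, 2648, 2048))
  bus <- bus_create()
  res <- run_trial(g, cfg, test_win, bus = bus)
  expect_identical(res$outcome, "REWARDED")
  expect_false(is.null(res$reward_pulse))
  expect_identical(bus_log(bus)$endpoint, "reward.dio0")
  # reward time: acquire 100, hold end 300, test acquire 400, + 250 hold
  expect_identical(res$reward_pulse$t_us, 650 * 1000)
  # gaze stays on the extinguished fixation point instead of the image
  g2 <- step_trace(c(0, 0, 0), c(100, 2048, 2048))
  res2 <- run_trial(g2, cfg, test_win)
  expect_identical(res2$outcome, "FAIL_TEST")
  expect_null(res2$reward_pulse)
  # per-trial reset: rerunning either input reproduces its result exactly
  expect_identical(run_trial(g2, cfg, test_win), res2)
  expect_identical(run_trial(g, cfg, test_win)$outcome, "REWARDED")
})

test_that("run_trial matches the sample-by-sample replay oracle on 500 random traces", {
  cfg <- oracle_monitor_cfg()
  test_win <- c(1948, 2348, 1948, 2348)
  set.seed(2024)
  outcomes <- character(0)
  for (k in seq_len(500)) {
    g <- random_dac_trace(cfg)
    got <- run_trial(g, cfg, test_win)
    want <- oracle_run_trial(g, cfg, test_win)
    expect_identical(got$outcome, want$outcome)
    # every event time bit-identical
    expect_identical(vapply(got$transcript, `[[`, 0, "t_event"),
                     vapply(want$reports, `[[`, 0, "t_event"))
    if (got$outcome == "REWARDED")
      expect_identical(got$reward_pulse$t_us, want$reward_t)
    outcomes <- c(outcomes, got$outcome)
  }
  # the random traces exercise every outcome class
  expect_setequal(unique(outcomes),
                  c("REWARDED", "FAIL_ACQUIRE", "FAIL_HOLD", "FAIL_TEST"))
})

test_that("enlarging the forgiveness window never breaks a per-phase success", {
  cfg <- oracle_monitor_cfg()
  grow <- c(-80, 80, -80, 80)
  set.seed(77)
  for (k in seq_len(200)) {
    g <- random_dac_trace(cfg)
    small <- cfg$window; big <- cfg$window + grow
    a_small <- monitor_acquire(g, small, 0, 300 * 1000)
    a_big <- monitor_acquire(g, big, 0, 300 * 1000)
    if (a_small$state == "SUCCESS") {
      expect_identical(a_big$state, "SUCCESS")
      expect_lte(a_big$t_event, a_small$t_event)
    }
    h_small <- monitor_hold(g, small, 0, 200 * 1000)
    if (h_small$state == "SUCCESS")
      expect_identical(monitor_hold(g, big, 0, 200 * 1000)$state, "SUCCESS")
  }
})

test_that("reward pulses equal rewarded outcomes over a session", {
  cfg <- oracle_monitor_cfg()
  test_win <- c(1948, 2348, 1948, 2348)
  bus <- bus_create()
  set.seed(42)
  n_rewarded <- 0L
  for (k in seq_len(60)) {
    g <- random_dac_trace(cfg)
    g$t_us <- g$t_us + (k - 1) * 2e6
    res <- run_trial(g, cfg, test_win, bus = bus)
    if (res$outcome == "REWARDED") n_rewarded <- n_rewarded + 1L
  }
  log <- bus_log(bus)
  expect_identical(sum(log$kind == "ttl" & log$endpoint == "reward.dio0"),
                   n_rewarded)
})
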