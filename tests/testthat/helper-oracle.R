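# Independent sample-by-sample replay simulator for the three-section
# behavioral monitor. Walks the gaze stream one sample at a time with an
# explicit state variable, the way the real-time device would; used as the
# oracle that run_trial must match bit-for-bit.

oracle_inside <- function(x, y, w) {
  isTRUE(!is.na(x) && !is.na(y) &&
         x >= w[1] && x <= w[2] && y >= w[3] && y <= w[4])
}

oracle_run_trial <- function(gaze, cfg, test_window,
                             t_start_us = gaze$t_us[1]) {
  us <- function(steps) steps / cfg$tb$steps_per_ms * 1000
  t_acq <- us(cfg$t_acquire_steps)
  t_fix <- us(cfg$t_initial_fix_steps)
  t_rwd <- us(cfg$t_reward_fix_steps)

  state <- "ACQUIRE"
  deadline <- t_start_us + t_acq
  hold_end <- NA_real_
  reports <- list()
  outcome <- NULL
  reward_t <- NA_real_
  i <- 1L
  n <- nrow(gaze)
  while (is.null(outcome)) {
    if (i > n) stop("oracle: stream exhausted before a decision")
    t <- gaze$t_us[i]; x <- gaze$x[i]; y <- gaze$y[i]
    if (state == "ACQUIRE") {
      if (t > deadline) {
        reports <- c(reports, list(list(phase = "ACQUIRE",
                                        state = "FAILURE",
                                        t_event = deadline)))
        outcome <- "FAIL_ACQUIRE"
      } else if (t >= t_start_us && oracle_inside(x, y, cfg$window)) {
        reports <- c(reports, list(list(phase = "ACQUIRE",
                                        state = "SUCCESS", t_event = t)))
        state <- "HOLD"; hold_end <- t + t_fix
        # do not consume: the hold re-examines this sample
      } else i <- i + 1L
    } else if (state == "HOLD") {
      if (t_fix == 0 || t >= hold_end) {
        reports <- c(reports, list(list(phase = "HOLD", state = "SUCCESS",
                                        t_event = hold_end)))
        state <- "TEST_ACQUIRE"; deadline <- hold_end + t_acq
      } else if (!oracle_inside(x, y, cfg$window)) {
        reports <- c(reports, list(list(phase = "HOLD", state = "FAILURE",
                                        t_event = t)))
        outcome <- "FAIL_HOLD"
      } else i <- i + 1L
    } else if (state == "TEST_ACQUIRE") {
      if (t > deadline) {
        reports <- c(reports, list(list(phase = "TEST", state = "FAILURE",
                                        t_event = deadline)))
        outcome <- "FAIL_TEST"
      } else if (oracle_inside(x, y, test_window)) {
        reports <- c(reports, list(list(phase = "TEST", state = "SUCCESS",
                                        t_event = t)))
        state <- "TEST_HOLD"; hold_end <- t + t_rwd
      } else i <- i + 1L
    } else {                       # TEST_HOLD
      if (t_rwd == 0 || t >= hold_end) {
        reports <- c(reports, list(list(phase = "TEST", state = "SUCCESS",
                                        t_event = hold_end)))
        outcome <- "REWARDED"; reward_t <- hold_end
      } else if (!oracle_inside(x, y, test_window)) {
        reports <- c(reports, list(list(phase = "TEST", state = "FAILURE",
                                        t_event = t)))
        outcome <- "FAIL_TEST"
      } else i <- i + 1L
    }
  }
  list(outcome = outcome, reports = reports, reward_t = reward_t)
}

# zero-duration holds: the oracle above stamps hold_end which equals the
# phase start when the duration is 0, matching monitor_hold's immediate
# SUCCESS at t_start.

# random piecewise-constant gaze trace in DAC counts around a window,
# long enough to cover any outcome path of the given config. Segments are
# drawn inside the window with probability p_in (sticky fixation) so that
# every outcome class is exercised, with occasional NA dropouts.
random_dac_trace <- function(cfg, total_ms = 1500, seg_ms = c(60, 220),
                             p_in = 0.7, na_prob = 5e-4) {
  w <- cfg$window
  spread <- 2.5 * c(diff(w[1:2]), diff(w[3:4]))
  center <- c(mean(w[1:2]), mean(w[3:4]))
  t_us <- seq(0, total_ms * 1000, by = 1000)
  x <- numeric(length(t_us)); y <- numeric(length(t_us))
  i <- 1L
  while (i <= length(t_us)) {
    if (stats::runif(1) < p_in) {
      # fixation dwells are long enough to span hold criteria
      len <- round(stats::runif(1, 250, 700))
      idx <- i:min(i + len - 1L, length(t_us))
      x[idx] <- round(stats::runif(1, w[1], w[2]))
      y[idx] <- round(stats::runif(1, w[3], w[4]))
    } else {
      len <- round(stats::runif(1, seg_ms[1], seg_ms[2]))
      idx <- i:min(i + len - 1L, length(t_us))
      x[idx] <- round(center[1] +
                        sample(c(-1, 1), 1) * stats::runif(1, 0.6, 1) *
                        spread[1])
      y[idx] <- round(center[2] + stats::runif(1, -spread[2], spread[2]))
    }
    i <- i + len
  }
  drop <- stats::runif(length(t_us)) < na_prob
  x[drop] <- NA; y[drop] <- NA
  data.frame(t_us = t_us, x = x, y = y)
}

oracle_monitor_cfg <- function() {
  monitor_config(window = c(1848, 2248, 1848, 2248),
                 t_acquire_steps = 300 * 1000,
                 t_initial_fix_steps = 200 * 1000,
                 t_reward_fix_steps = 250 * 1000,
                 reward_steps = 1000, tb = time_base())
}
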