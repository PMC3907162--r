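#' Sequencer monitoring configuration
#'
#' The variables the real-time sequencer loads at trial initialization: the
#' forgiveness-window edges in DAC counts, the three timing criteria
#' ("Time to get on Target", "Initial Fixation Time", "Fixation Time for
#' Reward") expressed in sequencer steps, and the reward pulse duration in
#' steps. A [time_base()] carries the step-to-clock conversion.
#'
#' @param window numeric vector `c(x_lo, x_hi, y_lo, y_hi)` in DAC counts,
#'   with `x_lo < x_hi` and `y_lo < y_hi`. Edges are inclusive.
#' @param t_acquire_steps time allowed to get on target, in steps.
#' @param t_initial_fix_steps initial fixation hold time, in steps.
#' @param t_reward_fix_steps test-stimulus fixation time for reward, in steps.
#' @param reward_steps reward pulse duration, in steps.
#' @param tb a [time_base()].
#' @return object of class `monitor_config`.
#' @export
monitor_config <- function(window, t_acquire_steps, t_initial_fix_steps,
                           t_reward_fix_steps, reward_steps,
                           tb = time_base()) {
  if (length(window) != 4 || window[1] >= window[2] || window[3] >= window[4])
    stop("window must be c(x_lo, x_hi, y_lo, y_hi) with lo < hi")
  durs <- c(t_acquire_steps, t_initial_fix_steps, t_reward_fix_steps,
            reward_steps)
  if (any(durs < 0)) stop("all durations must be >= 0 steps")
  structure(list(window = as.numeric(window),
                 t_acquire_steps = t_acquire_steps,
                 t_initial_fix_steps = t_initial_fix_steps,
                 t_reward_fix_steps = t_reward_fix_steps,
                 reward_steps = reward_steps, tb = tb),
            class = "monitor_config")
}

#' Window containment test
#'
#' Is a gaze sample (DAC counts) inside the rectangular forgiveness window?
#' Edges are inclusive -- forgiveness semantics, and the zero-width window
#' degenerates sensibly. Missing (NA/NaN) samples count as outside: signal
#' dropout must never earn a reward.
#'
#' @param x,y gaze sample in DAC counts (vectorized).
#' @param window `c(x_lo, x_hi, y_lo, y_hi)` in DAC counts.
#' @return logical vector.
#' @export
in_window <- function(x, y, window) {
  inside <- x >= window[1] & x <= window[2] & y >= window[3] & y <= window[4]
  inside & !is.na(inside)
}

new_fix_report <- function(phase, state, t_event) {
  list(phase = phase, state = state, t_event = t_event)
}

#' Monitor target acquisition
#'
#' First monitoring section: the subject must bring gaze inside the window
#' within the allowed epoch. SUCCESS is stamped at the first sample time
#' inside the window (deadline boundary inclusive); otherwise FAILURE at the
#' deadline.
#'
#' @param gaze data.frame with `t_us`, `x`, `y` in DAC counts.
#' @param window forgiveness window `c(x_lo, x_hi, y_lo, y_hi)`.
#' @param t_start_us phase start time (microseconds).
#' @param deadline_us allowed acquisition epoch (microseconds).
#' @param phase phase label for the report.
#' @return a fixation report `list(phase, state, t_event)`.
#' @export
monitor_acquire <- function(gaze, window, t_start_us, deadline_us,
                            phase = "ACQUIRE") {
  if (nrow(gaze) == 0) stop("monitoring error: empty gaze stream")
  t_end <- t_start_us + deadline_us
  if (max(gaze$t_us) < t_end)
    stop("monitoring error: gaze stream does not cover the acquisition epoch")
  sel <- gaze$t_us >= t_start_us & gaze$t_us <= t_end
  inside <- in_window(gaze$x[sel], gaze$y[sel], window)
  if (any(inside)) {
    new_fix_report(phase, "SUCCESS", gaze$t_us[sel][which(inside)[1]])
  } else {
    new_fix_report(phase, "FAILURE", t_end)
  }
}

#' Monitor fixation hold
#'
#' Second monitoring section: fixation must be maintained inside the window
#' for the specified duration. FAILURE is stamped at the first sample
#' strictly before the duration elapses that falls outside; otherwise
#' SUCCESS at `t_start_us + duration_us`. A zero duration is an immediate
#' SUCCESS.
#'
#' @inheritParams monitor_acquire
#' @param duration_us required hold time (microseconds).
#' @return a fixation report `list(phase, state, t_event)`.
#' @export
monitor_hold <- function(gaze, window, t_start_us, duration_us,
                         phase = "HOLD") {
  if (nrow(gaze) == 0) stop("monitoring error: empty gaze stream")
  t_end <- t_start_us + duration_us
  if (duration_us == 0) return(new_fix_report(phase, "SUCCESS", t_start_us))
  if (max(gaze$t_us) < t_end)
    stop("monitoring error: gaze stream does not cover the hold epoch")
  sel <- gaze$t_us >= t_start_us & gaze$t_us < t_end
  outside <- !in_window(gaze$x[sel], gaze$y[sel], window)
  if (any(outside)) {
    new_fix_report(phase, "FAILURE", gaze$t_us[sel][which(outside)[1]])
  } else {
    new_fix_report(phase, "SUCCESS", t_end)
  }
}

#' Run one trial through the three-section state machine
#'
#' Chains the sequencer's monitoring sections over one gaze stream:
#' \enumerate{
#'   \item ACQUIRE -- get on the fixation target within the acquisition
#'     epoch (`cfg$window`, `t_acquire`);
#'   \item HOLD -- maintain fixation for the initial fixation time
#'     (`cfg$window`, `t_initial_fix`);
#'   \item TEST -- acquire and hold the test stimulus inside its own
#'     image-sized window (`test_window`, acquisition deadline reusing
#'     `t_acquire`, hold time `t_reward_fix`).
#' }
#' If all sections succeed a reward pulse of `cfg$reward_steps` is emitted
#' (on `reward_line` when a bus is supplied). Whatever the outcome, no state
#' survives the call: the sequencer resets to its initial variables, so
#' consecutive trials are independent.
#'
#' @param gaze data.frame with `t_us`, `x`, `y` in DAC counts, covering the
#'   whole trial span.
#' @param cfg a [monitor_config()].
#' @param test_window the image-sized forgiveness window for the test phase,
#'   `c(x_lo, x_hi, y_lo, y_hi)` in DAC counts.
#' @param t_start_us trial start (fixation-target onset), default the first
#'   gaze sample time.
#' @param bus optional [bus_create()] to log the reward pulse on.
#' @param reward_line logic line for the reward pulse.
#' @return object of class `trial_result`: `outcome` (one of REWARDED,
#'   FAIL_ACQUIRE, FAIL_HOLD, FAIL_TEST), `transcript` (ordered fixation
#'   reports), `reward_pulse` (list or NULL).
#' @export
run_trial <- function(gaze, cfg, test_window, t_start_us = NULL,
                      bus = NULL, reward_line = "reward.dio0") {
  stopifnot(inherits(cfg, "monitor_config"))
  if (nrow(gaze) == 0) stop("monitoring error: empty gaze stream")
  if (is.null(t_start_us)) t_start_us <- gaze$t_us[1]
  tb <- cfg$tb
  t_acq <- steps_to_us(tb, cfg$t_acquire_steps)
  t_fix <- steps_to_us(tb, cfg$t_initial_fix_steps)
  t_rwd <- steps_to_us(tb, cfg$t_reward_fix_steps)

  transcript <- list()
  r1 <- monitor_acquire(gaze, cfg$window, t_start_us, t_acq, phase = "ACQUIRE")
  transcript <- c(transcript, list(r1))
  if (r1$state == "FAILURE")
    return(new_trial_result("FAIL_ACQUIRE", transcript, NULL))

  r2 <- monitor_hold(gaze, cfg$window, r1$t_event, t_fix, phase = "HOLD")
  transcript <- c(transcript, list(r2))
  if (r2$state == "FAILURE")
    return(new_trial_result("FAIL_HOLD", transcript, NULL))

  r3a <- monitor_acquire(gaze, test_window, r2$t_event, t_acq,
                         phase = "TEST")
  transcript <- c(transcript, list(r3a))
  if (r3a$state == "FAILURE")
    return(new_trial_result("FAIL_TEST", transcript, NULL))

  r3b <- monitor_hold(gaze, test_window, r3a$t_event, t_rwd, phase = "TEST")
  transcript <- c(transcript, list(r3b))
  if (r3b$state == "FAILURE")
    return(new_trial_result("FAIL_TEST", transcript, NULL))

  dur_ms <- steps_to_ms(tb, cfg$reward_steps)
  pulse <- list(t_us = r3b$t_event, line = reward_line, duration_ms = dur_ms)
  if (!is.null(bus)) emit_ttl(bus, reward_line, r3b$t_event, dur_ms)
  new_trial_result("REWARDED", transcript, pulse)
}

new_trial_result <- function(outcome, transcript, reward_pulse) {
  structure(list(outcome = outcome, transcript = transcript,
                 reward_pulse = reward_pulse),
            class = "trial_result")
}

#' @export
print.trial_result <- function(x, ...) {
  cat(sprintf("<trial_result> %s (%d fixation reports%s)\n", x$outcome,
              length(x$transcript),
              if (!is.null(x$reward_pulse))
                sprintf(", reward at %g us", x$reward_pulse$t_us) else ""))
  invisible(x)
}

#' Summarize trial results as one CSV row
#'
#' @param result a `trial_result`.
#' @param trial_id trial counter.
#' @return one-row data.frame: trial_id, outcome, t_acquire_event, t_fail,
#'   reward_t (microseconds; NA where not applicable).
#' @export
trial_result_row <- function(result, trial_id) {
  tr <- result$transcript
  acq <- tr[[1]]
  t_acq <- if (acq$state == "SUCCESS") acq$t_event else NA_real_
  last <- tr[[length(tr)]]
  t_fail <- if (last$state == "FAILURE") last$t_event else NA_real_
  data.frame(trial_id = trial_id, outcome = result$outcome,
             t_acquire_event = t_acq, t_fail = t_fail,
             reward_t = if (is.null(result$reward_pulse)) NA_real_
                        else result$reward_pulse$t_us)
}
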