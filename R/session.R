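# Closed-loop session runner: controller <-> sequencer <-> presenter <-> rig.

# vectorized degree -> DAC conversion preserving NA (dropout) samples
gaze_to_dac <- function(gaze, cal) {
  cx <- round(cal$gain_x * gaze$x + cal$offset_x)
  cy <- round(cal$gain_y * gaze$y + cal$offset_y)
  bad <- c(cx, cy)
  bad <- bad[!is.na(bad)]
  if (length(bad) && (min(bad) < cal$range[1] || max(bad) > cal$range[2]))
    stop("gaze trace exceeds the DAC range")
  data.frame(t_us = gaze$t_us, x = cx, y = cy)
}

# rectangular window in degrees -> DAC counts
window_to_dac <- function(cal, center_deg, half_deg) {
  lo <- deg_to_dac(cal, center_deg[1] - half_deg[1],
                   center_deg[2] - half_deg[2])
  hi <- deg_to_dac(cal, center_deg[1] + half_deg[1],
                   center_deg[2] + half_deg[2])
  c(min(lo[1], hi[1]), max(lo[1], hi[1]), min(lo[2], hi[2]),
    max(lo[2], hi[2]))
}

#' Default session configuration
#'
#' A complete in-memory configuration for a closed-loop run, mirroring the
#' dialog-box parameters of the original rig: subject, display geometry,
#' eye calibration, time base, task, behavioral policy, window size and
#' reward duration, neurons, trial count and the 2 s inter-trial refresh.
#'
#' @param subject subject name.
#' @param n_trials number of trials.
#' @param task a [task_spec()].
#' @param policy a [subject_policy()].
#' @param window_deg fixation forgiveness-window half-width (degrees).
#' @param image_size_deg test-image size `c(w, h)` degrees; the test-phase
#'   window equals the image size.
#' @param reward_ms reward pulse duration (ms).
#' @param refresh_ms inter-trial black-screen refresh period (ms, default
#'   the 2 s timeout).
#' @param neurons named list of [neuron_model()]s.
#' @param record synthesize the multichannel recording (memory-heavy for
#'   long sessions).
#' @param out_dir output directory for per-trial data files.
#' @return a `session_config` list.
#' @export
session_config <- function(subject = "subj01", n_trials = 20,
                           task = task_spec("ASSOCIATION"),
                           policy = subject_policy(),
                           window_deg = 2, image_size_deg = c(4, 4),
                           reward_ms = 50, refresh_ms = 2000,
                           neurons = list(
                             unit1 = neuron_model("AUDITORY_ONSET",
                                                  alignment = "test_on")),
                           record = FALSE, out_dir = tempdir()) {
  structure(list(subject = subject, n_trials = n_trials, task = task,
                 policy = policy, geometry = display_geometry(
                   121, 68, 1920, 1080),
                 calibration = dac_calibration(), timebase = time_base(),
                 window_deg = window_deg, image_size_deg = image_size_deg,
                 reward_ms = reward_ms, refresh_ms = refresh_ms,
                 neurons = neurons, record = record, out_dir = out_dir),
            class = "session_config")
}

#' Run a closed-loop simulated session
#'
#' The full triad loop, one trial at a time: the controller plans the
#' trial and commands the fixation target through the bus; the presenter
#' answers each token with a frame-quantized display change, a reply and a
#' TTL timestamp; the virtual subject produces a gaze trace; the sequencer
#' replays it through the three monitoring sections and (on success) the
#' reward pulse fires on the reward line; the controller's do-case then
#' commands the test stimulus or the black-screen reset. Trials are
#' separated by the 2 s refresh period. All randomness flows from one seed,
#' so a rerun reproduces the bus log and recording exactly.
#'
#' @param config a [session_config()].
#' @param seed integer seed for the session RNG.
#' @param scenario_schedule optional data.frame with `at_trial` and
#'   `scenario` columns: before the given (1-based) trial the session
#'   switches scenario, rolling the data file over.
#' @return list of class `session_run`: `bus`, `presenter`, `trials`
#'   (data.frame), `events` (data.frame), `files`, `recording` (or NULL),
#'   `config`, `seed`.
#' @export
run_session <- function(config, seed = 1, scenario_schedule = NULL) {
  stopifnot(inherits(config, "session_config"))
  set.seed(seed)
  geom <- config$geometry; cal <- config$calibration; tb <- config$timebase
  task <- config$task

  bus <- bus_create()
  pres <- presenter_create(geom)
  register_default_objects(pres, image_size_deg = config$image_size_deg)
  for (w in names(pres$alias)) {
    local({
      word <- w
      bus_register_handler(bus, "presenter", word, function(wd, t_us) {
        ev <- handle_token(pres, wd, t_us, bus = bus)
        structure(ev$reply, t_us = ev$t_onset_us)
      })
    })
  }

  sess <- session_open(config$subject, task$kind, config$out_dir,
                       params = list(window_deg = config$window_deg,
                                     reward_ms = config$reward_ms))
  timing <- task$timing_ms
  cfg <- monitor_config(
    window = window_to_dac(cal, c(0, 0), rep(config$window_deg, 2)),
    t_acquire_steps = ms_to_steps(tb, timing$t_acquire),
    t_initial_fix_steps = ms_to_steps(tb, timing$t_initial_fix),
    t_reward_fix_steps = ms_to_steps(tb, timing$t_reward_fix),
    reward_steps = ms_to_steps(tb, config$reward_ms), tb = tb)

  t_clock <- 0
  trials <- list(); events <- list(); gaze_all <- list()
  send <- function(word, t_us) {
    reply <- send_command(bus, "controller", "presenter", word, t_us)
    pres$events[[length(pres$events)]]
  }
  for (i in seq_len(config$n_trials)) {
    if (!is.null(scenario_schedule)) {
      hit <- scenario_schedule$at_trial == i
      if (any(hit)) switch_scenario(sess, scenario_schedule$scenario[hit][1])
    }
    plan <- plan_trial(task)
    # F1: black screen, no target -> present the fixation target
    ev_fix <- send(dispatch("PRE", "FAILURE"), t_clock)
    t0 <- ev_fix$t_onset_us
    events[[length(events) + 1L]] <- data.frame(t_us = t0,
                                                label = "fixation_on")
    gaze <- generate_gaze(plan, config$policy, sm = saccade_model())
    gaze$t_us <- gaze$t_us + t0
    test_win <- window_to_dac(cal, plan$target_pos,
                              config$image_size_deg / 2)
    res <- run_trial(gaze_to_dac(gaze, cal), cfg, test_win,
                     t_start_us = t0, bus = NULL)
    tr <- res$transcript
    last <- tr[[length(tr)]]
    if (res$outcome %in% c("FAIL_ACQUIRE", "FAIL_HOLD")) {
      # F2: failure during fixation -> black screen
      ev_end <- send(dispatch("FIX", "FAILURE"), last$t_event)
    } else {
      # S2: initial fixation complete -> present the test stimulus
      ev_test <- send(dispatch("FIX", "SUCCESS"), tr[[2]]$t_event)
      events[[length(events) + 1L]] <-
        data.frame(t_us = ev_test$t_onset_us, label = "test_on")
      if (res$outcome == "REWARDED") {
        emit_ttl(bus, "reward.dio0", res$reward_pulse$t_us,
                 res$reward_pulse$duration_ms)
        events[[length(events) + 1L]] <-
          data.frame(t_us = res$reward_pulse$t_us, label = "reward")
        ev_end <- send(dispatch("TEST", "SUCCESS"), last$t_event)
      } else {
        ev_end <- send(dispatch("TEST", "FAILURE"), last$t_event)
      }
    }
    session_record_trial(sess, res)
    row <- trial_result_row(res, sess$trial_counter)
    row$scenario <- sess$scenario
    row$data_file <- basename(sess$data_file)
    trials[[length(trials) + 1L]] <- row
    gaze_all[[length(gaze_all) + 1L]] <- gaze
    t_clock <- ev_end$t_onset_us + config$refresh_ms * 1000
  }
  files <- session_quit(sess)
  trials <- do.call(rbind, trials)
  events <- do.call(rbind, events)
  duration_us <- t_clock

  recording <- NULL
  if (isTRUE(config$record)) {
    eye <- splice_gaze(gaze_all, duration_us)
    spikes <- list()
    for (nm in names(config$neurons)) {
      m <- config$neurons[[nm]]
      ev_t <- events$t_us[events$label == m$alignment]
      spikes[[nm]] <- generate_spikes(m, ev_t, duration_us)
    }
    recording <- record_session(eye, spikes, events, duration_us)
  }
  structure(list(bus = bus, presenter = pres, trials = trials,
                 events = events, files = files, recording = recording,
                 config = config, seed = seed),
            class = "session_run")
}

# stitch per-trial gaze traces into one continuous 1 kHz session trace,
# holding the last position through the inter-trial refresh
splice_gaze <- function(gaze_all, duration_us, rate_hz = 1000) {
  t_us <- seq(0, duration_us, by = 1e6 / rate_hz)
  x <- rep(NA_real_, length(t_us)); y <- x
  for (g in gaze_all) {
    i0 <- findInterval(g$t_us[1], t_us)
    idx <- i0 + seq_len(min(nrow(g), length(t_us) - i0)) - 1L
    x[idx] <- g$x[seq_along(idx)]
    y[idx] <- g$y[seq_along(idx)]
  }
  # carry last observation forward; lead-in defaults to straight ahead
  locf <- function(v) {
    if (is.na(v[1])) v[1] <- 0
    filled <- !is.na(v)
    v[cummax(ifelse(filled, seq_along(v), 0L))]
  }
  gaze_stream(t_us, locf(x), locf(y))
}

#' @export
print.session_run <- function(x, ...) {
  tab <- table(x$trials$outcome)
  cat(sprintf("<session_run> %d trials (%s), %d bus records, %d data file(s)\n",
              nrow(x$trials),
              paste(names(tab), tab, sep = "=", collapse = ", "),
              length(x$bus$log), length(x$files)))
  invisible(x)
}

#' Summarize a session run
#'
#' @param object a [run_session()] result.
#' @param ... unused.
#' @return list with outcome counts, rewarded fraction and lockstep check.
#' @export
summary.session_run <- function(object, ...) {
  tab <- table(object$trials$outcome)
  list(n_trials = nrow(object$trials),
       outcomes = tab,
       rewarded_fraction = mean(object$trials$outcome == "REWARDED"),
       lockstep = check_lockstep(bus_log(object$bus), require_ttl = TRUE))
}
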