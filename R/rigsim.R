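#' Behavioral policy of the simulated subject
#'
#' Stands in for a trained subject: per-phase compliance probabilities plus
#' reaction-time and fixation-noise parameters. With probabilities
#' `(p_acquire, p_hold, p_target_choice)` the expected rewarded fraction of
#' trials is their product.
#'
#' @param p_acquire probability of acquiring the fixation target in time.
#' @param p_hold probability of maintaining the initial fixation.
#' @param p_target_choice probability of choosing (and holding) the test
#'   stimulus rather than looking elsewhere.
#' @param reaction_ms `c(mean, sd)` of the saccadic reaction latency (ms).
#' @param jitter_deg fixation noise SD in degrees.
#' @return object of class `subject_policy`.
#' @export
subject_policy <- function(p_acquire = 1, p_hold = 1, p_target_choice = 1,
                           reaction_ms = c(180, 30), jitter_deg = 0.1) {
  p <- c(p_acquire, p_hold, p_target_choice)
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  if (reaction_ms[2] < 0 || jitter_deg < 0) stop("SDs must be >= 0")
  structure(list(p_acquire = p_acquire, p_hold = p_hold,
                 p_target_choice = p_target_choice,
                 reaction_ms = reaction_ms, jitter_deg = jitter_deg),
            class = "subject_policy")
}

#' Saccade kinematics model
#'
#' Affine main sequence (`duration = d0 + k * amplitude`) with a
#' raised-cosine (minimum-jerk-like) velocity profile: symmetric, unimodal,
#' zero velocity at both endpoints. Defaults `d0 = 20` ms and
#' `k = 2` ms/degree are standard primate values.
#'
#' @param d0_ms duration intercept (ms).
#' @param k_ms_per_deg duration slope (ms per degree of amplitude).
#' @return object of class `saccade_model`.
#' @export
saccade_model <- function(d0_ms = 20, k_ms_per_deg = 2) {
  if (d0_ms <= 0 || k_ms_per_deg <= 0) stop("main-sequence parameters > 0")
  structure(list(d0_ms = d0_ms, k_ms_per_deg = k_ms_per_deg),
            class = "saccade_model")
}

saccade_duration_ms <- function(sm, amplitude_deg) {
  sm$d0_ms + sm$k_ms_per_deg * amplitude_deg
}

# raised-cosine displacement fraction at phase u in [0,1]
raised_cosine <- function(u) 0.5 * (1 - cos(pi * pmin(pmax(u, 0), 1)))

# band-limited fixation noise: white noise convolved with a Gaussian kernel
# (correlation length l_ms), scaled to SD sd_deg. Fixational drift/tremor is
# slow; unfiltered white noise at 1 kHz would carry implausible
# sample-to-sample velocities (~70 deg/s at 0.1 deg SD).
fixation_noise <- function(n, sd_deg, l_ms = 25, rate_hz = 1000) {
  if (sd_deg <= 0 || n == 0) return(numeric(n))
  l <- l_ms * rate_hz / 1000
  k <- seq(-3 * l, 3 * l)
  g <- exp(-0.5 * (k / l)^2)
  w <- stats::rnorm(n + length(k) - 1, 0, sd_deg / sqrt(sum(g^2)))
  stats::convolve(w, g, type = "filter")[seq_len(n)]
}

#' Synthetic neuron archetypes
#'
#' Four rate-profile archetypes used by the spike generator, each defined by
#' a baseline rate plus a response profile around an alignment event:
#' \describe{
#'   \item{AUDITORY_ONSET}{silent until `latency_ms` after sound onset, then
#'     an abrupt peak decaying exponentially; first-peak latencies around
#'     20 ms are typical of collicular auditory responses.}
#'   \item{SC_BUILDUP_BURST}{a 60--80 ms linear build-up in activity
#'     followed by a burst of spikes around saccade initiation.}
#'   \item{FIXATION}{sustained elevation from `latency_ms` (visual delay,
#'     > 20 ms) after fixation-target onset for `sustain_ms`.}
#'   \item{REWARD_EXPECTATION}{ramp over `buildup_ms` up to the reward
#'     event, silent after.}
#' }
#'
#' @param archetype one of the four archetype names.
#' @param baseline_hz baseline rate (Hz, >= 0).
#' @param response_hz peak response rate above baseline (Hz, >= 0).
#' @param latency_ms response latency (ms, >= 0).
#' @param buildup_ms build-up/ramp duration (ms).
#' @param sustain_ms sustained-response duration for FIXATION (ms).
#' @param decay_ms exponential decay constant for AUDITORY_ONSET (ms).
#' @param burst_ms burst duration for SC_BUILDUP_BURST (ms).
#' @param alignment label of the event the profile is aligned to.
#' @return object of class `neuron_model`.
#' @export
neuron_model <- function(archetype = c("AUDITORY_ONSET", "SC_BUILDUP_BURST",
                                       "FIXATION", "REWARD_EXPECTATION"),
                         baseline_hz = 5, response_hz = 80,
                         latency_ms = 21, buildup_ms = 70, sustain_ms = 500,
                         decay_ms = 30, burst_ms = 20,
                         alignment = "stimulus") {
  archetype <- match.arg(archetype)
  if (baseline_hz < 0 || response_hz < 0) stop("rates must be >= 0")
  if (latency_ms < 0) stop("latency must be >= 0")
  structure(list(archetype = archetype, baseline_hz = baseline_hz,
                 response_hz = response_hz, latency_ms = latency_ms,
                 buildup_ms = buildup_ms, sustain_ms = sustain_ms,
                 decay_ms = decay_ms, burst_ms = burst_ms,
                 alignment = alignment),
            class = "neuron_model")
}

# response profile (Hz above baseline) at time t_ms relative to the event
neuron_profile <- function(model, t_ms) {
  r <- model$response_hz
  out <- numeric(length(t_ms))
  if (model$archetype == "AUDITORY_ONSET") {
    on <- t_ms >= model$latency_ms
    out[on] <- r * exp(-(t_ms[on] - model$latency_ms) / model$decay_ms)
  } else if (model$archetype == "SC_BUILDUP_BURST") {
    ramp <- t_ms >= -model$buildup_ms & t_ms < 0
    out[ramp] <- 0.3 * r * (t_ms[ramp] + model$buildup_ms) / model$buildup_ms
    burst <- t_ms >= 0 & t_ms < model$burst_ms
    out[burst] <- r
  } else if (model$archetype == "FIXATION") {
    on <- t_ms >= model$latency_ms & t_ms < model$latency_ms + model$sustain_ms
    out[on] <- r
  } else {                               # REWARD_EXPECTATION
    ramp <- t_ms >= -model$buildup_ms & t_ms < 0
    out[ramp] <- r * (t_ms[ramp] + model$buildup_ms) / model$buildup_ms
  }
  out
}

#' Generate an inhomogeneous-Poisson spike train
#'
#' Thinning algorithm: candidate spikes are drawn homogeneously at the
#' envelope rate `baseline + max(gains) * response` and accepted with
#' probability `rate(t) / envelope`, where
#' `rate(t) = baseline + sum_i gain_i * profile(t - event_i)`. Accepted
#' times are rounded to the acquisition timestamp grid (0.1 ms, i.e. the
#' 10 kHz timestamp clock) and deduplicated, so trains are strictly
#' increasing.
#'
#' @param model a [neuron_model()].
#' @param events_us alignment-event times (microseconds).
#' @param duration_us train duration (microseconds).
#' @param gains per-event multiplicative response gain (recycled); used for
#'   e.g. direction tuning of perisaccadic bursts.
#' @param seed optional integer seed for reproducibility.
#' @param grid_ms timestamp resolution in ms (default 0.1).
#' @return numeric vector of spike times in microseconds, strictly
#'   increasing.
#' @export
generate_spikes <- function(model, events_us, duration_us, gains = 1,
                            seed = NULL, grid_ms = 0.1) {
  stopifnot(inherits(model, "neuron_model"))
  if (length(events_us) && (min(events_us) < 0 || max(events_us) > duration_us))
    stop("events must lie within [0, duration]")
  if (!is.null(seed)) set.seed(seed)
  gains <- rep_len(gains, max(length(events_us), 1L))
  rate_fn <- function(t_us) {
    r <- rep(model$baseline_hz, length(t_us))
    for (i in seq_along(events_us))
      r <- r + gains[i] * neuron_profile(model, (t_us - events_us[i]) / 1000)
    r
  }
  envelope <- model$baseline_hz +
    (if (length(events_us)) max(gains) else 0) * model$response_hz
  if (envelope <= 0) return(numeric(0))
  n_cand <- stats::rpois(1, envelope * duration_us / 1e6)
  if (n_cand == 0) return(numeric(0))
  cand <- sort(stats::runif(n_cand, 0, duration_us))
  keep <- stats::runif(n_cand) < rate_fn(cand) / envelope
  ts <- round(cand[keep] / (grid_ms * 1000)) * (grid_ms * 1000)
  unique(ts)
}

#' Simulate the gaze trace for one trial
#'
#' Draws the subject's compliance for each phase from the policy, then
#' renders a 1 kHz gaze trace: reaction delay, main-sequence saccade to the
#' fixation target (if the acquire draw succeeds), jittered hold (if the
#' hold draw succeeds; otherwise a departure saccade at a uniform random
#' time), then a saccade to the test stimulus or elsewhere per the
#' target-choice draw, and a final hold. Failure draws produce traces that
#' violate exactly the corresponding monitoring phase.
#'
#' @param plan a [plan_trial()] result (positions and timing).
#' @param policy a [subject_policy()].
#' @param seed optional integer seed.
#' @param sm a [saccade_model()].
#' @param rate_hz eye-channel sampling rate (default 1000).
#' @param start_pos initial gaze position `c(x, y)` degrees; default a
#'   random point 6--10 degrees from the fixation target.
#' @return a [gaze_stream()] (degrees, trial-local microseconds) with
#'   attributes `draws` (the three compliance draws) and `saccades`
#'   (data.frame of true saccade onsets/offsets/amplitudes/angles, ms).
#' @export
generate_gaze <- function(plan, policy, seed = NULL, sm = saccade_model(),
                          rate_hz = 1000, start_pos = NULL) {
  stopifnot(inherits(policy, "subject_policy"))
  if (!is.null(seed)) set.seed(seed)
  timing <- plan$timing_ms
  t_acq <- timing$t_acquire; t_fix <- timing$t_initial_fix
  t_rwd <- timing$t_reward_fix
  total_ms <- t_acq + t_fix + t_acq + t_rwd + 200
  n <- floor(total_ms * rate_hz / 1000) + 1L
  dt_ms <- 1000 / rate_hz
  t_ms <- (seq_len(n) - 1L) * dt_ms

  fix_pos <- c(0, 0)
  tgt_pos <- as.numeric(plan$target_pos)
  if (is.null(start_pos)) {
    ang <- stats::runif(1, 0, 2 * pi); ecc <- stats::runif(1, 6, 10)
    start_pos <- fix_pos + ecc * c(cos(ang), sin(ang))
  }

  acquired <- stats::runif(1) < policy$p_acquire
  held <- stats::runif(1) < policy$p_hold
  chose <- stats::runif(1) < policy$p_target_choice

  x <- rep(start_pos[1], n); y <- rep(start_pos[2], n)
  saccades <- data.frame(t_onset_ms = numeric(0), t_offset_ms = numeric(0),
                         amplitude = numeric(0), angle = numeric(0))
  add_saccade <- function(t0_ms, from, to) {
    amp <- sqrt(sum((to - from)^2))
    dur <- saccade_duration_ms(sm, amp)
    u <- (t_ms - t0_ms) / dur
    frac <- raised_cosine(u)
    after <- t_ms >= t0_ms
    x[after] <<- from[1] + frac[after] * (to[1] - from[1])
    y[after] <<- from[2] + frac[after] * (to[2] - from[2])
    saccades[nrow(saccades) + 1L, ] <<- c(t0_ms, t0_ms + dur, amp,
                                          atan2(to[2] - from[2],
                                                to[1] - from[1]) * 180 / pi)
    t0_ms + dur
  }
  draw_reaction <- function(deadline_ms, amp) {
    dur <- saccade_duration_ms(sm, amp)
    r <- stats::rnorm(1, policy$reaction_ms[1], policy$reaction_ms[2])
    min(max(r, 60), deadline_ms - dur - 20)
  }

  if (acquired) {
    amp0 <- sqrt(sum((start_pos - fix_pos)^2))
    t_arr <- add_saccade(draw_reaction(t_acq, amp0), start_pos, fix_pos)
    hold_start <- t_arr
    if (held) {
      test_start <- hold_start + t_fix
      if (chose) {
        # saccade to the test stimulus; hold through the reward epoch
        amp1 <- sqrt(sum((tgt_pos - fix_pos)^2))
        if (amp1 < 0.5) {
          # central test stimulus: gaze simply stays put
        } else {
          add_saccade(test_start + draw_reaction(t_acq, amp1), fix_pos,
                      tgt_pos)
        }
      } else {
        # looks away from the (extinguished) fixation region instead of the
        # test stimulus; away vector avoids the target
        ang <- atan2(tgt_pos[2], tgt_pos[1]) + pi
        away <- fix_pos + 12 * c(cos(ang), sin(ang))
        add_saccade(test_start + draw_reaction(t_acq, 12), fix_pos, away)
      }
    } else {
      # break fixation partway through the initial hold
      t_leave <- hold_start + stats::runif(1, 0.1, 0.8) * t_fix
      ang <- stats::runif(1, 0, 2 * pi)
      away <- fix_pos + 10 * c(cos(ang), sin(ang))
      add_saccade(t_leave, fix_pos, away)
    }
  }
  # band-limited fixation jitter everywhere
  if (policy$jitter_deg > 0) {
    x <- x + fixation_noise(n, policy$jitter_deg, rate_hz = rate_hz)
    y <- y + fixation_noise(n, policy$jitter_deg, rate_hz = rate_hz)
  }
  g <- gaze_stream(round(t_ms * 1000), x, y)
  attr(g, "draws") <- list(acquired = acquired, held = held,
                           chose_target = chose)
  attr(g, "saccades") <- saccades
  g
}

#' Simulate a free-viewing scan trace
#'
#' A sequence of fixations separated by main-sequence saccades in random
#' directions, for exercising the saccade detector and perisaccadic
#' analyses outside the task structure.
#'
#' @param n_saccades number of saccades.
#' @param sm a [saccade_model()].
#' @param amp_range amplitude range in degrees (uniform draw).
#' @param fix_ms `c(min, max)` inter-saccadic fixation duration (ms).
#' @param jitter_deg fixation noise SD.
#' @param seed optional integer seed.
#' @param rate_hz sampling rate.
#' @return a [gaze_stream()] with attribute `saccades` (true events:
#'   t_onset_ms, t_offset_ms, amplitude, angle).
#' @export
generate_scan_trace <- function(n_saccades = 50, sm = saccade_model(),
                                amp_range = c(4, 15), fix_ms = c(300, 600),
                                jitter_deg = 0.05, seed = NULL,
                                rate_hz = 1000) {
  if (!is.null(seed)) set.seed(seed)
  segs <- list(); pos <- c(0, 0); t_cur <- 0
  truth <- data.frame(t_onset_ms = numeric(0), t_offset_ms = numeric(0),
                      amplitude = numeric(0), angle = numeric(0))
  pieces <- list()
  for (i in seq_len(n_saccades)) {
    fix_dur <- stats::runif(1, fix_ms[1], fix_ms[2])
    amp <- stats::runif(1, amp_range[1], amp_range[2])
    ang <- stats::runif(1, 0, 2 * pi)
    # keep gaze within +-20 degrees: flip direction if it would exit
    tgt <- pos + amp * c(cos(ang), sin(ang))
    if (any(abs(tgt) > 20)) {
      tgt <- pos - amp * c(cos(ang), sin(ang))
      ang <- ang + pi
    }
    dur <- saccade_duration_ms(sm, amp)
    pieces[[length(pieces) + 1L]] <- list(t0 = t_cur, fix = fix_dur,
                                          from = pos, to = tgt, dur = dur)
    truth[nrow(truth) + 1L, ] <- c(t_cur + fix_dur, t_cur + fix_dur + dur,
                                   amp, (atan2(tgt[2] - pos[2],
                                               tgt[1] - pos[1]) * 180 / pi))
    t_cur <- t_cur + fix_dur + dur
    pos <- tgt
  }
  total_ms <- t_cur + 400
  dt_ms <- 1000 / rate_hz
  t_ms <- seq(0, total_ms, by = dt_ms)
  x <- numeric(length(t_ms)); y <- numeric(length(t_ms))
  for (p in pieces) {
    after <- t_ms >= p$t0
    x[after] <- p$from[1]; y[after] <- p$from[2]
    s0 <- p$t0 + p$fix
    u <- (t_ms - s0) / p$dur
    frac <- raised_cosine(u)
    moving <- t_ms >= s0
    x[moving] <- p$from[1] + frac[moving] * (p$to[1] - p$from[1])
    y[moving] <- p$from[2] + frac[moving] * (p$to[2] - p$from[2])
  }
  x <- x + fixation_noise(length(t_ms), jitter_deg, rate_hz = rate_hz)
  y <- y + fixation_noise(length(t_ms), jitter_deg, rate_hz = rate_hz)
  g <- gaze_stream(round(t_ms * 1000), x, y)
  attr(g, "saccades") <- truth
  g
}

#' Multiplex a simulated session into a multichannel recording
#'
#' Assembles the session record with the acquisition channel layout: eye
#' position at 1 kHz, one raw neural-signal channel at 25 or 50 kHz, spike
#' timestamps on the 0.1 ms (10 kHz) grid, and the event log. The raw
#' channel is synthesized from the first unit's spike train -- a biphasic
#' template added onto Gaussian noise at the requested SNR -- so that
#' threshold re-extraction of spike times is testable against the
#' generator's ground truth.
#'
#' @param gaze a [gaze_stream()] in degrees covering the session.
#' @param spike_trains named list of spike-time vectors (microseconds), one
#'   per unit.
#' @param events data.frame with `t_us` and `label` columns (the TTL event
#'   log).
#' @param duration_us session duration.
#' @param neural_rate_hz raw-channel rate, 25000 or 50000.
#' @param snr template peak amplitude over noise SD.
#' @param seed optional integer seed (noise synthesis).
#' @return object of class `rig_recording`.
#' @export
record_session <- function(gaze, spike_trains, events, duration_us,
                           neural_rate_hz = 25000, snr = 10, seed = NULL) {
  if (!neural_rate_hz %in% c(25000, 50000))
    stop("neural_rate_hz must be 25000 or 50000")
  if (!is.null(seed)) set.seed(seed)
  for (st in spike_trains)
    if (length(st) > 1 && any(diff(st) <= 0))
      stop("spike timestamps must be strictly increasing per unit")
  n_wave <- floor(duration_us * neural_rate_hz / 1e6)
  wave <- stats::rnorm(n_wave)
  # biphasic template, ~1.2 ms, peak amplitude snr (noise SD is 1)
  tmpl_t <- seq(0, 1.2, by = 1000 / neural_rate_hz)
  tmpl <- snr * (exp(-((tmpl_t - 0.25) / 0.1)^2) -
                 0.5 * exp(-((tmpl_t - 0.55) / 0.18)^2))
  if (length(spike_trains)) {
    idx0 <- floor(spike_trains[[1]] * neural_rate_hz / 1e6) + 1L
    for (i0 in idx0) {
      ii <- i0:min(i0 + length(tmpl) - 1L, n_wave)
      if (i0 <= n_wave) wave[ii] <- wave[ii] + tmpl[seq_along(ii)]
    }
  }
  structure(list(eye = gaze, eye_rate_hz = 1000,
                 neural = wave, neural_rate_hz = neural_rate_hz,
                 spikes = spike_trains, spike_grid_ms = 0.1,
                 events = events, duration_us = duration_us, snr = snr),
            class = "rig_recording")
}

#' @export
print.rig_recording <- function(x, ...) {
  cat(sprintf(paste0("<rig_recording> %.2f s: eye %d samples @%d Hz, ",
                     "neural %d samples @%d Hz, %d unit(s), %d events\n"),
              x$duration_us / 1e6, nrow(x$eye), x$eye_rate_hz,
              length(x$neural), x$neural_rate_hz, length(x$spikes),
              nrow(x$events)))
  invisible(x)
}

#' Re-extract spike times from the raw channel by threshold
#'
#' The on-the-fly timestamping done at acquisition: an adjustable threshold
#' on the neural channel, with a 1 ms dead time, times snapped to the
#' 0.1 ms grid.
#'
#' @param rec a [record_session()] recording.
#' @param threshold detection threshold (defaults to half the template
#'   peak).
#' @return spike times in microseconds.
#' @export
extract_spikes_threshold <- function(rec, threshold = rec$snr / 2) {
  stopifnot(inherits(rec, "rig_recording"))
  w <- rec$neural
  above <- which(w[-1] >= threshold & w[-length(w)] < threshold) + 1L
  if (!length(above)) return(numeric(0))
  dead <- rec$neural_rate_hz / 1000        # 1 ms in samples
  keep <- above[c(TRUE, diff(above) > dead)]
  round((keep - 1L) / rec$neural_rate_hz * 1e6 / 100) * 100
}

#' Save a recording as a plain-text bundle
#'
#' Writes a directory of CSV channel files plus a JSON metadata/manifest
#' file: `eye.csv`, `neural.csv`, `spikes_<unit>.csv`, `events.csv`,
#' `meta.json`.
#'
#' @param rec a `rig_recording`.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
save_recording <- function(rec, dir) {
  stopifnot(inherits(rec, "rig_recording"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(rec$eye), file.path(dir, "eye.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(v = rec$neural), file.path(dir, "neural.csv"),
                   row.names = FALSE)
  for (u in names(rec$spikes))
    utils::write.csv(data.frame(t_us = rec$spikes[[u]]),
                     file.path(dir, paste0("spikes_", u, ".csv")),
                     row.names = FALSE)
  utils::write.csv(rec$events, file.path(dir, "events.csv"),
                   row.names = FALSE)
  meta <- list(eye_rate_hz = rec$eye_rate_hz,
               neural_rate_hz = rec$neural_rate_hz,
               spike_grid_ms = rec$spike_grid_ms,
               duration_us = rec$duration_us, snr = rec$snr,
               units = names(rec$spikes))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Load a recording saved by [save_recording()]
#'
#' @param dir bundle directory.
#' @return a `rig_recording`.
#' @export
load_recording <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "meta.json"))
  eye <- utils::read.csv(file.path(dir, "eye.csv"))
  spikes <- list()
  for (u in meta$units)
    spikes[[u]] <- utils::read.csv(
      file.path(dir, paste0("spikes_", u, ".csv")))$t_us
  structure(list(eye = gaze_stream(eye$t_us, eye$x, eye$y),
                 eye_rate_hz = as.numeric(meta$eye_rate_hz),
                 neural = utils::read.csv(file.path(dir, "neural.csv"))$v,
                 neural_rate_hz = as.numeric(meta$neural_rate_hz),
                 spikes = spikes,
                 spike_grid_ms = as.numeric(meta$spike_grid_ms),
                 events = utils::read.csv(file.path(dir, "events.csv")),
                 duration_us = as.numeric(meta$duration_us),
                 snr = as.numeric(meta$snr)),
            class = "rig_recording")
}

#' Deterministic hash of an R object
#'
#' MD5 of the ASCII serialization; used to assert that seeded runs
#' reproduce bus logs and recordings exactly.
#'
#' @param x any serializable object.
#' @return character MD5 hash.
#' @export
rig_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(serialize(x, NULL, ascii = TRUE), f)
  unname(tools::md5sum(f))
}
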