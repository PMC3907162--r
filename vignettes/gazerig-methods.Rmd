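---
title: "gazerig: simulation and analysis of a gaze-contingent experiment-control rig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{gazerig: simulation and analysis of a gaze-contingent experiment-control rig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazerig)
```

## The system being modeled

Operant gaze-contingent experiments in behaving primates are classically run
by three cooperating programs on separate machines: a *presenter* that draws
stimuli and plays sounds, a *controller* that decides what happens next, and
a real-time *sequencer* on the acquisition device that watches eye position
sample by sample and gates reward. The three stay synchronized through two
message fabrics: newline-terminated ASCII command words with echoed replies
on a serial line, and 1 ms TTL pulses on a parallel line that double as
event timestamps in the recorded data.

`gazerig` re-implements this triad as a deterministic, hardware-free engine.
Every component that in the laboratory touches hardware — the eye coil, the
display, the reward solenoid, the neuron under the electrode — is replaced
by an explicit simulation with a seed, so the complete closed loop becomes a
testable function from configuration to artifacts (bus log, trial table,
multichannel recording).

## The behavioral state machine

A trial of the association task has three monitored phases, each judged
against a rectangular *forgiveness window* expressed in DAC counts:

1. **Acquire** — gaze must enter the fixation window within the "Time to
   get on Target" epoch. Success is stamped at the first in-window sample;
   failure at the deadline.
2. **Hold** — gaze must stay in the window for the "Initial Fixation Time".
   The first sample outside before the duration elapses fails the trial at
   that sample.
3. **Test** — the image + sound stimulus appears, and fixation is judged
   against a window equal to the image size for the "Fixation Time for
   Reward". Only full compliance triggers the reward pulse.

Numerical conventions, chosen once and kept:

* **Window edges are inclusive.** Forgiveness semantics: a sample exactly on
  an edge counts as inside, and a zero-width window still contains its
  center rather than nothing.
* **Missing samples are outside.** An NA/NaN gaze sample (signal dropout)
  can never contribute to acquisition or survive a hold: no reward on a
  dead signal.
* **Deadline boundaries are inclusive for acquisition** (a sample exactly at
  the deadline succeeds) and **exclusive for holds** (the hold has already
  succeeded when the duration elapses).
* The sequencer evaluates **every 1 kHz sample**; there is no decimation
  and no grace period for brief excursions — leaving the window for one
  sample during a hold fails the trial.
* The test phase runs its own acquisition with the same "Time to get on
  Target" deadline before its hold. The original description gives the test
  phase only a fixation duration; splitting it into acquire + hold mirrors
  phases 1–2 and is configurable through the monitor timings.

The implementation (`run_trial`) is vectorized; the test suite replays the
same traces through an independently written one-sample-at-a-time state
machine and requires bit-identical outcomes and event times on hundreds of
random traces, including traces with dropouts.

## Unit systems and conversions

Three conversion layers connect user-facing units to device units:

* **Degrees to pixels** uses the exact tangent projection
  `offset_px = distance_cm * tan(angle) * res / size_cm`. No small-angle
  approximation is used, so eccentric stimuli land where they should.
  Degrees are signed, right/up positive, origin at straight-ahead gaze.
* **Degrees to DAC counts** is the affine map
  `counts = round(gain * deg + offset)`. The hardware's bit depth and
  volts-per-degree scaling are configuration, not constants of nature;
  defaults are 100 counts/degree around the mid-range (2048) of a 12-bit
  converter, which keeps worked examples exact. Out-of-range conversions
  raise an error rather than clamping — a silently clamped window edge
  would corrupt containment tests.
* **Milliseconds to sequencer steps** is `round(ms * steps_per_ms)` with a
  default of 1000 steps/ms matching a 1 µs sequencer tick; real sequencers
  may step slower, hence the parameter.

## Protocol and timing model

The bus is an in-memory deterministic queue with one session clock; real
serial transport is out of scope. Command words are free-length printable
ASCII (a defensive 32-character cap), and reply content — unspecified in
the original system beyond its existence — is the command word prefixed
`ack:`. An alias table maps wire words to registry object names (the
7-character `grendot` calls the object `greendot`), so no word-length
limit needs to be guessed.

Display changes are **frame-quantized**: an onset requested at time *t*
takes effect at the next multiple of `1e6 / refresh_hz` microseconds. At
60 Hz the worst-case onset error is therefore one frame, 16 ms truncated —
the engine reports this bound via `worst_case_onset_error_ms()`. Sound is
modeled as unquantized (zero audio latency by default, configurable), so
`audit_av_sync()` bounds the image-minus-sound onset offset by one frame
period. The TTL timestamp is stamped at the frame boundary (stimulus
onset), not at command receipt; the alternative convention would shift
every event time earlier by the quantization delay.

The controller's do-case is a total function on exactly six situations —
three fixation failures, three successes — and issues one command per
situation. The lockstep contract (one command, one reply, one TTL per
stimulus change, TTL at or after the command) is checked by replaying the
bus log, not by trusting the code that produced it.

## The virtual subject

The simulated subject draws three Bernoulli compliance decisions per trial
(`p_acquire`, `p_hold`, `p_target_choice`), so the expected rewarded
fraction is their product; the draws then deterministically shape a 1 kHz
gaze trace:

* saccades follow an affine main sequence, `duration = 20 ms + 2 ms/deg ×
  amplitude`, standard primate values, with a raised-cosine velocity
  profile (symmetric, unimodal, zero at the endpoints);
* reaction latencies are Gaussian (default 180 ± 30 ms), truncated so that
  a compliant trial cannot miss its deadline by construction — the draws,
  not the kinematics, decide the outcome;
* fixation jitter is band-limited noise (white noise convolved with a
  25 ms Gaussian), not white noise: white positional noise at 1 kHz would
  carry ~70 deg/s sample-to-sample velocities at 0.1 deg SD and bury every
  saccade for a velocity-threshold detector. Band-limiting emulates slow
  fixational drift.

What the generator does **not** emulate: torsion and vergence, corrective
and micro-saccades, blinks beyond isolated NA dropouts, slow drifts in
calibration, and any dependence of behavior on the stimulus content.
Passing tests therefore certify the engine's bookkeeping and estimators on
idealized oculomotor behavior, not detector performance on real eye
signals.

## Synthetic neurons and the recording

Spike trains are inhomogeneous Poisson by thinning: candidates are drawn at
the envelope rate and accepted with probability `rate(t) / envelope`, where
the rate is baseline plus an archetype profile around each alignment event.
Four archetypes cover the analysis surface: an auditory onset response
(silent until its latency, then an exponentially decaying peak; ~21 ms
latency by default), a build-up/burst unit (linear ramp over 70 ms into a
perisaccadic burst, optionally direction-gained for tuning studies), a
sustained fixation response with a >20 ms visual delay, and a
reward-expectation ramp. Accepted times are rounded to the 0.1 ms
acquisition grid — the stated resolution of the 10 kHz timestamp channel,
which this package interprets as the spike-timestamp stream — and
deduplicated so trains are strictly increasing.

`record_session()` assembles the stated channel layout: eye position at
1 kHz, one raw neural channel at 25 or 50 kHz (a biphasic ~1.2 ms template
added to unit-variance Gaussian noise at a configurable SNR, so that
threshold re-extraction of spike times is testable against ground truth),
spike timestamps, and the event log. Recordings persist as a plain-text
bundle — CSV channels plus a JSON manifest — with a lossless load
round-trip.

## Analysis choices

* **Saccade detection**: radial velocity from sample differences, 5 ms
  boxcar smoothing, 30 deg/s onset/offset threshold crossings, 0.5 deg
  minimum amplitude — standard oculomotor practice. Amplitude and angle
  come from the onset/offset positions.
* **PSTH**: fixed 10 ms bins (right-open), counts pooled over trials,
  rate = counts / (n_trials × bin width). Count conservation and rate
  normalization are exact identities, enforced by tests.
* **Spike density**: per-trial delta trains convolved with a unit-area
  Gaussian (default SD 10 ms, matching the PSTH bin scale), averaged and
  scaled to spikes/s; the windowed integral equals the mean per-trial
  count whenever kernels clear the window edges.
* **First-peak latency**: the first post-event bin whose rate exceeds the
  baseline mean + 3 baseline SDs, refined below bin width by a local
  parabola through the crossing bin and its neighbors evaluated at the
  half-rise level, bounded to one bin. The refinement targets the rising
  edge: interpolating at the criterion level itself lands near the
  previous bin center (the criterion sits barely above baseline), and the
  parabola's vertex targets the peak; both are biased estimators of onset.
  A PSTH with no supra-criterion bin yields a distinct "no response"
  (`NA`), never 0. When the baseline SD is zero (empty baseline), a
  Poisson floor `sqrt(max(mean, 1))` stands in so the criterion is never
  degenerate.
* **Preferred saccade vector**: burst-window rates binned on an
  amplitude × direction grid; the preferred vector is the rate-weighted
  circular mean direction and rate-weighted mean amplitude of the
  supra-median bins. Reliability is judged by the rate-weighted resultant
  over the *full* map (threshold 0.1): supra-median selection alone
  inflates the resultant of a flat map, flagging untuned units as tuned.
  The burst window (default 0–20 ms from saccade onset) is a parameter
  because the build-up/burst boundary has no canonical numerical
  definition. At least 20 saccades spanning at least 90 degrees of
  directions are required.

## Problem sizes and reproducibility

The test suite and the acceptance script run the engine at the sizes the
design calls for: 500 random traces for oracle equivalence, 200-trial
sessions for protocol checks, 400 trials for behavioral statistics, 40
alignment repeats for PSTH calibration, 10 synthetic units for latency
recovery, and 150-saccade scan traces for tuning recovery. All randomness
descends from a single session seed; identical seeds reproduce the bus
log and the recording byte-for-byte (verified by hashing), and scenario
switches roll the trial data file over without losing or duplicating any
flushed trial.

## Known limitations

* The engine is a simulator: no driver layer exists for real acquisition
  or presentation hardware, and the serial transport is an interface stub.
* No spike sorting or template matching — the recording's threshold
  re-extraction is a self-consistency check, not a sorter.
* No microstimulation, torsional eye position, nonlinear coil
  calibrations, video stimuli, or acoustic waveform synthesis.
* Hold monitoring has no re-entry grace period; whether brief excursions
  should be forgiven is a policy question the original description leaves
  open, and the strict reading is implemented.
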