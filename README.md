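# gazerig

Closed-loop control of gaze-contingent behavioral experiments — sequencer,
controller and stimulus presenter — re-implemented as a hardware-free,
seedable simulation engine in R, together with the event-aligned analyses
(rasters, PSTHs, spike-density functions, saccade metrics) used on the data
such rigs record.

## Who this is for

Behavioral neurophysiology rigs traditionally run three cooperating scripts:
a real-time *sequencer* on the acquisition device that monitors eye position
against a rectangular "forgiveness" window and gates reward, a *controller*
that maps each (trial phase, fixation state) situation to the next stimulus
command through a six-case dispatch table, and a *presenter* that answers
newline-terminated command tokens (e.g. `grendot\n`, `SndPICn\n`) by drawing
at the next display frame, replying on the serial path and emitting a 1 ms
TTL timestamp pulse. `gazerig` is for experimenters and tool builders who
want to design, test and reason about such protocols — timing criteria,
window sizes, synchronization contracts, expected behavioral statistics —
without a rig: every hardware-facing piece is replaced by a deterministic
simulation (a virtual subject with saccadic kinematics, synthetic Poisson
neurons, a multiplexed multichannel recording).

## The core machinery

* **Trial state machine** — three monitored phases per trial: acquire the
  fixation target within *t*₍acquire₎, hold it for *t*₍fix₎, then fixate the
  test stimulus (window = image size) for *t*₍reward₎; success emits a
  reward pulse, any failure resets to the black screen. Window edges are
  inclusive; missing samples count as outside.
* **Conversions** — exact tangent mapping deg ↔ px; affine deg ↔ DAC counts
  (`counts = round(gain·deg + offset)`, errors instead of clamping);
  `steps = round(ms × steps_per_ms)` for the 1 µs sequencer clock.
* **Lockstep protocol** — one command token, one reply, one TTL per stimulus
  change, checkable post hoc by replaying the bus log.
* **Frame quantization** — onsets snap to the next multiple of
  `1e6/refresh_hz` µs; at 60 Hz the worst-case onset error is 16 ms.
* **Analyses** — velocity-threshold saccade detection; PSTHs
  (rate = counts/(n·Δ), 10 ms bins); Gaussian spike-density functions;
  first-peak response latency (baseline + 3 SD criterion with sub-bin
  refinement); preferred saccade vector from perisaccadic rate maps.

## Worked example

```r
library(gazerig)

cfg <- session_config(
  subject = "subj01", n_trials = 40,
  task    = task_spec("ASSOCIATION"),
  policy  = subject_policy(p_acquire = 0.8, p_hold = 0.9, p_target_choice = 1),
  window_deg = 2, reward_ms = 50, record = TRUE)

run <- run_session(cfg, seed = 42)
run
#> <session_run> 40 trials (FAIL_ACQUIRE=11, FAIL_HOLD=3, REWARDED=26), 344 bus records, 1 data file(s)

s <- summary(run)
s$rewarded_fraction        # expectation 0.8 * 0.9 * 1 = 0.72
#> [1] 0.65
s$lockstep$ok              # one command / one reply / one TTL per change
#> [1] TRUE

run$recording
#> <rig_recording> 112.92 s: eye 112917 samples @1000 Hz, neural 2822916 samples @25000 Hz, 1 unit(s), 92 events

aligns <- run$events$t_us[run$events$label == "test_on"]
ps <- build_psth(run$recording$spikes$unit1, aligns, bin_ms = 10)
ps
#> <psth> 26 trials, 40 bins of 10 ms, 122 aligned spikes
round(first_peak_latency(ps), 1)   # simulated unit has a 21 ms onset latency
#> [1] 18.5

nrow(detect_saccades(run$recording$eye))
#> [1] 71
```

The 40-trial rewarded fraction (0.65) scatters binomially around the policy
product 0.72; the recovered onset latency (18.5 ms) sits within the sub-bin
resolution of the 10 ms PSTH around the unit's true 21 ms latency; the
saccade count reflects the acquisition and test saccades of the 26 completed
trials plus departures on failed ones.

A ready-made config ships with the package
(`system.file("extdata", "example_session.yaml", package = "gazerig")`), and
`exec/gazerig` wraps the same functionality for the shell:

```sh
gazerig fixtures --out fixtures/          # placeholder PNG/WAV assets + config
gazerig run --config fixtures/example_config.yaml --seed 42 --out out/
gazerig analyze --recording out/recording --out analysis/
```

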