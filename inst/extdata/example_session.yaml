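# Example session configuration: an association-training scenario run
# against the simulated subject. Fields mirror the rig's set-up dialogs.
subject: subj01
n_trials: 20
task: ASSOCIATION
timing_ms:
  t_acquire: 500        # "Time to get on Target"
  t_initial_fix: 300    # "Initial Fixation Time"
  t_reward_fix: 500     # "Fixation Time for Reward"
window_deg: 2           # forgiveness-window half-width, degrees
image_size_deg: 4       # test image size; also the test-phase window
reward_ms: 50           # reward pulse duration
refresh_ms: 2000        # inter-trial black-screen refresh
policy:
  p_acquire: 0.8
  p_hold: 0.9
  p_target_choice: 1.0
  reaction_mean_ms: 180
  reaction_sd_ms: 30
  jitter_deg: 0.1
neurons:
  unit1:
    archetype: AUDITORY_ONSET
    baseline_hz: 5
    response_hz: 80
    latency_ms: 21
    alignment: test_on
record: true
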