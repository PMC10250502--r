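# Example experiment configuration: the standard validation design.
conditions:
  - {carrier_hz: 400,  mod_hz: 5}
  - {carrier_hz: 1000, mod_hz: 5}
  - {carrier_hz: 400,  mod_hz: 10}
  - {carrier_hz: 1000, mod_hz: 10}
staircase:
  start_value: 6          # dB modulation depth
  step_sizes: [1, 0.5]    # dB
  change_points: [1]      # step drops to 0.5 dB after the first reversal
  n_down: 3
  schedule_mode: reversal
observer:
  midpoint_db: -9
  std_db: 2
session:
  n_participants: 10
  reps_per_position: 12   # 36 trials per condition play
  repetitions: 3          # each condition played three times, one track
  stim_duration_s: 0.5
  onsets_s: [0.5, 1.5, 2.5]
  trial_period_s: 4
  rate: 44100
  base_seed: 1
  n_reversals: 6
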