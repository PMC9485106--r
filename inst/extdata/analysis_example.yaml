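# Example analysis configuration (defaults shown where practical).
bands: [theta, slow_gamma, fast_gamma]
coupling_band: theta
n_segments: 16
window_s: 15
max_lag_ms: 500
peak_mode: signed
amplitude_mode: filtered
filter:
  stopband_atten_db: 80
  passband_ripple_db: 1
  transition_width_hz: 0.5
artifact:
  zscore_threshold: 6
  min_duration_ms: 50
blocks:
  - {block: Hab,       session: Hab,        trial_index: [1, 2, 3, 4, 5]}
  - {block: ACQ,       session: ACQ,        trial_index: [3, 4, 5]}
  - {block: EarlyEXT,  session: EXT1,       trial_index: [1, 2, 3]}
  - {block: LateEXT,   session: EXT2,       trial_index: [10, 11, 12]}
  - {block: EXTrecall, session: EXT_recall, trial_index: [1, 2]}
  - {block: Renewal,   session: Renewal,    trial_index: [1, 2]}
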