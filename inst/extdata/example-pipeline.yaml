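# Example end-to-end configuration for podrift::run_pipeline().
# Angles are degrees on the 180-degree-periodic orientation circle, [-90, 90).
imaging:
  n_neurons: 120
  session_days: [0, 21]
  frame_rate: 5
  response_amplitude: 0.6
  noise_sd: 0.2
  fraction_untuned: 0.15
  drift_model:
    type: biased_walk
    step_sd: 1.5
    target_orientation: -30
    bias_strength: 0.01
  seed: 2024
analysis:
  n_boot: 500
  alpha: 0.05
drift:
  experienced: -30
  n_shuffle: 500
model:
  n: 100
  scale: 1440          # 30 stimuli per simulated day
  seed: 2024
protocol:
  type: deprivation
  n_days: 14
  measure_every: 7
  ensemble_size: 1
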