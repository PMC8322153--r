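# Demo synthetic session: two neuron pairs sharing a per-trial latent
# excitability state, two stimulation frequencies, depressive adaptation.
n_trials: 200
frequencies: [1, 4]
seed: 2024
session: demo-01
whisker: C2
reliability: 0.75
adaptation:
  latency_amp: 2
  count_rate: 0.3
  trials_to_saturation: 20
  latency_freq_threshold: 1
  count_freq_threshold: 5
neurons:
  - {neuron_id: 1, ei_type: E, layer: L4}
  - {neuron_id: 2, ei_type: I, layer: L5A}
  - {neuron_id: 3, ei_type: E, layer: L5B/6}
  - {neuron_id: 4, ei_type: E, layer: L4}
cluster_specs:
  - neurons: [1, 2]
    clusters:
      - {prob: 0.55, mean: [11, 19], lambda: [1.5, 0.8], sigma: [1.0, 1.0]}
      - {prob: 0.35, mean: [24, 12], lambda: [0.8, 1.3], sigma: [1.2, 1.2]}
  - neurons: [3, 4]
    clusters:
      - {prob: 0.8, mean: [15, 22], lambda: [1.2, 1.2], sigma: [0.9, 0.9]}
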