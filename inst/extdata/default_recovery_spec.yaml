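# Default planted ground truth for the inversion validation: bimodal
# gamma-mixture SIP distribution (modes near 4 s and 9 s), 500 events per
# seed, signal-to-noise ratio 10.
directing:
  name: gamma-mixture
  means: [4.0, 9.0]
  shape: 20
  probs: [0.5, 0.5]
n_events: 500
amplitude: 10
noise_sd: 1
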