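oels:
  Cr: 0.5
  Fe: 10
  Mn: 0.1
  Ni: 1
  Pb: 0.05
band_edges: [0.005, 0.05, 0.25, 0.5]
action_level_fraction: 0.5
control_labels:
  - no action
  - general hazardous communication
  - chemical-specific hazardous communication
  - exposure surveillance/medical surveillance/work practices
  - respirators/work practice controls
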