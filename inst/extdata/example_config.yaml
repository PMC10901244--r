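# Example run configuration: situation 2 at 2 Hz on the default head model
protocol:
  situation: 2
  sample_rate_hz: 2
mode: nonlinear
noise_sd: 0
seed: 1
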