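data:
  hr_B: 0.75
  ci_B: [0.48, 1.18]
  hr_C: 0.61
  ci_C: [0.49, 0.75]
  labels: [non-metastatic, metastatic]
prior:
  family: normal
  muC: {mean: 0, sd: 10}
  delta: {mean: 0, sd: 10}
mcmc:
  n_chains: 2
  iterations: 6000
  burn_in: 1000
  thin: 1
  seed: 1
pi: [0.52]
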