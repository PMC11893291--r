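data:
  hr_B: 0.54
  ci_B: [0.34, 0.84]
  hr_C: 0.71
  ci_C: [0.55, 0.91]
  labels: [bone metastases, no bone metastases]
prior:
  family: normal
  muC: {mean: 0, sd: 10}
  delta: {mean: -0.122, sd: 0.334}
mcmc:
  n_chains: 2
  iterations: 12000
  burn_in: 2000
  thin: 1
  seed: 1
design:
  n_total: 900
  pi: [0.3333333333333333, 0.5, 0.6666666666666666]
  event_rates:
    B: {active: 0.6, control: 0.8}
    C: {active: 0.5, control: 0.7}
  crit: -1.96
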