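{
  "alphas": [0.1, 0.05, 0.01, 0.005, 0.001],
  "betas": [0.5, 0.55, 0.6, 0.65, 0.7, 0.75, 0.8, 0.85, 0.9, 0.95],
  "exponent": 0.37,
  "n_sim": 2000,
  "method": "asymptotic",
  "n_perm": 1000,
  "kernel": "gaussian",
  "estimator": "local-linear",
  "bandwidth_rule": "leave-one-out CV",
  "seed": 20260928,
  "n_scenarios": 675,
  "bandwidths": [0.544146579232145, 0.544146579232145, 0.544146579232145, 0.544146579232145, 0.756089220121621]
}
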