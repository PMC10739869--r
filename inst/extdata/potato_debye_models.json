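{
  "n2": {
    "sigma_s": 2.508e-2,
    "eps_inf": 3.463e2,
    "poles": [
      {"delta_eps": 1.104e6, "tau": 1.932e-3},
      {"delta_eps": 3.308e4, "tau": 4.181e-7}
    ]
  },
  "n4": {
    "sigma_s": 2.159e-2,
    "eps_inf": 1.747e2,
    "poles": [
      {"delta_eps": 2.251e6, "tau": 3.783e-3},
      {"delta_eps": 2.918e4, "tau": 2.309e-5},
      {"delta_eps": 1.836e4, "tau": 1.005e-6},
      {"delta_eps": 1.053e4, "tau": 1.658e-7}
    ]
  },
  "n6": {
    "sigma_s": 2.087e-2,
    "eps_inf": 1.621e2,
    "poles": [
      {"delta_eps": 3.198e6, "tau": 5.067e-3},
      {"delta_eps": 3.321e4, "tau": 3.563e-4},
      {"delta_eps": 1.968e4, "tau": 2.495e-5},
      {"delta_eps": 1.048e4, "tau": 3.775e-6},
      {"delta_eps": 1.548e4, "tau": 6.013e-7},
      {"delta_eps": 7.628e3, "tau": 1.403e-7}
    ]
  }
}
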