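{
  "seed": 17,
  "simulate": {
    "n_founders": 40,
    "cycle_time": {"family": "lognormal", "mean": 16, "cv": 0.15},
    "recombination_time": 0,
    "horizon": 75,
    "exit_prob": 0.2,
    "recombined_fraction": 0.9,
    "partition": "deterministic"
  },
  "noise": {"multiplicative_cv": 0, "background_mean": 0, "background_sd": 0},
  "normalize": {"n_ref": 10},
  "infer": {"C": 1}
}
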