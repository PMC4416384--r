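{
  "n_subjects": 34,
  "seed": 20080901,
  "out": "trial.csv",
  "data": "trial.csv",
  "covariate": "power",
  "error": "proportional",
  "n_rep": 1000
}
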