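{
  "disease_spec": "default",
  "scenario": 7,
  "methods": ["DIRECT", "SONG", "PUHAN", "GLMFE", "GLMRE"],
  "n_pop": 50000,
  "reps": 1000,
  "psa_iters": 1100,
  "n_per_arm": 500,
  "wtp_grid": {"from": 0, "to": 100000, "by": 5000},
  "seed": 1,
  "out_dir": "nmahesim-output"
}
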