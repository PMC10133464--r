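{
  "data": {
    "preset": "cross_modality",
    "size": 32,
    "n_source": 60,
    "n_target": 40,
    "n_val": 10,
    "n_test": 20
  },
  "train": {
    "max_iter": 600,
    "batch_size": 2,
    "base_lr": 0.02,
    "xi_threshold": 0.8,
    "xi_weight": 1.0,
    "lambda_adv_initial": 0.1,
    "lambda_adv_final": 1.0,
    "eval_every": 100,
    "seed": 1
  }
}
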