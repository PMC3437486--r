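{
  "de": {"n_fold": 2860, "n_r": 116, "n_overlap": 2},
  "cos": {"n_families": 638, "n_fail_stage1": 0, "n_fail_stage2": 82,
          "n_paralog": 90, "n_prior_cos": 79}
}
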