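# Example pipeline configuration for read_pipeline_config().
# Keys mirror the arguments of pipeline_config(); anything omitted keeps
# its default.
seed: 1
outdir: "dhd_run"
synthetic:
  n_patients: 25000
  target_prevalence: 0.089
split: "random-by-patient"
test_fraction: 0.10
rebalance: "class_weight"
learners: ["lr", "gbt"]
calibration: "stratified:instability"
fairness_attributes: ["sex", "residency", "instability"]
explain:
  model: "gbt"
  subsample_fraction: 0.10
  background_n: 100
  n_samples: 10
  top_k: 10
  risk_threshold: 0.5
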