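# Demonstration pipeline configuration: simulate a two-stage, three-fraction
# polysome-profiling experiment with planted translational states, classify,
# and summarize. Run with run_pipeline("demo_run.yaml").
out_dir: polystate_demo
seed: 7
alpha: 0.05
detection_threshold: 1.0
simulate:
  n_isoforms: 400
  n_replicates: 3
  baseline_mean: 50
  dispersion: 0.1
  effect_fold: 4
  detection_fraction: 0.1
  state_proportions:
    steady: 0.8
    repressed: 0.1
    derepressed: 0.1
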