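# Example experiment configuration for the plasticsnn CLI.
# Unknown keys are rejected; anything omitted falls back to the defaults in
# default_experiment_config().
task: cue_low        # cue_low | cue_high | toy_locomotion
rule: ndp_oja        # none | dp_linear | dp_oja | dp_bcm | ndp_oja | ndp_bcm
scale: scaled        # scaled | full
seed: 1
out_dir: runs/example
train:
  max_iterations: 300
  halt_loss: -0.97
rule_opts:
  clip: 2
noise:
  kind: action
  sigmas: [0, 0.1, 0.25]
  n_eval: 20
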