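# Full-scale selection study on the nine-state AML benchmark:
# 225 replicates, lambda tuned by GCV on the 20-point log grid for the
# global lasso (1, 1) and for every (alpha, gamma) combination of the
# mixing grids (the FSGL method reports the per-replicate GCV winner).
# Driven by cmd_study(); an overnight run on one core.
nsim: 225
base_seed: 1
grid:
  n_lambda: 20
  lambda_min: 0.01
  lambda_max: 500
  alphas: [0.0, 0.25, 0.5, 0.75, 1.0]
  gammas: [0.0, 0.25, 0.5, 0.75, 1.0]
fsgl_alpha: [0.0, 0.25, 0.5, 0.75, 1.0]
fsgl_gamma: [0.0, 0.25, 0.5, 0.75, 1.0]
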