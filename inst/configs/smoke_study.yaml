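# Small smoke-test study: 5 replicates at reduced sample size, lasso and
# FSGL at the benchmark's reported optimal mixing combination.
nsim: 5
base_seed: 1
dgp:
  N: 200
grid:
  lambdas: [1, 5, 10, 30, 100]
fsgl_alpha: 1.0
fsgl_gamma: 0.25
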