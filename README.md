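# fusedmsm

Joint variable selection for **multi-state survival models** via the
**fused sparse-group lasso (FSGL)** penalty, fitted by an adapted **ADMM**
algorithm.

Multi-state models describe a patient's disease pathway — e.g. active
disease, remission, relapse, death — as a process over states, with a Cox
proportional hazards model per transition:

    h_q(t | x) = h_{0,q}(t) * exp(beta_q' x),   q = 1..Q.

With P covariates measured once per subject this gives P·Q coefficients.
For high-dimensional biomarker panels, a parsimonious model needs three
kinds of structure at once: most effects are zero, clinically *similar*
transitions (e.g. remission→relapse after first and second remission)
carry effects of similar size, and effects cluster by transition. The FSGL
penalty encodes all three on the stacked coefficient vector:

    p(beta) = lambda * [ alpha*gamma * sum_{p,q} |beta_{p,q}|
            + (1-gamma)  * sum_{(q,q') in S} sum_p |beta_{p,q} - beta_{p,q'}|
            + (1-alpha)*gamma * sum_q w_q ||beta_q||_2 ]

The non-separable objective is minimized by ADMM: a Newton-type update of
the smooth stacked partial likelihood, a closed-form soft-thresholding
update of the penalty's auxiliary variable `theta = K beta` (the penalty
structure matrix `K` holds unit, contrast and group-selector rows), a dual
ascent step, and adaptive step-size balancing. Exact zeros — and hence the
selection — live in `theta`. The overall level `lambda` is tuned by
generalized cross-validation with an effective-number-of-parameters
correction. A competing-risks simulator, selection/estimation metrics
(TPR, FDR, bias, non-zero MSE, Monte Carlo SEs) and a small CLI support
replicated selection studies; the packaged benchmark is a nine-state,
eight-transition acute myeloid leukemia (AML) pathway.

## Worked example

```r
library(fusedmsm)

chart  <- aml_state_chart()          # 9 states, 8 transitions, pairs (3,7), (4,8)
dat    <- simulate_paths(aml_dgp(N = 1000), seed = 11)
design <- expand_design(dat, chart)  # stacked design: P*Q = 16 coefficients
ps     <- penalty_structure(chart, P = 2)

tuned <- fsgl_tune(design, ps, alphas = 1, gammas = 0.25)
tuned$argmin
#>  alpha gamma   lambda          gcv        e      nll n_selected converged
#>      1  0.25 29.00006 0.0005361024 2.695783 11788.66          7      TRUE

round(tuned$fits[["1/0.25"]]$beta_hat, 3)
#>  [1]  1.392  0.000  1.004 -0.363  0.000  0.000  1.004 -0.363 -0.013  0.000
#> [11]  0.000  0.000  0.018  0.000  0.000  0.000
```

The tuned fused fit recovers all five truly nonzero effects of biomarker
X1 (stacked order: transitions 1..8 for X1, then X2): the strong effect on
transition 1, and the two fused pairs — transitions 3/7 estimated at the
common value 1.004 (truth 1.2) and transitions 4/8 at −0.363 (truth −0.8,
shrunk but jointly retained) — plus two small false positives on the null
biomarker X2; the other nine null coefficients are exact zeros. The GCV
column is the tuned statistic (about 0.54·10⁻³ on this data, reported per
long-format row); `e` is the effective number of parameters of the
selected fit. A pure-lasso fit (`alphas = 1, gammas = 1`) on the same
data typically drops the weak late effect on transition 8 entirely and
cannot tie the pairs together.

Study-scale replication (the basis of the package's selection
benchmarks):

```r
study <- run_study(aml_dgp(), nsim = 50, base_seed = 7000)
summarize_study(study)$selection[, c("method", "tpr_median", "fdr_median")]
```

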