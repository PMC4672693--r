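# longcace

Complier-average causal effects (CACE) for longitudinal randomised trials in
which control-arm participants may cross over to a one-off intervention at
any time during follow-up.

## The problem and who this is for

Trial statisticians analysing a two-arm trial with a repeatedly measured
outcome (say hearing loss in dB at visits 1..m) face a familiar bind when
crossover is substantial: intention-to-treat (ITT) compares policies and
dilutes a transient treatment effect — at late visits much of the "control"
arm has quietly been treated — while per-protocol and as-treated analyses
are confounded by whoever chooses to cross over.  `longcace` estimates the
causal effect of the intervention *k visits (or days) after receiving it*,
among the principal strata of compliers, using only the randomisation for
identification.

## The model

Compliance type `C = 0..m` is the last visit before a subject would receive
the intervention under randomisation to control (`C = m`: never).  Outcomes
are multivariate normal with unstructured covariance and mean

    E[Y_ij | R_i, C_i] = alpha(C_i, j) + beta(k_ij),

where `k_ij` is the number of visits since treatment (`j` in the
intervention arm; `j - C_i` after crossover; 0 while untreated) and
`beta(0) = 0`.  Type-specific untreated trajectories `alpha(c, j)` absorb
indirect selection; `beta(j)` is the CACE at visit `j`.  A day-scale variant
interpolates `beta` piecewise-linearly in exact days since treatment.
Estimation is Bayesian (Gibbs sampling with data augmentation over the
latent types and missing-at-random outcomes).  A closed-form recursive
moment estimator inverts the population identity
`ITT(j) = beta(j) - sum_{c<j} gamma(c) beta(j-c)`, and ITT and 2SLS
instrumental-variables fits are included as comparators.

## Worked example

```r
library(longcace)

cfg <- sim_config(n = 300, n_replicates = 1, base_seed = 42)  # reference design
d   <- generate_dataset(cfg, 1)    # truth: beta = (10, 8, 6, 4, 2)

cace_moment(d)
#> Recursive moment estimates of the longitudinal CACE
#>   gamma (type probabilities): 0.099 0.099 0.079 0.086 0.159 0.477
#>                visit1 visit2 visit3 visit4 visit5
#> ITT difference 10.269  4.052  4.815  1.541 -1.727
#> CACE beta      11.401  5.756  6.987  4.080  1.711

fit <- cace_bayes(d, control = cace_control(n_iter = 3000, n_burnin = 500),
                  seed = 7)
coef(fit)
#>   beta[1]   beta[2]   beta[3]   beta[4]   beta[5]
#> 11.511878  5.913672  7.288468  3.858020  1.747169

fit_iv(d)
#> Two-stage least-squares CACE estimates (cluster-robust by subject)
#>       estimate    se  lower  upper
#> beta1   11.401 1.231  8.988 13.814
#> beta2    5.756 1.284  3.240  8.272
#> beta3    6.987 1.415  4.213  9.761
#> beta4    4.080 1.373  1.389  6.770
#> beta5    1.711 1.413 -1.059  4.481
```

The ITT differences understate the effect at every visit past the first
(4.1 vs a true 8 at visit 2) because the control arm is progressively
contaminated; both CACE estimators undo the dilution.  With complete data
the 2SLS and moment point estimates coincide (the system is
just-identified); the Bayesian posterior means agree within sampling noise
but carry tighter intervals.

`read_trial_csv()` / `write_trial_csv()` handle real datasets (one row per
subject: `id, R, D, [T_days], y1..ym`), and a thin command-line wrapper in
`inst/cli/longcace.R` exposes `fit`, `simulate` and `study` subcommands.

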