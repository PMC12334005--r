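# apcbayes

Bayesian regularization for age-period-cohort (APC) analysis, with the
machinery to measure — on data whose truth is known — which priors recover
true linear trends and which silently reassign them.

## The problem

An APC table indexes an outcome by age group *i* = 1..*I*, period
*j* = 1..*J*, and birth cohort *k* = *j* − *i* + *I* (*K* = *I* + *J* − 1).
The Gaussian working model is

    y_n ~ Normal(b0 + bA_i + bP_j + bC_k, sigma),

each effect block summing to zero. Because cohort = period − age exactly,
the centered indexes satisfy `vA_i − vP_j + vC_k = 0`, and shifting the
three blocks by `(+s·vA, −s·vP, +s·vC)` leaves every fitted mean unchanged
for any real *s*: the linear components of the three effects are not
identified by the likelihood. Every APC method resolves this flat direction
by a constraint, and the constraint — not the data — decides where the
linear trend lands.

The package implements three Gaussian shrinkage priors that make that
choice differently:

| prior | penalizes | slope weight per block |
|---|---|---|
| random effects | squared levels, per-block scale | `sum(v^2) = M(M+1)(M−1)/12` |
| ridge (intrinsic estimator) | squared levels, one shared scale | `sum(v^2)` |
| random walk | squared adjacent differences | `M − 1` |

Since *K* > *I*, *J*, the `sum(v^2)` weighting presses hardest on the
cohort slope — magnitude shrinkage tends to flatten cohort trends, while
difference shrinkage (random walk) need not. The gap between the two
weighting schemes is strictly positive for every grid
(`index_weight_gap()`).

Fitting is by an exact blocked Gibbs sampler (RcppArmadillo) under a hard
sum-to-zero parameterization, with a collapsed Metropolis move along the
likelihood-flat direction so chains cross between posterior basins;
convergence is judged by split-R-hat < 1.05. Against a known truth, the
identification-shift bias statistic

    s = [Σ vA·(est−truth)A − Σ vP·(est−truth)P + Σ vC·(est−truth)C] /
        [Σ vA² + Σ vP² + Σ vC²]

is the closed-form shift best aligning estimate and truth (`solve_s()`);
|s| < 0.02 grades A, < 0.04 B, and so on to E. Simulation drivers
(`run_simulation1/2/3()`) generate trigonometric artificial parameters,
fit all three models, and aggregate `delta = mean(s²)` over converged
replicates.

## Worked example

Generate data in which *only the cohort effect* carries a linear slope
(0.1 per index step, with a small nonlinear cosine of amplitude 0.05),
then ask each prior what it found:

```r
library(apcbayes)

grid  <- apc_grid(10, 10)                       # K = 19 cohorts, N = 1000
truth <- make_trig_params(grid, slopes = c(0, 0, 0.1),
                          amps = c(0, 0, 0.05), gamma = 0.1)
data  <- generate_data(truth, replicates = 10, seed = 1)

for (kind in apc_model_kinds()) {
  fit <- fit_apc(kind, data, sampler_config(seed = 1))
  s <- solve_s(point_estimates(fit), truth)
  cat(sprintf("%-15s s = %+.3f  grade %s  (converged: %s)\n",
              kind, s, grade_s(s), fit$converged))
}
```

```
random_effects  s = -0.099  grade E  (converged: TRUE)
ridge           s = -0.077  grade D  (converged: TRUE)
random_walk     s = +0.000  grade A  (converged: TRUE)
```

All three fits converge and reproduce the data equally well — yet the
random-effects model has shifted the entire cohort slope into the age and
period blocks (s ≈ −0.099 cancels the true 0.1 almost exactly), the ridge
model has removed most of it (the minimum-norm split across the index
weights), and only the random-walk prior returns the trend to the cohort
block. A command-line front end over the same functions is in
`inst/cli/apc-sim.R`.

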