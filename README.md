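# pnpmix

Precise/not-precise (PNP) mixture modeling of judgment data.

## The problem

In multiple-cue judgment, people produce a response `y` from numeric cues
`x` via some cognitive algorithm `g(x | θ)` — adding up cue weights,
multiplying a probability by a payoff, computing an area, or averaging
remembered exemplars. Standard modelling assumes every response is
perturbed by homogeneous Gaussian noise, `y = g(x | θ) + N(0, σ²)`. That is
right for *intuitive* processes, whose errors are ubiquitous but modest.
It is wrong for *analytic* ones: someone who mentally computes an expected
value produces the exact number on most trials and an occasional large
error — a leptokurtic error distribution that biases least-squares
parameter estimates and misses the most diagnostic feature of the data,
the error distribution itself.

`pnpmix` implements the PNP model for researchers in judgment and decision
making: a two-component Gaussian mixture around the algorithm's
predictions,

```
f(y) = λ · N(y; g(x|θ), σ²) + (1 − λ) · N(y; g(x|θ), τ²)
```

where `λ` is the probability of a non-precise response, `σ` the execution
-error scale, and `τ` a fixed, very narrow width defining what counts as
"precise" (a technical constant, by default `sd(y) × 10⁻³`). At `λ = 1`
the model reduces exactly to conventional Gaussian regression. A fitted
`λ` near 1 labels an intuitive process; a low, usually nonzero `λ` with
the typical response exactly on the rule labels an analytic one. Because
the likelihood surface is needle-shaped, the fitter combines an exact-fit
consensus search over minimal trial subsets with classification-based
estimation and an EM polish, always keeping the `λ = 1` regression
solution in the comparison set (see the methods vignette,
`vignettes/pnp-model.Rmd`).

The package also ships the surrounding toolkit: a reference-algorithm
library (additive, multiplicative/divisive, expected value, nonadditive
exponential, exemplar-based), BIC-based per-participant strategy
classification with Intuition/Analysis labels, test-retest reliability and
the saturation index `SI = R²/ρ`, Kolmogorov–Smirnov residual diagnostics,
a synthetic-data generator implementing the model's generative process,
and a parameter-recovery harness comparing the mixture against ordinary
regression.

## Worked example

An analytic participant: 32 willingness-to-pay judgments of lotteries, 25
exactly equal to the lottery's expected value, 7 perturbed by large noise
(sd 92.6):

```r
library(pnpmix)
d <- make_fixture("id24_like", seed = 3)
fit <- pnp(response ~ cue_1 + cue_2, d, algorithm = "expected_value",
           tau = 1e-3)
summary(fit)
#> Precise/not-precise mixture fit (algorithm: expected_value, n = 32 trials)
#>   theta:
#> alpha  beta
#>     0     1
#>   lambda = 0.219   sigma = 83.959   tau = 0.001
#>   logLik = 91.965   BIC = -170.068   adj. R^2 = 0.013
#>   precise trials: 25 / 32; process label: mixed
#> K-S test vs N(0, 39.3^2): D = 0.406, p = 5.174e-05 (n = 32)
```

The mixture recovers the generating rule exactly (`α = 0`, `β = 1`) and
reads `λ = 7/32 = .219` off the data as the share of non-precise trials;
the K-S test rejects a homogeneous Gaussian error. An ordinary regression
on the same data (`pnp(..., lambda = 1)`) is pulled off the rule by the
seven errors (`β ≈ 0.67`) and, by BIC, fits worse — precisely the bias
the mixture exists to remove. On data with *no* exact matches the two
models return identical estimates and `λ = 1`.

The parameter-recovery study (21 error probabilities × 100 simulated
participants × 50 trials, additive truth `θ = (50, 4, 3, 2, 1)`,
`σ = 10`):

```r
rec <- run_recovery(seed = 1)
rec
#> Parameter recovery: 21 lambda points x 100 participants x 50 trials
#> Grand means of parameter estimates across the grid:
#>  model  alpha beta_1 beta_2 beta_3 beta_4 sigma
#>    pnp 50.012  3.999  3.003  1.992  1.003 9.669
#>    reg 49.990  3.994  2.999  2.001  1.003 6.093
#> Mixture lambda MSE over all fits: 0.00409
```

Both models recover the location parameters on average, but only the
mixture recovers the error magnitude `σ` (the regression estimate is
biased toward `σ√λ` because precise trials dilute its residual variance),
and the mixture's per-parameter mean squared error is far below the
regression's at intermediate error probabilities, where exact trials pin
`θ` down exactly.

## Command-line interface

```sh
pnp=inst/scripts/pnp
Rscript $pnp simulate --kind id24_like --seed 3 --out id24.csv
Rscript $pnp fit      --data id24.csv --algo expected_value --tau 1e-3
Rscript $pnp select   --data cohort.csv --candidates product,linear_additive
Rscript $pnp recover  --seed 1 --out recovery        # add --full for 101×1000
```

Datasets are delimited text (comma or tab) with columns `participant_id`,
`item_id`, `repetition`, `cue_1..cue_k`, `response` and an optional
`condition`; fits serialise to JSON, tables to CSV.
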