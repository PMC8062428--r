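---
title: "The precise/not-precise mixture model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The precise/not-precise mixture model: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pnpmix)
```

## The model

Conventional cognitive modelling assumes that a judgment $y$ is the output
of an algorithm $g(\mathbf{x}\,|\,\boldsymbol\theta)$ over a cue vector
$\mathbf{x}$, perturbed on every trial by homogeneous Gaussian error:
$y = g(\mathbf{x}\,|\,\boldsymbol\theta) + N(0, \sigma^2)$. That assumption
is adequate for noisy, intuitive processes, but it misdescribes analytic
ones, where people *execute* an explicit rule: most responses are then
numerically exact, and the rare errors can be large. The error distribution
around the rule is leptokurtic, not Gaussian, and a least-squares or
homogeneous-ML fit is biased by the few large errors.

The precise/not-precise (PNP) mixture makes the two realisations explicit.
With probability $\lambda$ a response carries execution error
($N(0, \sigma^2)$); otherwise it is a precise execution. Because a point
mass admits no density, the precise branch is represented by a very narrow
Gaussian of fixed width $\tau$, giving the trial density

$$f(y) \;=\; \lambda\, N\!\big(y;\, g(\mathbf{x}|\boldsymbol\theta),
\sigma^2\big) \;+\; (1-\lambda)\, N\!\big(y;\,
g(\mathbf{x}|\boldsymbol\theta), \tau^2\big).$$

$\lambda$, $\sigma$ and $\boldsymbol\theta$ are estimated by maximum
likelihood; $\tau$ is a *technical* constant — a definition of how close a
response must be to count as exact — never an error estimate, and it is not
counted as a free parameter. At $\lambda = 1$ the model reduces exactly to
the homogeneous Gaussian regression, which `pnp(..., lambda = 1)` fits as
the baseline with one fewer free parameter. A fitted $\lambda$ near 1 with
Gaussian residuals is the signature of an intuitive process; a low but
usually nonzero $\lambda$, with the typical response exactly on the rule,
is the signature of an analytic one.

## Choosing tau

The default follows the convention of placing $\tau$ three decimal orders
below the variation of the response variable,
$\tau = \mathrm{sd}(y) \times 10^{-3}$. At that scale no behaviourally
plausible response lands inside the precise band by accident, while exact
executions (which match $g$ to machine precision in simulated data, and to
the response resolution in real data) always do. When the response scale is
known a priori — e.g. willingness-to-pay in whole currency units —
passing an explicit `tau` (the worked examples use `1e-3`) is preferable,
and when several response variables with different ranges are analysed
side by side, $\tau$ should be set per variable. Results are insensitive to
$\tau$ over two orders of magnitude precisely because it only defines a
tolerance band; what matters is that $\tau \ll \sigma$.

## Why fitting needs an exact-fit search

The mixture likelihood is needle-shaped in $\boldsymbol\theta$: whenever
some parameter vector reproduces a subset of responses exactly, the narrow
component multiplies the likelihood by roughly $\sigma/\tau$ *per matching
trial*. A simplex or gradient search started from the least-squares
solution never sees these needles — the basin of attraction has width
$\tau$ — and collapses to $\lambda = 1$. The fitter in `pnp()` therefore
works in four stages:

1. **Exact-fit consensus search.** For algorithms linear in
   $\boldsymbol\theta$ (all built-ins except the exemplar model), solve
   $g(\mathbf{x}|\boldsymbol\theta) = y$ on many minimal trial subsets and
   count how many other trials the solution reproduces. Subsets are drawn
   from pools of trials with the smallest current residuals (several pool
   sizes, enumerated exhaustively when the pool is tiny), because precise
   trials concentrate at the bottom of the residual ordering of any
   reasonable reference fit; this is what makes the search practical even
   when only 20–30% of trials are precise and a blind minimal-subset draw
   would almost never be all-precise. If a full pass finds nothing, trials
   are re-ordered by trimmed least-squares refits and the pass repeats.
2. **Admission rule.** A candidate is admitted only if *strictly more*
   trials than it has parameters match it to numerical exactness
   (`exact_tol`, default $10^{-8}\,\mathrm{sd}(y)$). Any $d$ generic trials
   are interpolated exactly by a $d$-parameter linear rule, so a bare
   minimal subset carries no evidence; and under pure noise, hyperplanes
   through $d$ noisy trials pick up *coincidental* near-matches inside a
   loose tolerance band often enough that they would otherwise outscore
   the honest Gaussian solution in mixture likelihood. Requiring exact
   support beyond the subset makes the false-positive probability
   negligible while never rejecting genuine precise structure, whose
   residuals are zero up to float arithmetic. The looser band
   $5\tau$ (`precise_mult`) is still used where the model's own semantics
   require it: classifying trials as precise versus non-precise.
3. **Classification estimate and EM polish.** Each admitted candidate is
   turned into a full parameter vector ($\lambda$ = share of non-precise
   trials, $\sigma$ = ML scale of the non-precise residuals,
   $\boldsymbol\theta$ refitted on the precise set) and polished by EM,
   whose M-step for $\boldsymbol\theta$ is a weighted least squares with
   weights $r_i/\sigma^2 + (1-r_i)/\tau^2$. For cleanly separated
   solutions a final exact refit on the posterior-precise set pins
   $\boldsymbol\theta$ to machine precision and $\lambda$ to a trial
   fraction.
4. **Likelihood comparison.** The $\lambda = 1$ Gaussian solution is always
   in the comparison set, so the returned log-likelihood never falls below
   the baseline's likelihood evaluated under the mixture density, and data
   without exact matches reduce *identically* to the regression fit.

During optimisation $\sigma$ is bounded below by
$\max(100\tau,\ 10^{-6}\mathrm{sd}(y))$ to keep the two components
identifiable. If no trial is classified non-precise the fit reports
$\lambda = 0$ with `sigma_defined = FALSE`: execution error is only
measured on errors that actually occurred, and such fits are excluded from
$\sigma$ summaries.

One real limitation follows from the admission rule: precise responses are
assumed to be *numerically exact* relative to the recorded response (true
of the generative process, and of behavioural data wherever responses are
recorded at the resolution at which people produce them). If responses are
exact executions later perturbed by sub-$\tau$ recording jitter, lower
`exact_tol` appropriately (e.g. to `tau`), at a small risk of coincidental
admissions in pure-noise data.

## Estimator conventions

All scale estimates are maximum likelihood: the Gaussian baseline reports
$\hat\sigma^2 = \mathrm{RSS}/n$ (not $/(n-p)$), and the mixture's
$\hat\sigma$ divides by the (effective) number of non-precise trials
without small-sample correction. Free-parameter counts for the BIC are
$\dim(\boldsymbol\theta) + 1$ for the baseline and
$\dim(\boldsymbol\theta) + 2$ for the mixture; $\tau$ is never counted.
Adjusted $R^2$ adjusts by $\dim(\boldsymbol\theta)$. These conventions
shift small-sample summaries by a few percent relative to
degrees-of-freedom-corrected alternatives, which is why the recovery
study's $\sigma$ summaries (below) have tolerances of that order.

## The reference algorithm library

Built-in algorithms cover the judgment domains the package targets:
a `linear_additive` rule $\alpha + \sum_i \beta_i x_i$ (the default rule
people fall back on in multiple-cue judgment); linearly scaled
single-core functions $\alpha + \beta\,\mathrm{core}(\mathbf{x})$ with
multiplicative (`product`, `expected_value`) and divisive (`dividend_m1`,
`dividend_m2`) cores and the identity core (`area_scaled`), capturing both
biased and unbiased ($\alpha = 0, \beta = 1$) rule use; a fixed nonadditive
exponential criterion `nonadditive_exp`,
$509.05 + 0.54\,e^{(4x_1+3x_2+2x_3+x_4)/18}$, whose constants match the
additive rule's training criterion range; and an `exemplar` model — a
generalized context model for a continuous criterion — predicting the
similarity-weighted average of stored exemplar criteria with sensitivity
$\delta$ and attention weights $\omega_i$, using city-block similarity
$\exp(-\delta \sum_i \omega_i |x_i - x^*_{ji}|)$ on raw (unstandardised)
cues.

Two open choices were fixed as follows. The attention weights are
constrained to the unit simplex during fitting because their overall scale
is confounded with $\delta$; the exemplar model therefore contributes
$k$ free parameters ($\delta$ plus $k-1$ weights). And because exemplar
predictions essentially never match responses exactly (judgments of
exemplar users carry ubiquitous similarity-weighting noise), the exemplar
fit uses multi-start Nelder–Mead over $(\log\delta,$ attention logits$)$
with $\delta$ starts $\{0.1, 1, 10\}$, maximising the profile mixture
likelihood with $(\lambda, \sigma)$ handled by EM per candidate — an
exact-fit search would have nothing to find there.

## The synthetic-data generator

`simulate_participant()` *is* the model's generative process: cues drawn
uniformly (by default on $[0, 10]$), a Bernoulli($\lambda$) error
indicator per trial, and responses equal to $g$ exactly on error-free
trials — not $g$ plus narrow noise; the narrow component exists only to
make the likelihood integrable. The defaults of the recovery study
(`run_recovery()`) are the study conditions of the additive
multiple-cue-judgment design: four cues on $[0,10]$,
$\boldsymbol\theta = (50, 4, 3, 2, 1)$, $\sigma = 10$, $n = 50$ trials per
participant. The desk-scale default grid is 21 error probabilities
$(0, .05, \dots, 1)$ with 100 participants each — 2,100 mixture fits plus
2,100 baseline fits, a few minutes on one CPU — rather than the full
$101 \times 1000$ design, which the same function runs when asked
(`lambda_grid = seq(0, 1, by = .01), n_participants = 1000`). Tolerances
on recovery summaries are set to the Monte-Carlo error of the scaled-down
design. Per-participant seeds derive from the master seed by a stated
counter scheme (`participant_seed()`), so any single participant can be
re-simulated in isolation; cue designs are drawn fresh per participant.

What the generator does *not* emulate: discrete or rounded response
scales (which can produce exact matches "by chance" and bias $\lambda$
downward — no chance-match correction is implemented), item repetition
effects, learning or drift across trials, and cue distributions other than
independent uniforms. Passing recovery therefore shows that the estimator
is consistent under its own generative assumptions, not that those
assumptions hold in any particular experiment.

Grand means across the grid average the per-grid-point means with equal
weight (equivalent to pooling here, since every point has the same number
of participants). The mixture's $\sigma$ grand mean skips fits with
$\hat\lambda = 0$ (no errors to measure) and hence the $\lambda = 0$ grid
point entirely; the baseline's includes its degenerate $\hat\sigma = 0$
fits at $\lambda = 0$.

## Classification, reliability, saturation

`select_model()` fits the mixture once per candidate algorithm and keeps
the lowest BIC; exact ties break deterministically to fewer free
parameters, then to the additive rule, then to candidate order. Fitted
$\lambda$ values are labelled by the empirically bimodal cutpoints
`analysis` ($\lambda < .1$), `intuition` ($\lambda > .8$) and `mixed`
otherwise — the middle bin is deliberate, to avoid forcing a dichotomy on
genuinely blended processes.

Model fit is reported three ways. BIC ranks candidates but says nothing
about absolute fit; adjusted $R^2$ measures explained variance; and the
saturation index $SI = R^2/\rho$ measures the share of *systematic*
variance explained, where the reliability $\rho$ is the Pearson
correlation between two presentations of the same items
(`estimate_reliability()`; classical test theory, since no other
definition is forced by the data layout). $SI \approx 1$ means the
algorithm captures all the structure there is to capture; a low $SI$ with
high $\rho$ flags a misspecified algorithm even when $R^2$ looks fine.
Sampling error can push $SI$ slightly above 1; such values are flagged,
not truncated. Residual normality is tested with a one-sample
Kolmogorov–Smirnov test against $N(0, \hat\sigma^2)$ with the scale
plugged in; because the scale is estimated from the same residuals, the
test is anti-conservative, which is acceptable for its diagnostic role
(the mixtures it is meant to reject fail it by enormous margins).

## Numerical notes

Mixture log-densities are computed by log-sum-exp; EM stops at a relative
log-likelihood change of $10^{-10}$ or 300 iterations; subset solves that
hit singular designs (duplicated items) are discarded and redrawn;
division cores reject divisors below $10^{-12}$ with the offending trial
index; exemplar similarity underflow (all similarities zero) falls back to
the unweighted criterion mean and is flagged. Every stochastic routine
takes an explicit seed and restores the caller's RNG state; fits are
deterministic given `pnp_control(seed = )`.

## Known limitations

Beyond the exactness assumption and the missing discrete-response
correction noted above: $\tau$ is fixed, never estimated, and no
non-Gaussian error families are offered for the wide component; the
exemplar store must be supplied (no feedback-learning dynamics); and group
-level inferential statistics are out of scope — classification tables are
exported for the user's statistics environment instead.
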