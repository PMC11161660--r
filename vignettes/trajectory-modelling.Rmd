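---
title: "Continuous-time trajectory models for bounded ordinal symptom scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuous-time trajectory models for bounded ordinal symptom scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ideatraj)
```

## The model

`ideatraj` models irregularly observed, bounded integer symptom scores
(the summed SIDAS suicidal-ideation scale, 0–50) as noisy, discretised
observations of a continuous-time latent process. Three layers:

**Latent dynamics.** Individual $m$ has a latent state $x_m(t)$ following
either a Wiener process or an Ornstein–Uhlenbeck process. Both admit exact
Gaussian transitions over an arbitrary gap $\Delta$ (days):

- Wiener: $x(t+\Delta) \mid x(t) \sim N\!\big(x(t),\; e^{2\phi_2}\Delta\big)$.
- OU, with rate $\theta = e^{\phi_3}$:
  $x(t+\Delta) \mid x(t) \sim
  N\!\big(\phi_4 + (x(t)-\phi_4)e^{-\theta\Delta},\;
  \tfrac{e^{2\phi_2}}{2\theta}(1 - e^{-2\theta\Delta})\big)$.

The initial latent state *is* the baseline parameter: $x_m(0) = \phi_{m,1}$.
The first observation is still noisy through the observation layer, so
$\phi_{m,1}$ is estimated, not pinned to the first score.

**Observation model.** A scaled-logistic link maps the unbounded state to a
mean on the score scale, $\mu = S\,\mathrm{logistic}(c\,x)$ with $S = 50$,
and the integer score follows a discretised normal around $\mu$ with SD
$\sigma_y$: interior scores take the probability of their unit-width bin,
and the boundary scores 0 and 50 absorb the tails, so the pmf is proper for
every $\mu$ and the log-likelihood is finite for every finite state.

**Population layer.** Each parameter slot is either a *random* effect,
$\phi_{m,j} \sim N(\mu_j, \tau_j^2)$, or a *fixed* effect shared across the
cohort. Four standard variants ([`model_spec()`]) ladder up from
random-baseline/fixed-diffusion Wiener (1) to fully random OU (4).

## Parameterisation choices

- **Diffusion on the log-SD scale** ($e^{\phi_2}$ = latent SD per
  $\sqrt{\text{day}}$) and **OU rate as $e^{\phi_3}$**: both keep the
  natural-scale quantities positive while leaving the sampled parameters
  unbounded, which is what the normal random-effects layer assumes.
- **Time unit: days** throughout (gaps, horizons, FUT).
- **Link calibration.** Only the *form* of the link (logistic) and
  observation family (discretised normal) are structural; the steepness $c$
  and noise $\sigma_y$ set the meaning of the diffusion scale. The defaults
  $c = 0.5$, $\sigma_y = 0.5$ are calibrated to the one public numeric
  anchor for this model family: a trajectory started at score 2 with
  $\phi_2 = -1.23$ must diffuse to a day-7 95% equal-tailed interval of
  $[1, 4]$. Under $c = 1$ or $\sigma_y = 2$ the same start produces far
  wider intervals (e.g. $[0, 9]$), inconsistent with that anchor. Both
  values remain user-configurable in [`obs_config()`].
- **$\sigma_y$ shared across the cohort**, fixed by default and optionally
  sampled (pseudo-marginal step, prior $\log\sigma_y \sim N(0,1)$). A
  single observation-noise scale is the parsimonious reading when nothing
  identifies individual-specific noise in sparse series.

## Inference

The discretised observation model destroys the Kalman recursions, so each
individual's marginal likelihood is estimated by a bootstrap particle
filter: particles start at $\phi_1$ at $t=0$, propagate by the exact
transition over each gap, are weighted by the observation pmf, contribute
the predictive increment $\log(\text{mean weight})$, and are
systematically resampled. The per-observation increments are retained —
they are the pointwise terms WAIC needs.

Sampling is Metropolis-within-Gibbs:

1. **Individuals** — correlated pseudo-marginal MH. All the filter's random
   inputs are explicit auxiliary variables (one normal per particle per
   transition; one per resampling step, mapped to a uniform through the
   normal CDF). A proposal refreshes them by Crank–Nicolson,
   $u' = \rho u + \sqrt{1-\rho^2}\,\varepsilon$, so successive likelihood
   estimates share most of their Monte-Carlo noise and the acceptance
   ratio is not drowned by estimator variance. Defaults: 100 particles,
   $\rho = 0.99$ — standard correlated-pseudo-marginal practice; the test
   suite verifies that $\rho = 0.99$ beats $\rho = 0$ on acceptance rate at
   small particle counts.
2. **Population** — semi-conjugate Gibbs: normal full conditional for each
   $\mu_j$, then inverse-gamma for $\tau_j^2$. Default hyperpriors
   $\mu_j \sim N(0, 5^2)$, $\tau_j^2 \sim \mathrm{IG}(2, 1)$ are weakly
   informative on the latent scale (state units are roughly logits/2).
3. **Fixed effects** — a joint pseudo-marginal MH step summing all
   individuals' filter log-likelihoods.

Proposal scales adapt during burn-in towards 0.3 acceptance
(Robbins–Monro on the log scale, gain $\min(0.25, 2/\sqrt{t})$) and are
frozen afterwards, so the post-burn-in chain is a fixed Markov kernel.

### Numerical choices

- Observation log-likelihoods are computed directly on the log scale
  (log-CDF differences with `log1p`/`expm1`), never by logging a pmf
  entry, so deep-tail weights stay finite and the filter cannot produce
  $-\infty$ weights for finite parameters.
- The OU variance uses `-expm1(-2\theta\Delta)/(2\theta)` with a series
  switch below $\theta\Delta = 10^{-10}$, making the Wiener limit exact
  rather than catastrophically cancelled.
- Particles are sorted by state before systematic resampling. This leaves
  the marginal distribution of the likelihood estimator unchanged (verified
  against an unsorted filter) but makes the auxiliary-to-likelihood map
  smooth, which the correlated refresh relies on.
- Duplicate (individual, time) records keep the last entry (clinical
  re-entry reading); residual exact ties are offset by $10^{-3}$ days to
  preserve strict ordering.

### Validation oracles

The sampler's components are checked against independent reference
implementations that share no code with the package: Gauss–Hermite
quadrature (800 nodes — fewer under-resolve the narrow observation bump
against the wide transition density) and a dense-grid HMM filter for the
likelihood; an exact Kalman filter in a linear-Gaussian observation mode
(`obs_config(family = "gaussian")`, identity link, continuous density)
that exists solely for this purpose; and a 201-point grid posterior for
the MH kernel with the exact likelihood substituted.

## Prediction and clinical summaries

Predictions are posterior predictive: for each retained parameter draw the
particle filter is re-run and the current latent state sampled from the
filtering distribution at the last observation (not a smoothed or point
estimate — forecasting conditions on the observed past only), then the SDE
is stepped daily over a 60-day horizon and a score sampled each day.
Summaries per day: median, 68% and 95% equal-tailed intervals.

- **IHIP**: fraction of trajectories strictly exceeding score 20 on any
  day. Evaluated on the observed (score) scale.
- **FUT**: first day the 95% ETI range exceeds 25 (half the scale), read as
  "information half-life"; if never crossed it is reported as the horizon
  with an explicit censoring flag rather than a sentinel value. "Range" is
  hi − lo of the 95% ETI — the level the FUT rule itself names.
- **V**: within each parameter draw, the 95% ETI range of the day-60
  score across that draw's trajectories; V is the mean of these ranges and
  is reported with their 80% HDI. Computing the range *within* draws gives
  the HDI a well-defined distribution to summarise; the 80% level is used
  because the range distribution is wide-tailed and asymmetric.
- **Dynamic updating** ([`update_individual()`]): a single individual is
  re-estimated from an observation prefix with the population prior frozen
  at MAP point estimates ([`map_population()`]), then predicted forward.
  Population-parameter uncertainty is deliberately not propagated — the
  cost of the approximation is an understatement of band width early in
  care, and the test suite verifies the qualitative behaviour that bands
  tighten as observations accrue.
- **Covariate associations**: per posterior draw, the Pearson correlation
  (continuous) or group-mean difference (binary) between individuals'
  diffusion values and a baseline covariate, summarised by mean and 95%
  ETI, so parameter uncertainty propagates into the interval.

## The synthetic cohort generator

[`generate_cohort()`] emulates the sampling structure of digital
measurement-based-care cohorts, and its defaults are the study conditions
all package validation runs under:

| feature | default | note |
|---|---|---|
| observation count | median 2, mean 4.5, min 2 | zero-inflated shifted geometric: exactly 2 w.p. 0.55, else $3 + \mathrm{Geom}(0.18)$; a plain shifted geometric cannot hit both median 2 and mean 4.5 |
| gaps | log-normal, median 35 d, sdlog 3.47 | sdlog matches the 1:108 interquartile *ratio*; a two-parameter log-normal cannot match median 35 and quartiles (1, 108) simultaneously |
| zero-ideation subgroup | 26% | structural zeros: all-zero scores regardless of latent dynamics |
| population | $\mu = (-4.39, -1.23)$, $\tau = (2, 0.6)$, $\sigma_y = 0.5$ | baseline centre is the latent preimage of score 5; SDs give baseline scores roughly 0–20 and a plausible volatility spread |

Structural zeros are generated but *not* specially modelled by inference —
the continuous model cannot represent a hard zero state, and that mismatch
is a known limitation of the model class, so recovery studies set
`zero_fraction = 0`. What passing tests show is therefore recovery under
the model's own assumptions plus the cohort's sampling structure; they do
not show robustness to never-ideating subgroups, informative (not-missing-
at-random) observation timing, or abrupt regime changes, none of which the
generator emulates.

## Simulation-study sizes

The validation studies are sized to be decisive yet quick on one CPU:
parameter recovery uses 40 individuals × 20 observations with a 700/300
iteration chain at 100 particles (population hyperparameters recovered
within 3 posterior SDs; individual-diffusion correlation with truth
\> 0.9); model selection fits variants 1 and 2 to 10 cohorts of 12 × 12
with 300-iteration chains (WAIC, on individuals with ≥ 10 observations,
prefers the generating random-diffusion variant in ≥ 8/10); the
grid-posterior check runs a 4000-step exact-likelihood chain (posterior-
mean discrepancy \< 0.02 typical). Full-cohort analyses at clinical scale
(hundreds of individuals) use the same code with longer chains.

## Known limitations

- One model family across the population: individuals with a genuine
  stable set-point are approximated by a random walk unless the OU variants
  fit better; mixture or regime-switching dynamics are out of scope.
- The binary character of ideation (exact zeros, sudden onsets) is not
  modelled; predictions for never-ideating individuals inherit a small
  but non-zero predicted spread.
- FUT depends on the chosen certainty rule (95% ETI range \> 25) and should
  be read as a relative, not absolute, monitoring recommendation.
- WAIC is used in place of cross-validation on run-time grounds; it is an
  approximation to out-of-sample predictive accuracy.
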