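---
title: "Dynamic multistate occupancy models for territory monitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic multistate occupancy models for territory monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

territrend fits a hidden Markov model to long-term territory survey
records in which the observed category on a visit can understate, but
never overstate, the territory's true condition. This vignette is the
package's own account of the model, the sampler, the numerical
choices, and what the synthetic studies in the test suite do and do
not establish.

## The state-space model

Each territory occupies one of four ordered states per breeding
season: 1 unoccupied, 2 single owl, 3 non-reproducing pair, 4
reproducing pair. The true state `z_it` is latent and evolves as a
first-order Markov chain with initial distribution `phi0` (length-4
probability vector) and season-specific 4x4 transition probability
matrices (TPMs). The true state is assumed constant within a season;
dynamics happen between seasons.

Every visit yields an observed state `y_itj` drawn conditional on
`z_it` from the row of a detection probability matrix (DPM). The DPM's
structural constraint — `Pr(y = n | z = m) = 0` for `n > m`, and row 1
equal to `(1, 0, 0, 0)` — encodes that surveyors can miss owls or miss
evidence of pairing/reproduction, but cannot observe a pair where only
a single owl lives. This constraint is what separates the four
detection regimes and lets the model allocate, say, a season with
observations `{1, 2, 4}` to a reproducing-pair territory with
imperfect detection rather than to a state change.

Both matrices use multi-logit (softmax) links with category 1 as
baseline:

* TPM row m: effects `beta0_t[m,n]`, n = 2..4, one free effect per
  destination per season; `beta0_t[m,n] ~ N(mu[m,n], sigma[m,n])`
  across seasons. All 16 transitions are estimable; no structural
  zeros are imposed even where data are sparse (e.g. unoccupied to
  reproducing), because the hierarchy's priors regularize poorly
  informed cells toward their hyper-means.
* DPM row m (m > 1): effects
  `alpha0_t[m,n] + alpha1_t[m,n] JD + alpha2_t[m,n] JD^2` over
  observed states n = 2..m, where JD is the standardized Julian date.
  Each of the three coefficients has its own normal random effect
  across seasons. The quadratic term lets detectability rise and fall
  within the March-August season, as it does for nesting raptors.

Julian dates are centred and scaled by the pooled mean and sample SD
(n - 1 denominator) over all records — one centre and scale across
blocks and years, since stratified scaling would make coefficients
incomparable across years. Degenerate inputs (all dates equal) are
refused rather than silently scaled.

All parameters are block-specific: `fit_multistate()` fits one block
per call, because management blocks with different histories should
not share transition or detection parameters.

### Territories entering the program late

Monitoring programs add territories over time. How the original
analyses of such data handled post-first-season entries is generally
not stated, so the package makes one defensible choice and flags it
here: every territory in a block gets a latent trajectory from the
block's first season, with pre-entry seasons treated as unvisited
(latent-only, no detection terms). This back-casts occupancy for late
entries under the block's shared dynamics; the alternative
(conditioning each territory on its own entry season) would change the
interpretation of early-season state counts. Seasons without visits
contribute transition structure but no detection factors throughout.

## Priors and their ambiguities

* `phi0 ~ Dirichlet(1,1,1,1)` — uniform over the simplex.
* Hyper-means ~ N(0, 2). Literature convention for "N(0, 2)" is
  ambiguous; the package reads it as variance 2 (SD ~1.41), with
  `prior_spec(mu_prior = "sd")` available for the SD-2 reading.
* Hyper-spreads ~ Gamma(shape 2, rate 0.5), placed on the SD by
  default (`sd_prior_on = "variance"` switches to the variance). The
  default gives prior mean 4 on the SD — weakly informative, allowing
  both near-constant and strongly year-varying effects.

On the probability scale these choices imply broad, non-degenerate
priors for every TPM/DPM entry.

## The sampler

`fit_multistate()` runs a purpose-built Gibbs sampler (C++ core):

1. **Latent states** by forward-filtering backward-sampling (FFBS):
   an exact draw from the joint conditional of each territory's state
   path. Forward probabilities are normalized per season, and
   per-season detection products are rescaled by their maximum before
   exponentiation, so long histories with many visits cannot
   underflow.
2. **Initial state probabilities** by a conjugate Dirichlet update
   from the season-1 state counts.
3. **Transition effects**: given the imputed states, each season-row
   `beta0_t[m, ]` has a multinomial likelihood in the transition
   counts; a 3-dimensional random-walk Metropolis step updates the row
   jointly.
4. **Detection effects**: each (season, true-state, observed-state)
   coefficient triple gets a random-walk Metropolis step against the
   likelihood of that season's visits at territories currently imputed
   to that state.
5. **Hyper-means** by conjugate normal updates; **hyper-SDs** by
   random-walk Metropolis on log sigma (with the change-of-variables
   Jacobian), so proposals stay positive.

Proposal scales adapt in batches of 50 iterations during burn-in
(targets 0.30 for the 3-dimensional blocks, 0.44 for scalars) and are
frozen afterwards, preserving detailed balance in the sampling phase.
All multi-logit and forward computations use log-sum-exp
stabilization, since effects can be large under the vague hyperpriors.
Chains run sequentially with seeds `seed + chain - 1`; every fit is
exactly reproducible from its configuration.

The default `mcmc_config()` (3 chains x 55,000, burn-in 5,000, thin
100, 1,500 retained draws per chain) mirrors standard practice for
this model class. Convergence is monitored with the Gelman-Rubin
statistic computed on retained draws (`gelman_rubin()`,
`rhat_table()`; split-chain variant optional); `fit_multistate()`
warns — never silently proceeds — when any hyper-parameter R-hat
exceeds 1.1.

Correctness checks in the test suite are dual-route: the forward
algorithm agrees with exhaustive path enumeration to 1e-10 on
randomized instances; FFBS draw frequencies match exact path
posteriors by chi-square test; and with zero visits the sampler's
hyper-mean marginals reproduce their N(0, 2) prior, which exercises
every update jointly.

## Derived quantities

Because states are imputed, the number of territories `N_t` in a state
set is available per posterior draw. `linear_trend()` computes, per
draw, the least-squares slope of `N_t` on centred year; the posterior
mean of those slopes is the trend estimate (territories per year) and
the equal-tailed 5%/95% draw quantiles give the 90% CRI.
`polynomial_trend()` projects each draw's count series on orthonormal
polynomial contrasts; its degree-1 contrast equals the linear slope
times `sqrt(sum((Yr - mean(Yr))^2))`, a pure rescaling, and the
degree-2 contrast measures curvature orthogonal to it.
`mean_transition_probs()` applies the multi-logit transform to the
hyper-means per draw, giving "average year" transition probabilities
such as the probability of reproducing given reproduction the year
before. Trend windows are inclusive of both endpoint years, so
adjacent windows deliberately share their boundary year; sub-window
trends reuse the same fitted draws rather than refitting. Windows that
extend past a block's surveyed seasons are refused (reported NA with a
message) rather than extrapolated.

## Posterior predictive checks

`ppc_check()` implements the generic replicate-and-compare scheme for
state-space models: for each retained draw, simulate replicated
observations at the real visit design conditional on that draw's
imputed states and detection parameters, and compare scalar
discrepancy statistics with `ppp = Pr(T(rep) >= T(obs))`. The
statistic set spans visit-level state frequencies, territory-level
naive best states, and between-year variability of the naive
reproducing count — chosen to probe the detection model, the state
allocation, and the dynamics respectively. This is a reconstruction of
standard practice for such models, not a reproduction of any specific
published checklist. Because replicates condition on the imputed `z`,
extreme ppp values flag detection-model misfit more sharply than
process misfit; the two cannot be fully disentangled.

## The synthetic-data generator

`simulate_surveys()` generates data in the model's own generative
direction: draw year effects from their hyper-distributions, draw and
propagate latent states, draw visit counts (support 1-15, median 3)
and distinct uniform dates within March 1 - August 31, then draw
observations from the DPM rows at the realized standardized dates.
`mendocino_preset()` fixes the emulated design: blocks of 18, 62 and
24 territories, seasons 1990-2014 with the third block discontinued
after 2006, and an 85% chance a territory is surveyed in a given year.
The default true hyper-parameters are synthetic values chosen once so
that all four states occur with non-negligible frequency and detection
is imperfect but informative (reproducing pairs detected well, singles
poorly); they are stored in `sim_config()`'s defaults and documented
as synthetic, not estimates.

What the generator does not emulate: staggered territory discovery
(all territories exist from season one), barred-owl or habitat
covariates, spatial correlation between territories, and
protocol-driven revisit rules (visit dates are exchangeable within a
season; an option concentrates them in April-June). Passing tests on
synthetic data therefore demonstrate that the estimation machinery
recovers the truth under the model's own assumptions — they cannot
certify those assumptions for any real dataset.

`drift_config()` builds the trend-recovery scenario: every TPM row
equals a year-specific target distribution whose state-4 mass falls
linearly (so the chain mixes in one step and the marginal state
distribution equals the target exactly), hyper-SDs are zero, and
detection is strong. With 18 territories and a decline of 0.5
reproducing territories per season, the expected count has slope
exactly -0.5/year; binomial noise in the realized counts leaves a
slope standard error near 0.12, so a recovered posterior mean within
0.2 of the truth is an informative check.

## Problem sizes in the shipped studies

The package's simulation studies run at reduced scale, chosen as the
smallest designs that still separate signal from Monte-Carlo noise:
hyper-mean coverage uses 20 replicates of 20 territories x 10 seasons
with 2 chains x 4,000 iterations; trend recovery uses 18 territories x
15 seasons; predictive calibration uses 10 replicates of 20
territories x 8 seasons. At these sizes individual-parameter R-hats
can sit above 1.1 — the coverage and calibration results are the
operative evidence there. Full-scale analyses should use the default
`mcmc_config()`.

## Known limitations

* Single-block fits only; cross-block hierarchies (sharing hyper-priors
  across blocks) are not implemented, matching the fully block-specific
  parameterization.
* No covariates on transitions or initial states, by design; detection
  covariates are limited to the quadratic date term.
* The sampler is serial; chains are short-memory but not parallelized.
* Closure within seasons is assumed, not tested; formal closure tests
  for dynamic multistate models remain an open methods problem.
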