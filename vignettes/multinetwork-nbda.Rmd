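---
title: "Multi-network diffusion analysis: model, assumptions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-network diffusion analysis: model, assumptions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mnbda)
```

## The question the model answers

When a novel resource (a new food patch, a feeder, a technique) appears
in an animal community, individuals can discover it on their own or be
led to it by knowledgeable associates. Network-based diffusion analysis
(NBDA) separates these two channels by asking whether the *order and
timing* of discoveries tracks a social network: if individuals acquire
faster when their associates are already informed, the network carries
information. `mnbda` implements the continuous time-of-acquisition
variant (often called continuous TADA), extended so that **several
network layers act simultaneously**, each with its own transmission
rate. The motivating design is a mixed-species community in which the
association network is split into a conspecific layer and a
heterospecific layer: separate rates `s_intra` and `s_inter` then
measure whether information also crosses species boundaries, a question
a single pooled network cannot answer.

## The hazard model

Each individual `i` that is still naive at time `t` acquires at rate

```
lambda_i(t) = lambda0(t) * ( sum_k s_k * sum_j a[i,j,k] z_j(t) T[i,j]  +  A_i )   (additive)
lambda_i(t) = lambda0(t) * A_i * ( sum_k s_k * sum_j a[i,j,k] z_j(t) T[i,j] + 1 ) (multiplicative)
```

* `lambda0(t)` is the asocial (baseline) discovery rate: constant
  (`lambda0`) or a Weibull hazard `lambda0 * kappa * t^(kappa-1)` that
  lets discoverability rise (`kappa > 1`) or fall (`kappa < 1`) over a
  trial. The constant baseline is the `kappa = 1` member of the same
  family, and the two code paths are identical by construction.
* `a[i,j,k]` is the association strength between `i` and `j` in layer
  `k` (a simple ratio index in the intended workflow, so `s_k` reads as
  the transmission rate *per unit of time spent in association*,
  relative to the baseline rate).
* `z_j(t)` is the informed state of `j`; once `i` is informed its own
  rate is zero.
* `T[i,j]` is the tie mask: pairs whose discoveries fall within the tie
  window (default 600 s) are treated as one travelling group making a
  joint discovery, and their mutual social terms are removed. Ties are
  pairwise, not chained, and tied individuals keep their recorded
  arrival times in the event and survival terms — only the social
  credit between them is withdrawn.
* `A_i = exp(sum_v beta_v V[v,i])` carries individual-level variables
  (species, site, residency). The exponential link keeps rates positive
  and makes effects interpretable as rate ratios ("species X is 5 times
  faster to discover asocially"). In the additive form covariates scale
  only the asocial channel; in the multiplicative form they scale the
  whole rate. Numeric covariates are standardised by default (the scale
  of a raw observation count would otherwise push its coefficient to
  tiny, poorly conditioned values); categorical covariates are
  treatment-coded against their first level.

A note on limits that the implementation makes explicit: because the
social term multiplies `lambda0(t)`, the parameter `s` is *relative* —
"transmission is `s` times the asocial rate per unit connection". A
"pure transmission" regime therefore means tiny `lambda0` with very
large `s`, never `lambda0 = 0`, which switches off both channels.

## Likelihood

Within one trial, arrivals partition time into segments on which every
rate is constant (the informed set only changes at arrivals; the
Weibull time factor integrates in closed form). The log-likelihood is

```
sum over events e:  log lambda_acquirer(t_e)      [state = arrivals strictly before t_e]
- sum over individuals i:  integral_0^min(t_i, t_end) lambda_i(u) du
```

with censored individuals contributing only the survival integral up to
the horizon `t_end` (3 days by default, the trial length of the
motivating experiment). Using the left limit of the informed state at
event times avoids self-excitation at coincident timestamps; genuinely
near-simultaneous discoveries are the tie mask's job. Seeded
demonstrators (individuals informed before the trial starts) are an
initial condition: they transmit from `t = 0` but contribute neither an
event term nor exposure. Several trials add their log-likelihoods;
transmission rates and covariate effects are shared across trials while
each trial uses the network stack of its site.

The closed-form evaluation is validated against adaptive quadrature of
the very same hazard function (`acquisition_rate()` integrated
piecewise, an independent code path) on randomly generated instances;
the test suite and the acceptance script both assert agreement to
better than `1e-6`, and observed discrepancies are at the `1e-13`
level.

## Candidate models and inference

The six transmission hypotheses — different per-layer rates, a shared
rate, one layer only (each), homogeneous transmission on an all-ones
network, and no transmission — crossed with additive/multiplicative
covariate entry and constant/Weibull baselines form the candidate set
(`nbda_model_set()`). Fits maximise the likelihood with seeded
multi-start L-BFGS-B on log-transformed positive parameters (5 starts
by default; the first start sits at the events-per-exposure heuristic,
the rest jitter it). Model comparison uses AICc with `n` set to the
total number of discovery events, which are the information units of an
arrival-time likelihood; the package documents this choice in the fit
object rather than hiding it, because with events rather than
individuals as `n` the small-sample correction is conservative. Akaike
weights are computed with the usual max-shift, summed per hypothesis,
and model-averaged estimates are reported in both the conditional
(renormalised over models containing the parameter) and the full
(absent = 0) conventions, since the literature uses both.

Confidence intervals use the profile likelihood: a parameter value is
inside the 95% interval when re-maximising all other parameters leaves
the log-likelihood within `qchisq(0.95, 1)/2 = 1.9207` of the maximum.
The difference of two transmission rates (`s_intra - s_inter`) is
profiled by reparameterising `s_a = s_b + d` and profiling `d`, with
the non-negativity of both rates enforced inside the nuisance
optimisation. Lower bounds that run into the domain boundary `s = 0`
are reported as 0 with a boundary flag rather than extrapolated, and a
profile that never crosses the threshold inside the expanding search
bracket is flagged open instead of silently truncated.

The social/asocial decomposition (`percent_social()`) evaluates, at
each event, the share of the acquirer's fitted rate contributed by each
network layer (the baseline cancels). Its mean over events estimates
the fraction of discoveries that were socially transmitted, reported
overall, per layer and per acquirer species. The first discoverer of a
trial has no informed associates, so its event is asocial by
construction — the decomposition can never reach 100% in an unseeded
diffusion.

## The generator and what passing tests mean

`simulate_diffusions()` draws from the exact hazard model by analytic
inversion of the cumulative hazard between state changes (no thinning,
valid for both baselines), so simulation and likelihood describe the
same process by construction. `simulate_network_stack()` provides
species-structured two-layer networks (Beta(1.5, 8) edge weights, mean
about 0.16, the scale of field simple ratio indices; within-species
edge probability 0.4, between-species 0.3; species proportions 0.65 /
0.30 / 0.05 echoing a tit community dominated by one species), and
`simulate_observation_stream()` produces co-observation streams with a
species-assortment knob and *known* dyadic co-membership probabilities
so the SRI estimator can be checked against its target.

The reference validation setting (`study_conditions()`) is 30
individuals, 8 three-day diffusions, `s_intra = 22.2`,
`s_inter = 12.5`, and `lambda0 = 6e-7`/s — the asocial rate was
calibrated once, by simulation, so that roughly 60% of individuals
discover within a trial, and then frozen. Under these conditions the
MLEs are unbiased to within a few percent when averaged over
replicates, and 95% profile intervals cover the truth in at least 8 of
10 replicates; a single replicate's estimate still carries 20–30%
sampling noise, which is the honest precision of ~150 events. The
generator does not emulate several features of real data — observation
error in the networks, temporal drift in associations, heterogeneous
per-individual detectability, or tie-like co-arrivals induced by actual
group travel — so passing recovery tests demonstrates correctness of
the inference machinery under the model, not robustness to model
violation.

The tie mask is deliberately *not* part of the generator (ties are an
analyst's correction for co-discovery, not a mechanism), so
recovery-style validation fits with `use_ties = FALSE`; on real data
the mask defaults on, and refitting without it measures how much
estimated social transmission rides on near-simultaneous arrivals.

## Numerical choices and edge cases

* Positive parameters are optimised on the log scale inside a ±30 box
  (about `1e-13`–`1e13`), leaving the `s -> 0` boundary reachable to
  optimiser precision; the convergence flag requires a clean optimiser
  status plus a small central-difference gradient, with coordinates
  pinned at the box exempt.
* A dyad never observed in the same sampling block has SRI denominator
  counted over blocks where at least one was seen; a dyad with an empty
  denominator gets weight 0, never `NaN`. Simultaneous presence at
  different locations (both observed, different gathering events in one
  block) counts in the denominator, as the simple ratio index requires.
* Degree assortativity of a graph with zero degree variance (e.g. a
  complete graph) is flagged `undefined` rather than propagating `NaN`;
  both binary-degree and strength-weighted variants are exposed because
  field reports rarely state which convention they used, and the mean
  weighted degree is reported both raw and normalised by `n - 1`.
* AICc requires `n - k - 1 > 0`; fits on degenerate data report the
  failure in a warning and carry `NA` rather than a misleading number.
* All times are seconds; defaults (15 s observation blocks, 600 s tie
  window, 0.95 confidence level, 3-day horizon) live in one table,
  `mnbda_defaults()`.

## Known limitations

Order-of-acquisition (OADA) likelihoods, time-varying networks, random
effects across trials, and Bayesian fitting are out of scope. The
Weibull family is one concrete choice of monotone non-constant
baseline; analyses that need a bathtub-shaped or seasonal baseline
would have to extend it. Profile intervals are conditional on one model
(canonically the best model containing the parameter); they do not
propagate model-selection uncertainty, which is what the reported
Akaike weights and model averages are for.
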