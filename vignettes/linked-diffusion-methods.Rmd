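---
title: "Linked acquisition and production: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linked acquisition and production: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cultdiff)
```

## The model

`cultdiff` simulates the spread of a novel behaviour "b" through a
population of `N` agents holding an established behaviour "a", on a static,
unweighted association network. Two sub-models are linked through the
production record.

**Acquisition.** Each timestep, a naive agent `i` (repertoire `{a}`)
acquires knowledge of "b" with probability

$$P_i(t) = 1 - \exp\{-\lambda_b (T_i(t) + A)\}, \qquad
T_i(t) = s \sum_j a_{ij}\, w_j(t),$$

where `a_ij` is the adjacency indicator, `A` switches asocial innovation on
or off, and the transmission weight `w_j(t)` is the proportion of the last
`m` timesteps in which neighbour `j` produced "b". Transmission therefore
depends on what neighbours *do*, not merely on what they *know* — this is
the link between the sub-models.

**Production.** Every agent produces exactly one behaviour per timestep.
For each behaviour `k` in its repertoire the agent tracks an expected value
updated as `E_k(t) = ρ r_k(t-1) + (1-ρ) E_k(t-1)` with `r_k = 1` only if
`k` was produced in the previous step, so unused behaviours decay towards 0
and values never exceed the unit reward. Values map to choice probabilities
through a softmax at temperature `α`, are mixed with a frequency-dependent
social term built from neighbour productions in the same `m`-step window
raised to the exponent `f`, and the mixture weight is the social
information bias `σ`:

$$P_{i,k}(t) = (1-\sigma)\,\mathrm{softmax}_\alpha(E_{i,k})
  + \sigma\,\frac{c_{i,k}^f}{\sum_{k'} c_{i,k'}^f}.$$

Agents only "see" neighbour productions of behaviours already in their own
repertoire, and a newly acquired behaviour starts at `E_b = 0`: its value
must be learned through the agent's own productions. This is what makes the
order of first productions diverge from the order of acquisitions.

## Parameters and defaults

| parameter | meaning | default | tested values |
|---|---|---|---|
| `sigma` | social vs individual information in choice | 0.5 | 0.25 / 0.5 / 0.75 |
| `f` | frequency-dependence of the social term | 1 | 0.33 / 1 / 3 |
| `m` | memory window (timesteps) | 10 | 10 / 20 / 30 |
| `rho` | weight of the most recent reward | 0.1 | 0.01 / 0.1 / 0.99 |
| `alpha` | softmax temperature (risk appetite) | 1 | 0.5 / 1 / 2 |
| `lambda_b` | baseline learning rate per step | 0.05 | fixed |
| `s` | social transmission rate | 5 | fixed |
| `A` | asocial innovation flag | 0 | 0/1 by design |
| `N`, `k` | population size, network degree | 24, 6 | fixed |

`reference_constellation()` returns these defaults; `table1_grid()` the
full 3^5 factorial over the production parameters. Populations sit on
connected random regular graphs (`generate_random_regular()`), which
standardize degree so that acquisition opportunities are identical across
agents; ring lattices are provided as the longer-pathed alternative.

## Conventions and numerical choices

Several conventions are under-determined by the model statement alone; the
package fixes them as follows and exposes switches where both readings are
defensible.

* **Memory window.** The window at timestep `t` covers the last `m`
  *completed* timesteps `t-m, …, t-1`: a decision made at `t` cannot
  condition on productions that have not happened yet. The transmission
  weight divisor is always `m`. `window_mode = "m_plus_1"` gives the
  literal `m+1`-index reading of the window sum.
* **Within-timestep ordering.** Productions are drawn first; the
  acquisition sweep follows, so an agent acquiring at `t` first produces
  "b" at `t+1` or later. The alternative (`acquire_first = TRUE`) lets a
  newly knowledgeable agent produce in the same step, which mechanically
  shortens acquisition-to-production delays by about a timestep and is
  inconsistent with the published delay summaries that the sequential
  ordering reproduces.
* **Seeding.** One uniformly random agent knows "b" from the start with
  `E_b = 0` and time of acquisition 0, so it is always rank 1 in the
  acquisition order. Its first production is stochastic like any other.
* **Ties.** Agents acquiring in the same timestep receive distinct ranks
  uniformly at random (seeded). For event-time analyses the discrete times
  are jittered uniformly within their timestep, preserving the tie-broken
  order.
* **Degenerate social counts.** If every in-repertoire neighbour count in
  the window is zero the social term is the uniform distribution over the
  repertoire (the `0/0` case of the normalization); `0^f` is taken as 0
  otherwise. Singleton repertoires give the degenerate distribution on "a".
* **Stalled runs.** With `A = 0` and `s = 0` a diffusion cannot complete;
  runs hit a hard cap (default 10,000 steps) and return a flagged record
  rather than an error.

## Diffusion statistics

From each completed run the package records times and ranks of acquisition
and of first production, and derives: time-to-diffusion (TTD) and
time-to-first-production (TTFP); the order divergence
`d_order = Σ|o_a - o_p| / (N-1)` (the seed's term is 0 by construction);
the mean absolute delay `d_time = mean(|t_a - t_p|)`; and the fraction of
agents whose two ranks differ. Batches report means, standard errors and
92% percentile intervals (linear-interpolation quantiles, type 7). Rank
R² values are computed on agent-level pairs pooled across all replicates of
a constellation, matching how the corresponding density plots pool agents;
per-run R² would carry the same information but a different sampling
distribution.

## Time-of-acquisition inference (TADAc)

The inferential hazard for naive agent `i` is
`λ_i(t) = λ0 (s Σ_j a_ij w_j z_j(t) + 1)`, with `z_j` the knowledge
indicator and `w_j` either 1 (ideal data) or the agent's static production
rate of "b" (realistic data). The additive baseline makes the asocial model
(`s = 0`) properly nested. Two likelihood forms are implemented:

* `form = "event"` — the textbook continuous formulation: knowledge states
  change at each jittered event time, intervals contribute
  survival-times-hazard terms. It is oracle-tested against a brute-force
  hazard product on a three-agent toy network.
* `form = "step"` (default) — exposures are evaluated per unit timestep
  with knowledge updating at step boundaries, and events contribute
  `log(1 - e^{-λ_i})`. This is the exact likelihood of the discrete-time
  generative process and the natural treatment of tied integer event
  times; it is what an NBDA analysis effectively sees when handed
  timestep-valued data. The two forms agree in sign patterns, but the
  event form dilutes the social signal whenever several events share a
  timestep — the jitter spreads tied events over the step, so part of each
  step's exposure is attributed to agents not yet active — which makes its
  ΔAICc medians on ideal data noticeably smaller than the step form's.

Fitting is by maximum likelihood. Under the event form `λ0` is profiled
out analytically, leaving a one-dimensional bounded search in `log10(s)`;
under the step form the asocial model has a closed-form per-step Bernoulli
MLE and the social model is maximized by bounded quasi-Newton from three
starts, with the `s = 0` boundary always evaluated so the nested ordering
of likelihoods is guaranteed. Model support is `ΔAICc = AICc_asocial −
AICc_social`, positive values supporting social transmission, with the
small-sample AICc correction using the number of events among initially
naive agents (23 when the seed is a demonstrator, 24 in asocial designs).

## Production-rule inference (EWA fitting)

`fit_ewa()` estimates `(ρ, σ)` — with `f`, `α`, `m` held at reference —
from a production history by rebuilding every agent's choice probabilities
deterministically from the data, exactly as the generative engine computes
them (`ewa_replay_probs()` reproduces the engine's probabilities to
machine precision, which is the core correctness oracle linking inference
to generation). Priors are uniform(0, 1). The sampler is an adaptive
random-walk Metropolis on the logit scale: any sampler meeting the
draw-count and convergence contract is acceptable for this posterior,
which is two-dimensional and well behaved; chains are checked with split
R-hat (≤ 1.01 typical, > 1.05 flagged) and ACF-based effective sample
sizes. Defaults mirror the study scale (5 chains × 4000 iterations, 1000
warmup).

The likelihood has two repertoire modes. `"realized"` honours each agent's
true knowledge state — the generative model's own likelihood.
`"full"` assumes every agent knew both behaviours throughout, which is the
assumption conventional homogeneous-repertoire analyses make;
`run_scenarios()` uses it for the heterogeneous-repertoire designs
(scenarios 2 and 3) precisely because that mismatch, not sampler error, is
what drives the documented overestimation of `σ`: agents that only produce
the established behaviour because they know nothing else look strongly
socially influenced. Scenario 1 initializes all agents with
`E_a = E_b = 1` (a stationary, symmetric start for the no-diffusion
design) and records 300 timesteps; scenarios 2 and 3 record each run for
twice its TTD, balancing observations during and after diffusion.

## What the generator does and does not emulate

The synthetic runs reproduce the study conditions: fixed population size
24, degree-6 random regular networks with unit edge weights, equal unit
rewards, one seeded knowledgeable agent (or none, under pure innovation
designs), and the parameter grids above. They do not emulate features of
real animal data — weighted or dynamic association, population turnover,
multiple competing novel behaviours, observation error in who saw whom, or
rewards that change with proficiency. Passing tests therefore demonstrate
internal consistency of the linked model and the behaviour of the
inferential methods *on data generated by this model*, not the methods'
performance on field data.

## Problem sizes

The package's own test and replication scale: 100-replicate batches for
the reference, maximal-divergence and one-at-a-time sensitivity
conditions; the full 243-constellation grid at 10 replicates (2430
datasets) for each model-comparison battery; and 3 replicates per cell for
the Bayesian recovery scenarios with 2 chains × 1000 iterations, which is
sufficient for the coverage/bias properties those checks assert. The
full-scale sampler defaults remain available through the function
arguments.

## Known limitations

* The TADAc step likelihood treats the recording as complete (no
  right-censoring); all simulated diffusions run to completion, so the
  restriction binds only if the engine's step cap is hit.
* `s` estimates trade off against `λ0` (flat profile ridges for weakly
  informative diffusions); medians over batches are stable but individual
  `s_hat` values can be large when a diffusion is nearly deterministic.
* The Metropolis sampler is adequate for the two-parameter posterior but
  would need replacement for extensions estimating `f`, `α` or `m`
  jointly.
* Metrics assume completed diffusions; records returned by the
  `twice_ttd` stopping rule can contain agents that never produced "b",
  for which rank-based statistics are undefined and left `NA`.
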