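# cultdiff

Agent-based simulation and inference for cultural diffusions in which
*acquiring* a behaviour and *producing* it are distinct, linked processes.

## The problem

Studies of animal and human culture use two families of inferential models
that talk past each other. Network-based diffusion analysis (NBDA) asks
whether a behaviour spread through social transmission, assuming that the
order in which individuals are first *seen* producing it equals the order
in which they *learned* it. Experience-weighted attraction (EWA) models ask
how individuals weigh personal and social information when choosing among
behaviours, assuming everyone already knows every behaviour. Real
diffusions violate both assumptions at once: an individual learns that a
behaviour exists (acquisition, through its associates' productions) and
only later, through reinforcement learning, comes to produce it often
(production). `cultdiff` implements a generative model that links the two,
the statistics that quantify their divergence, and both inferential
methods, so that the methods can be evaluated on data whose true generating
mechanism is known.

It is intended for researchers in cultural evolution and social-learning
statistics who want to simulate linked diffusions, stress-test NBDA/EWA
style analyses, or reuse the components (networks, reinforcement-learning
production rules, hazard-model fitting, posterior sampling) in their own
designs.

## The model in brief

`N = 24` agents sit on a connected random regular network (degree
`k = 6`, unit edge weights). All know behaviour `a`; one random seed agent
knows the novel behaviour `b`. Each timestep:

1. **Production** — each agent produces one behaviour from its repertoire
   with probability
   `P_i,k = (1-σ)·softmax_α(E_i,k) + σ·c_i,k^f / Σ c^f`, where `E` are
   reward-learned expected values (`E_k(t) = ρ r_k(t-1) + (1-ρ)E_k(t-1)`)
   and `c_i,k` counts productions of `k` by network neighbours in the last
   `m` timesteps.
2. **Acquisition** — each naive agent acquires `b` with probability
   `1 - exp(-λ_b(T_i + A))`, `T_i = s·Σ_j a_ij w_j`, where `w_j` is the
   proportion of the last `m` timesteps in which neighbour `j` produced
   `b`.

A newly knowledgeable agent starts at `E_b = 0`, so production lags
acquisition — the lag and the resulting rank divergence are the model's
central quantities. On top of the simulator the package provides
time-of-acquisition diffusion analysis (TADAc: social vs asocial hazard
models compared by AICc) and Bayesian estimation of `(ρ, σ)` from
production time series.

## Worked example

```r
library(cultdiff)

net <- generate_random_regular(24, 6, rng_seed = 7)
net
#> <social_network> 24 agents, architecture 'random_regular', degree 6, 72 edges

rec <- run_simulation(reference_constellation(), net, rng_seed = 42)
rec
#> <diffusion_record> 24 agents, 37 timesteps, TTD 36, TTFP 37

m <- diffusion_metrics(rec)
sprintf("d_order = %.2f, d_time = %.2f, divergent = %.0f%%",
        m$d_order, m$d_time, 100 * m$pct_divergent)
#> "d_order = 2.26, d_time = 3.71, divergent = 71%"
```

In this run the novel behaviour reached all 24 agents in 36 timesteps
(TTD) and had been produced by everyone one step later (TTFP). On average
an agent's first production came 3.7 timesteps after its acquisition
(`d_time`), by which point about two other agents had already acquired the
behaviour (`d_order` ≈ 2.3) — so 71% of agents produced in a different
order than they learned.

Batch summaries aggregate replicate runs, each on a fresh network:

```r
tab <- metrics_table(run_batch(reference_constellation(), reps = 100,
                               rng_seed = 1))
#> TTD  52.65 +/- 1.05  [37.92, 73.00]   (mean +/- s.e., 92% PI)
#> TTFP 58.32 +/- 1.08  [43.00, 79.04]
#> pooled R2 = 0.844, divergent agents = 74.0%
```

And the inferential layer fits hazard models to event times. Here a
diffusion generated by *asocial innovation only* is (wrongly) credited to
social transmission once production dynamics are allowed to shape the
observed first-production times:

```r
dat <- generate_realistic_data("asocial", rng_seed = 3)
cmp <- delta_aicc(fit_tadac(dat, "social"), fit_tadac(dat, "asocial"))
sprintf("dAICc = %.2f -> support %s", cmp$delta_aicc, cmp$support)
#> "dAICc = 11.17 -> support social"
```

`sensitivity_sweep()`, `nbda_battery()` and `run_scenarios()` orchestrate
the full factorial experiments; `make_report()` writes their summary
tables as CSV. See the vignette in `vignettes/` for the model's
assumptions, conventions and numerical choices.

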