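---
title: "Competing opinion diffusion: model, mean field, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Competing opinion diffusion: model, mean field, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The process

`opinionet` implements a multi-opinion voter process on a simple connected
undirected graph. Each of the `N` agents holds one opinion `i ∈ {1, …, I}`;
each degree class `k` has a fitness `f_k > 0` measuring persuasiveness. One
elementary step selects an agent uniformly at random. A committed agent does
nothing. A regular agent adopts the media opinion `m` with probability `P`,
and otherwise copies a neighbour sampled with probability proportional to the
neighbour's fitness — or, on weighted networks, to the edge weight
`w_uv = (k_u k_v)^θ`, optionally times fitness. Because the `k_u^θ` factor is
common to all of an agent's edges, weighted sampling is distributionally
identical to unweighted sampling with `f_k ∝ k^θ`; the test suite exploits
this with a coupling argument (a shared random stream must produce the
identical trajectory) in addition to an independent-stream ensemble
comparison.

Time is reported in units of one expected sweep of regular-agent updates:
`N` elementary selections when no one is committed, `N/(1−s)` selections when
a fraction `s` is committed (committed selections are no-ops, so either way a
unit is ≈ `N` regular updates).

## The conserved weighted fraction

The central quantity is the degree-and-fitness-weighted share

$$q_i^f \;=\; \frac{\sum_{v:\,\text{op}(v)=i} k_v f_{k_v}}{\sum_v k_v f_{k_v}}.$$

On degree-uncorrelated networks, a heterogeneous mean-field closure of the
per-class gain/loss rates gives `dq_{i,k}/dt = q_i^f − q_{i,k}`, from which
`q_i^f` is conserved and equals opinion `i`'s fixation probability. For
*constant* fitness this conservation is exact on any graph (the
degree-weighted share is a martingale of the death–birth update), which is
why the suite can check fixation frequencies against exact
`2^n`-state Markov-chain absorption probabilities to `1e-10` on graphs of up
to 10 nodes. For non-constant fitness the statement is mean-field-accurate
only; the corresponding tests carry statistical rather than exact tolerances.
With `f_k ∝ 1/k` the weighting cancels and `q_i^f = q_i` exactly.

## Committed agents and media

With committed fractions `s_i` (weighted `s_i^f`), only committed-backed
opinions survive, amplified by the network:
`q_i^f(∞) = s_i^f / \sum_j s_j^f` and
`q_i(∞) = s_i + (1−s)\, s_i^f/\sum_j s_j^f`. With an active media field the
fixed points generalize to

$$q_i(\infty) = s_i + (1-s)\frac{(1-P)s_i^f}{D}, \qquad
  q_m(\infty) = s_m + (1-s)\frac{(1-P)s_m^f}{D}
  + (1-s)\Big[P + \frac{(1-P)P(1-\sum_j s_j^f)}{D}\Big],$$

with `D = P + (1−P)\sum_j s_j^f`. The media opinion's share therefore
decomposes into four non-negative parts — committed core, network
amplification, direct broadcast, and broadcast relayed through social ties —
returned by `media_decomposition()`. `critical_media_strength()` bisects
`g(P) = q_m(∞) − q_\text{rival}(∞)` (monotone in `P`) to an interval and
residual of `1e-9`; the hand-solvable case `s_1 = s_2 = 0.2`,
`s_1^f = 0.5`, `s_2^f = 0.1` has the closed root `P* = 2/7`, frozen in the
tests as an independent oracle.

All formulas are evaluated on the *realized* network via node sums rather
than an idealized degree distribution. This is deliberate: quantities such as
`P*` depend on the realized hub degrees (the committed weighted fraction of a
hub-backed opinion varies a few percent between network draws), and only the
realized evaluation makes them reproducible from a seed.

## The degree-class mean field

`degree_class_tables()` projects a realized population onto
`(p_k, q_{i,k}, s_{i,k}, f_k)`. The ODE right-hand side is assembled from the
per-class gain/loss rates by `(gain − loss)/p_k` in all three regimes (pure,
committed, media). The media-regime ODE's fixed points are derived by noting
that the gain and loss coefficients sum to one, so

$$q_{i,k}(\infty) = \big(1-\textstyle\sum_j s_{j,k}\big)\,A_i + s_{i,k},$$

with network pull `A_i = (1−P)q_i^f(∞)` for `i ≠ m` and
`A_m = (1−P)q_m^f(∞) + P`; aggregating over classes reproduces the
population-level closed forms exactly, and `meanfield_steady_state()` is
tested to agree with the realized-network analytics to `1e-12`.

Two clock conventions exist: the printed per-class rates advance one time
unit per `N` elementary selections, while the simulator records one unit per
`N/(1−s)` selections (≈ `N` regular updates). `meanfield_rhs()` returns the
printed form; `integrate_meanfield()` multiplies it by `1/(1−s)` so that
deterministic trajectories overlay directly on simulated ensembles. Without
this conversion, committed-agent scenarios would appear to relax `1/(1−s)`
times slower in the ODE than in simulation.

Integration uses fixed-step RK4 (`deSolve`); the no-committed regime has the
analytic solution `q_{i,k}(t) = q_i^f + (q_{i,k}(0) − q_i^f)e^{−t}`, which
the integrator matches to `1e-6` at step `0.01`. Convergence to the
committed/media fixed points is geometric at rate
`≈ (P + (1−P)\sum_j s_j^f)/(1−s)`; the tests integrate to `t = 80` so that
even weakly committed random scenarios are within `1e-6` of the fixed point.
Class fractions are monitored to remain in `[0, 1]`; a violation aborts with
a step-size error.

## Networks and population construction

* **BA generator**: seed clique `K_{m+1}`, then each new node attaches to
  `m` distinct existing nodes sampled degree-proportionally without
  replacement (via an edge-endpoint list). The reference for this choice is
  that it drives the mean degree to `2m`, matching the study scenarios'
  mean degree 6 with `m = 3`, and produces near-zero degree assortativity at
  the sizes used (checked in `[−0.05, 0.05]` at `N = 10^4`), supporting the
  degree-uncorrelated closure.
* **Hubs**: `top_degree_nodes()` ranks by degree descending with ascending
  node id as the deterministic tie-break, so hub-committed allocations are
  reproducible.
* **Committed designation**: per opinion, the requested number of hubs is
  committed first (skipping nodes already committed to an earlier opinion,
  next-ranked node takes the place), then uniformly random free nodes fill
  to `round(s_i N)` — uniform filling is an assumption; sub-node remainders
  are dropped. Committed counts use `round`, so exact counts at the shipped
  scales.
* **Uniform(0,1) fitness** is drawn once per *degree class*, not per node,
  matching the degree-indexed notation `f_k` throughout the theory; zero
  draws are redrawn. Per-node heterogeneity can be emulated through the
  `table` fitness kind but is not used by the shipped scenarios.

## Randomness and reproducibility

Every scenario carries one master seed. Realization (network, fitness draw,
initial opinions, committed fill) consumes seeds derived deterministically
from it; each ensemble member gets its own derived dynamical seed, so
ensembles are reproducible and embarrassingly parallel, and all members share
the identical initial condition — ensemble standard deviations at `t = 0` are
exactly zero. The compiled kernel draws from R's RNG, so everything is
controlled by `set.seed` semantics.

## What the shipped scenarios emulate — and what they do not

The twelve `study_scenario()` setups use `N = 10^4`, mean degree 6, `I = 5`
opinions, random initial assignment, and the hub/committed/media
configurations described in their documentation. The `scale` option shrinks
`N` and the hub count proportionally while keeping all fractions; the
package's own validation runs at scale 0.2 (`N = 2000`, 20 hubs, ensembles
of 100, horizons of 100 units with the last 10 units averaged as the
steady-state estimate, chosen because relaxation is geometric with rate
≥ `Σ_j s_j^f/(1−s)` ≈ 0.9 per unit in those scenarios) and at full size for
the critical-strength calculations, which are cheap closed-form evaluations.

Synthetic BA networks are degree-uncorrelated and unclustered; real social
networks have assortativity, community structure, and degree–fitness
correlations beyond the degree-based models used here. Passing tests
demonstrate internal consistency of simulator and theory under the model's
assumptions, not the model's fidelity to any empirical social system.
Known limitations: the mean-field agreement degrades for strongly
degree-weighted sampling (large `θ` or fitness exponents), finite-size
deviations of order 0.01–0.02 are visible at `N = 2000` in hub-committed
scenarios with `f_k ∝ k^{0.5}`, and no degree-correlated closure is
provided.
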