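---
title: "Modelling transient explosive synchronization with resource-constrained adaptive coupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling transient explosive synchronization with resource-constrained adaptive coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(tesync)
```

## The model

`tesync` simulates a network of `N` Kuramoto phase oscillators in which
the coupling gain of every node is modulated by two slow, biologically
motivated variables: its *local synchrony* and its *excitability
resource*.  The phase of node $i$ evolves as

$$\dot\theta_i = \omega_i + \lambda_i \, r_i \sum_j W_{ij}
  \sin(\theta_j - \theta_i),$$

where $\omega_i \sim \mathrm{Uniform}[-1, 1]$ is the natural frequency,
$W_{ij}$ the weight of the edge $j \to i$, and

$$r_i = \frac{1}{s_i}\Big|\sum_j W_{ij} e^{i\theta_j}\Big|,
  \qquad s_i = \sum_j W_{ij}$$

the coherence of node $i$'s inputs (on binary graphs $s_i$ is the
in-degree).  Coupling *adaptively* strengthens where the neighbourhood
is already coherent — a population-level abstraction of
synchrony-dependent plasticity.  This positive feedback is what turns
the usual second-order Kuramoto transition into an *explosive*
(first-order, hysteretic) one on dense networks.

The resource $\lambda_i$ models a local energy pool (ATP-like) that
synchrony consumes:

$$\dot\lambda_i = \alpha\,(\lambda_o - \lambda_i) - \beta\, r_i .$$

Resources recover toward the bath capacity $\lambda_o$ at rate $\alpha$
and are consumed at rate $\beta r_i$ ($\beta$ is the maximal
consumption rate, reached when the neighbourhood is fully coherent).
With the resource frozen at a fixed value $\Lambda$ (the
*fixed-resource mode*, `model_params(fixed_lambda = )`) the model shows
a hysteresis loop in $\Lambda$; letting $\lambda_i$ evolve couples the
fast phase dynamics to a slow resource relaxation that drags the
network back and forth across that loop.  The result is *transient
explosive synchronization* (tES): recurring, self-initiating and
self-terminating epochs of near-global phase locking — the package's
abstraction of generalized seizure dynamics.  Network state is
summarised by the global order parameter
$R = |\tfrac{1}{N}\sum_i e^{i\theta_i}|$.

Macroscopically the cycle is: resources accumulate while the network is
incoherent; when the mean resource level crosses the forward tipping
point, the network jumps to the coherent branch; consumption then
outpaces recovery, the mean resource falls below the backward tipping
point, and the network collapses back to incoherence.

## Parameters, units and defaults

Time is in model time units; rates are per time unit.

| parameter | meaning | default |
|---|---|---|
| `alpha` | resource recovery rate | 0.01 |
| `beta` | maximal consumption rate | 0.002 |
| `lambda_o` | resource-bath capacity (dimensionless resource units) | — |
| `fixed_lambda` | frozen resource level $\Lambda$ (fixed mode) | — |
| `dt` | Euler step | 0.05 |
| `omega_range` | natural-frequency interval | $[-1, 1]$ |

The defaults are the study conditions used throughout the tests: a
recovery-to-consumption ratio $\alpha/\beta = 5$ places the small-world
network's bistable window at $\lambda_o \approx 0.1$–$0.21$.
Integration is explicit Euler with `dt = 0.05`; both the phase and
resource updates use the same pre-step state and phases are wrapped to
$[0, 2\pi)$ (wrapping leaves the $\sin$ differences untouched).  No
higher-order integrator is provided: the dynamics are non-stiff at
these rates, and the explicit scheme keeps bit-exact reproducibility
trivial.

Numerical edge cases are handled conservatively: $r_i$ is clamped to
$[0, 1]$ against rounding overshoot; isolated nodes get $r_i = 0$
(the definition is otherwise $0/0$) and therefore neither couple nor
consume; $\lambda_i$ is *not* floored at zero — the equation is
integrated literally, whose synchronized-state fixed point is
$\lambda_o - \beta/\alpha$ — and a trajectory that starts at or below
$\lambda_o$ can never exceed it, since $\dot\lambda \le 0$ at
$\lambda = \lambda_o$.

### Weighted directed networks

On weighted directed graphs (the connectome case) the package uses the
incoming-edge convention: `W[i, j]` multiplies the influence of source
`j` on target `i`; $r_i$ is normalised by the in-strength, so it stays
a coherence in $[0, 1]$, while the coupling sum uses the raw weights
without any degree normalisation, exactly as the binary equations do.
This choice degenerates to the binary model when all weights are 1, and
it explains why the fixed-resource tipping scale of a weighted
connectome (in-strengths of order one) sits far above the binary
small-world scale (in-degrees of order 40).

## Sweep protocols

**Hysteresis (`hysteresis_sweep`)** follows the fixed-resource protocol:
$\Lambda$ is stepped over a grid ($\Delta\Lambda = 0.003$ by default)
and the oscillator state is carried from each dwell to the next — the
warm start is what makes the sweep adiabatic.  The stationary order of
a dwell is the mean of $R$ over its last 25% (the dwell length is
stated, an averaging window is not; a tail mean is robust to the
transient at each step).  Tipping points are located at the largest
supra-threshold single-step jump of the branch (default threshold
$\Delta R = 0.2$): on a coarse grid this is more robust than derivative
fitting.

**Bifurcation over $\lambda_o$ (`bifurcation_sweep`)** simulates each
bath capacity from a fresh initial state (resources start full, at
$\lambda_o$), discards the first 20% of the dwell as burn-in and
classifies the remainder from the range of $R$: *incoherent* if
$\max R < R_\mathrm{high}$, *synchronized* if $\min R > R_\mathrm{low}$,
*bistable* if both levels are visited within the dwell.  Defaults
$R_\mathrm{low} = 0.2$, $R_\mathrm{high} = 0.5$ separate the incoherent
level ($R \sim N^{-1/2}$) from the coherent branch ($R \approx 1$ on
the small-world network); both are explicit knobs because a partially
synchronizing connectome plateaus lower (use $R_\mathrm{high} = 0.45$
for such graphs).  Note the deliberate distinction: *bistability* means
both states visited within one dwell at fixed parameters;
*hysteresis* means branch disagreement between sweep directions.  Both
are computed and reported separately.

The per-$\lambda_o$ dwell of 500 time units (10,000 Euler steps) used
in the tests and the acceptance script is a compromise: long enough
that a bistable dwell almost surely visits both states (the tES cycle
period is a few hundred time units at these rates), short enough that a
5-seed, 30-point sweep runs in about two minutes.  With this protocol
the small-world network's boundaries land at $\lambda_o \approx
0.10$–$0.12$ (left) and $0.21$ (right), stable across seeds.

**Ratio analysis (`ratio_sweep`)** repeats the bifurcation sweep for a
list of consumption rates $\beta$ at fixed $\alpha$.  Because the
bistable window scales roughly like
$[\Lambda_{fw} + (\beta/\alpha) r_\mathrm{inc},\;
\Lambda_{bw} + \beta/\alpha]$, the default grid for each $\beta$ spans
$0.01$ to $0.12 + 1.3\,\beta/\alpha$ with 30 points.  As $\alpha/\beta$
grows, both boundaries fall, the window narrows, and the fraction of
time spent synchronized inside the window — summarised by
`tes_probability`, the area under the $\langle t_s\rangle(\lambda_o)$
curve normalised by the window — declines.  At the three-$\beta$ scale
used in the tests the probability trend is assessed at the endpoints
(smallest vs largest ratio) plus a rank correlation; the middle value
moves within the classification noise of the coarse default grids.

## Transients, communities and cluster tracking

**Onset extraction (`find_onset_indices`, `extract_transients`).**  A
transition event is an upward crossing of `sync_threshold` (default
0.5) by $R$; its *onset index* is the latest preceding sample with $R$
below `desync_threshold` — the near-complete desynchronization that
immediately precedes each abrupt rise.  The desynchronization level is
not stated numerically in the source material; 0.1 is the default here
(the incoherent floor of a 400-node network), and the brain-like
fixture uses 0.15 because its incoherent floor at $N = 60$ is
correspondingly higher.  Events within a refractory dead time (default
100 time units) of the previous one are skipped, and windows that would
cross the end of a run are dropped so all windows share one shape.
Each window carries 50 time units of per-node phases and local
synchrony at stride 0.2.

**Participation.**  Actively participating nodes are those whose local
synchrony averaged over the final 20% of the window (the
post-transition plateau — "during the partially synchronized state"
refers to that plateau, not to the rise) exceeds 0.7.

**Community statistics.**  Communities come from weighted Louvain at
resolution 1; directed weights are symmetrized with
$\max(w_{ij}, w_{ji})$ first, since synchrony is a symmetric relation
and no directed-modularity variant is assumed.  Intramodular synchrony
is the modulus of a community's mean phasor; intermodular synchrony of
a pair is implemented through the identity
$\mathrm{IMS}_{c_1 c_2} = |0.5 (P_{c_1} + P_{c_2})|$ with $P_c$ the
community mean phasor — the literal double sum over node pairs is kept
in the package as an oracle and the two agree to machine precision.
Trial averaging pools IMS *values* across windows (not phasors): the
statistic of interest is the typical coherence level, not a
phase-aligned average.

**SCTA.**  The synchronization cluster tracking algorithm builds, at
every evaluation time (stride 0.2, matching the window stride),
clusters by threshold-gated breadth-first expansion on the undirected
skeleton: a node can join only if its own $r_i \ge 0.5$ (the membership
criterion is the node's network-local synchrony — the only per-node
synchrony quantity the model defines), and expansion proceeds only
through joined nodes, so one sub-threshold node severs the path.
Clusters carried over from the previous instant expand first (largest
first), seeded by their central nodes — the up-to-five members with
highest $r$ — and inherit the previous cluster's id; remaining
supra-threshold nodes then seed fresh clusters in descending-$r$ order.
By construction the resulting member sets equal the connected
components of the supra-threshold induced subgraph (the test suite
asserts this against an independent component oracle); the algorithm's
value is the *identity bookkeeping* across time, which yields per-node
residence times in the largest ("main") cluster.  Tie-breaks are
arbitrary but fixed: previous clusters by descending size then
ascending id, main-cluster ties to the smallest id, id inheritance
through the highest-$r$ central node when a previous cluster's centrals
are split, first assignment wins.  Residence time accrues one
evaluation stride per membership instant (the initial instant carries
none), so it is bounded by the window length; residence variance across
windows uses the population (divide-by-$n$) convention.  Driver nodes
are those combining out-degree > 30, median residence > 35 time units
and variance < 49 — residence thresholds are in time units, the natural
reading of a 50-time-unit window.

## The synthetic connectome fixture

`make_synthetic_connectome()` builds a 60-node stand-in for a mesoscale
whole-brain network so that every stage of the pipeline is exercised
without external data: two mirrored 30-node hemispheres, three planted
modules per hemisphere (intra-module edge probability 0.5, all other
pairs 0.05), directed edges with Pareto(shape 6) weights rescaled to a
maximum of 1, and a coupling hierarchy — module weights scaled by 1,
0.75, 0.5 — emulating strongly coupled cortical-like modules down to a
weakly coupled hindbrain-like one.  These values were fixed once, by
two requirements: weighted Louvain must recover the six planted modules
(adjusted Rand $\ge 0.9$ across ten seeds; heavier tails or a steeper
gradient break the weakest module apart), and at the operating point
the weakest module must stay largely outside the synchronization
cluster.  The operating point $\lambda_o = 0.72$ sits mid-bistable for
this graph: every 2000-time-unit run produces transients, and the
plateau is only partially synchronized ($R \approx 0.5$).

What the fixture does *not* emulate: realistic in/out-degree
distributions, log-normal weight spectra spanning orders of magnitude,
distance-dependent connection probability, or anatomically meaningful
module boundaries.  Tests passing on the fixture therefore demonstrate
that the algorithms behave as specified on a modular, weighted,
directed, bilaterally mirrored graph — not that any particular brain
region drives seizures.  Quantities tied to the real connectome
(fixed-resource bistability within $\Lambda \in [2.58, 2.65]$,
modularity $Q = 0.53$, plateau $R \approx 0.6$, 52 transients at
$\lambda_o = 2.87$) are deliberately not asserted anywhere; given the
external file, `mbn_reference_checks()` recomputes each of them next to
its reference value.

## Design choices made where the design was open

* **Small-world generator.**  The classic single-endpoint
  Watts–Strogatz rewiring is implemented directly (ring lattice of even
  degree, each lattice edge rewired with probability $p$ to a uniform
  non-neighbour).  The double-endpoint variant found in some libraries
  yields a far lower clustering coefficient (0.21 vs 0.36 at
  $p = 0.232$) and is not used.  At $n = 400$, $k = 40$, $p = 0.232$
  the generator gives $L_p \approx 2.03$, $C_p \approx 0.36$: the
  clustering matches the reference values this family is meant to
  reproduce, while the path length sits about 3% above — no rewiring
  probability attains both printed values simultaneously, so the
  discrepancy is reported rather than hidden.
* **Small-world coefficient.**  $\omega = L_\mathrm{rand}/L -
  C/C_\mathrm{latt}$ with, by default, the analytic references
  $L_\mathrm{rand} = \ln n / \ln\langle k\rangle$ and $C_\mathrm{latt}
  = 3(k-2)/(4(k-1))$; this convention reproduces the reference
  $\omega \approx 0.3$ for the small-world family ($-1$ lattice-like,
  $+1$ random-like, 0 ideal small world).  Sampled references (ten
  degree-preserving rewirings plus a measured ring lattice) are
  available via `reference = "sampled"`; at density $k/n \approx 0.1$
  they give systematically larger values ($\approx 0.46$) because a
  dense rewired graph's path length is much shorter than the
  logarithmic estimate.  $\omega$ is clamped to $[-1, 1]$.
* **Scale-free generator.**  igraph's preferential-attachment growth
  from a single seed node (each new node attaches to
  $\min(m, \text{existing})$ targets), so $n = m + 1$ yields a complete
  graph; the degree-distribution exponent is fitted by least squares on
  occupied log-log bins — a deliberately simple estimator that matches
  the qualitative $\gamma \approx -2$ claim (it lands near $-1.7$);
  maximum-likelihood tail fitting is out of scope.
* **Degenerate graphs.**  Generators regenerate with an incremented
  seed (up to 20 attempts, logged) when the draw is disconnected;
  metrics on a disconnected input use the largest component, logged.
* **Dwell-length readings.**  Where a dwell is stated in "time steps"
  it is read as Euler steps (1,000 steps = 50 time units) for the
  small-world protocols and as time units where stated so for
  connectome-scale runs; both are plain arguments (`dwell`,
  `run_duration`), so either reading is reproducible.
* **Determinism.**  Every stochastic step takes an integer seed;
  sweeps derive per-grid-point seeds by fixed arithmetic from the
  master seed, and `run_experiment()` offsets stage seeds by fixed
  constants, so any configured experiment reproduces byte-identical
  numeric CSVs.

## Known limitations

* Explicit Euler at `dt = 0.05` slightly smooths the sharpest
  transitions; halving `dt` moves the measured tipping points by less
  than the grid resolution but is not the default for cost reasons.
* Bistability classification depends on the dwell length: a dwell much
  shorter than the tES cycle period misclassifies bistable points as
  monostable.  The 500-unit default is tuned to the small-world study
  conditions; slower regimes (very small $\alpha$, large graphs) need
  proportionally longer dwells.
* The boundary estimates inherit the $\lambda_o$ grid resolution
  (0.01 by default); the reported right boundary is "last bistable plus
  one grid step".
* SCTA identity inheritance is heuristic by nature; only member sets
  (not ids) are uniquely defined by the phase configuration, which is
  why the tests assert set equality against the component oracle and
  id *stability* only on constructed panels.
* Communities are detected on the time-independent structure; no
  dynamic (time-resolved) community detection is attempted.

## Reproducing the study numbers

`scripts/acceptance.R` regenerates every headline quantity from
scratch — graph metrics over ten seeds, and the bistable-region
boundaries by majority vote over five independent 30-point bifurcation
sweeps at dwell 500 — and writes them to JSON; see the README for the
command line.  The test suite (`tests/testthat/test-acceptance.R`)
asserts the same quantities at their stated tolerances, plus the
qualitative tES phenomenology on the synthetic fixture.
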