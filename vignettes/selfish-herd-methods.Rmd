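---
title: "Methods: selfish-herd dynamics by multi-agent reinforcement learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: selfish-herd dynamics by multi-agent reinforcement learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(selfherd)
```

## The model

Hamilton's selfish-herd hypothesis proposes that animal groups form because
each individual selfishly reduces its own predation risk, quantified
geometrically by the *domain of danger* (DOD): the Voronoi cell around the
individual. `selfherd` implements a multi-agent reinforcement-learning
rendering of this idea. A herd of `N` disk-shaped agents (diameter `sigma`,
the length unit) lives on an unbounded plane. Each time step, every agent

1. perceives its surroundings through a 180° vision cone split into five
   36° sectors; every visible neighbour `j` adds `sigma / |r_ij|` to the
   sector holding its bearing, and (by default) neighbours whose sight line
   passes within `sigma/2` of a nearer agent's centre are invisible;
2. feeds the resulting 5-vector into a shared *actor* network producing a
   probability distribution over four actions — move forward, turn left,
   turn right, stand still — and samples one;
3. moves: 0.25 `sigma` per non-passive action, turns following an arc of
   radius 0.8 `sigma` through 18°, all motile actions subject to
   multiplicative Gaussian noise of relative strength 20%;
4. after a global hard-disk overlap resolution, receives the reward
   `r = r_SHH(A) + r_prox(d)` with

   `r_SHH(A) = (A_max - A) / (A_max - A_min)`,

   where `A` is the agent's Voronoi cell intersected with the disk of
   cutoff radius `delta = 10 sigma` around it (`A_max = pi delta^2`,
   `A_min = pi (sigma/2)^2`), and

   `r_prox(d) = -c [1 - tanh((d - d0)/w)]`

   penalizes nearest-neighbour distances `d` below the threshold `d0`.

Training is episodic under centralized training / decentralized execution:
all agents share one actor (and one critic baseline), and the pooled
experience of the whole herd updates the shared parameters after every
episode. With `c = 0.375` the two study parameter sets are `d0 = 1.0`
(dense packing tolerated, emergent *strongly rotating group*, SRG) and
`d0 = 1.5` (looser packing, *weakly rotating group*, WRG).

## Geometry

DOD areas are computed exactly, not by sampling: each agent's cell is the
intersection of the perpendicular-bisector half-planes with a bounding box,
then intersected with the cutoff disk using circular-segment arithmetic.
This direct half-plane construction is robust for collinear and other
degenerate configurations that break Delaunay-based tessellators, and it
makes the cutoff semantics explicit: the cell is clipped by the *per-agent*
disk of radius `delta`, so an isolated agent always has `A_max = pi
delta^2` independent of the configuration — the property the reward
normalization needs. Two agents count as Voronoi neighbours only if their
shared cell edge has positive length inside both cutoff disks; formal
adjacencies beyond the cutoff are not behaviourally meaningful. All
polygon clipping uses an absolute geometric tolerance of `1e-9 sigma`.

The test suite validates every area against an independent Monte-Carlo
oracle (uniform rejection sampling in the cutoff disk, classifying each
sample to its nearest generator) at the 3-standard-error level.

## Kinematics, noise and collisions

Turning actions follow a circular arc: the displacement is the chord of a
rotation by the signed turn angle about the centre of curvature at lateral
offset 0.8 `sigma`, so twenty noise-free left turns close an exact 20-gon.
The published noise statement fixes only "20% standard deviation"; we read
it multiplicatively — translation length `x (1 + 0.2 eta)`, turn angle
`x (1 + 0.2 eta)` — and give the forward action a heading wobble of
`0.2 x 18° x eta` so that no motile action is perfectly straight.
`stand_still` is exactly passive. Up to 50% noise the collective outcomes
are qualitatively unchanged, which the suite checks as a finiteness /
overlap-free robustness property.

Overlaps are resolved by synchronous (Jacobi) projection sweeps: all
overlapping pairs are pushed apart symmetrically along their centre line to
contact distance, accumulated, applied at once, and swept until the
residual overlap falls below `1e-6 sigma` or 100 sweeps have run.
Synchronous sweeps keep the update order-independent and preserve
configuration symmetries (an isolated pair conserves its centre of mass
exactly). Non-convergence in a dense transient produces a warning and a
best-effort frame, never an error. The update is overdamped and
instantaneous — one action per agent per time step `Delta t`, no inertia,
no sub-stepping, no walls.

## Learning algorithm

The published account specifies the actor, the four-action policy, the
discounted return, and the episode schedule (episodes of 3000 steps, about
30 episodes for 100 agents); the concrete optimizer is this package's own
choice and is fully config-exposed:

* advantage actor-critic in the REINFORCE-with-baseline form: the policy
  loss is `-log pi(a|o) * (G - V(o))` with an entropy bonus (default
  weight 0.03), the critic is regressed on the discounted returns
  (default `gamma = 0.99`);
* both networks are tanh multilayer perceptrons with two 64-unit hidden
  layers on the 5-dimensional observable (softmax head over four actions);
* after each episode the pooled experience (`steps x N` samples) is
  shuffled into minibatches of 1024 and traversed for
  `epochs_per_episode = 2` passes of Adam at learning rate `3e-4`.

The update cadence matters: with many passes per episode the policy
over-fits the stale on-policy batch and collapses to a near-deterministic
policy early (entropy < 0.3 nats within two episodes), after which learning
stalls; one to two passes keep the entropy near its maximum (`log 4 ~ 1.39`
nats) through the aggregation phase. Two passes are the default as the best
stable throughput. Advantages are standardized per episode; a non-finite
loss aborts with a diagnostic rather than continuing silently.

## Emergent statistics

* `rotational_order()` — the order parameter is `|sum_i (rhat_i x
  uhat_i)|/N` over centroid-relative unit positions and headings. The
  printed per-agent-absolute variant (`form = "absolute"`) is also
  available, but note its baseline for fully random headings is `2/pi ~
  0.64`, which cannot express the reported weak-rotation values around
  0.1; the signed form is therefore the default.
* `spatial_rotation_map()` — the signed cross product averaged on a square
  grid in the centroid frame; cells with fewer than 5 visits are masked.
* `msd()` — time-averaged squared displacements per agent with optional
  per-frame centroid subtraction; saturation onset is defined as the first
  lag reaching 95% of the plateau (mean over the last decade of lags).
* `dod_acf()` — per-agent mean-removed, variance-normalized
  autocorrelation averaged over agents (the standard biased estimator);
  the correlation time is the first crossing below `1/e`, and `Inf` when
  the curve never crosses (no decay).
* `cumulative_dod()` — running time averages `Abar_i(tau)`; the
  risk-sharing convergence lag is the first `tau` beyond which every agent
  stays within 10% of the ensemble mean.
* `neighbor_persistence()` — survival fraction of the within-cutoff
  Voronoi neighbour set, `p_NN(0) = 1`; the k-nearest alternative was
  considered and rejected to stay inside the same cutoff-Voronoi framework
  as the DOD itself.

## What the synthetic fixtures do and do not show

The fixture generators (`make_fixture()`: lattice, ring, mill, gas,
two-vortex) provide configurations with *known* geometry and rotational
state: mills give order parameter exactly 1, mixed-handedness rings exactly
0, rigidly rotating mills keep every neighbour forever, independently
re-scattered gas frames decay to the chance adjacency level. They validate
the estimators, not the biology: passing them shows the statistics measure
what they claim on clean inputs, while statements about real emergent herds
rest on the trained rollouts. The fixtures contain no motor noise, no
collision response and no learned behaviour.

## Problem sizes used by the shipped checks

Desk-scale checks (the test suite) run the full property set at small
sizes: herds of 10–20 agents for training sanity (800-step episodes, five
episodes, which lifts the mean reward more than five standard errors above
the random-policy baseline), and a reduced two-regime emergence run with 50
agents and twelve 1000-step episodes per reward parameter set. At that
reduced depth the herd aggregates and rotates for both `d0` values; the
clean separation into the strongly and weakly rotating phases (order
parameters near 0.6 versus 0.1) is an outcome of the full 100-agent,
9-million-action schedule and is seed-sensitive below it, so the desk-scale
checks assert the reduced-scale phenomena and the reproduction script
reports the measured regime statistics. The
reproduction script (`scripts/acceptance.R`) trains 100-agent herds for
twelve 1200-step episodes per parameter set and analyses 2500-step frozen
rollouts; these sizes were chosen as the smallest at which the SRG/WRG
contrast is reliably resolved. The published schedule (30 x 3000-step
episodes) remains the package default configuration, so
`shh_train(shh_config())` reproduces the full-scale experiment unchanged.

## Known limitations

* The exact training hyperparameters of the original study are not public;
  the actor-critic settings here are chosen for stability and documented
  above, so quantitative emergent values (order parameters, correlation
  times) should be compared at the "same phase, same ordering, similar
  magnitude" level rather than digit by digit — they are stochastic
  outcomes of training.
* Occlusion is binary (full-disk sight blocking of the centre line);
  partially occluded neighbours contribute either fully or not at all.
* The tanh proximity-penalty width is `w = 2 sigma` by default; the
  printed form of the penalty is ambiguous between `tanh((d - d0)/2)` and
  `tanh(2(d - d0))`, and `w` is config-exposed so both readings are
  testable.
* No predators, walls, heterogeneous speeds, or 3-D geometry.
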