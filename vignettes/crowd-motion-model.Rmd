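---
title: "Modelling cooperative crowd motion with diffusion adaptation"
author: "crowdadapt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cooperative crowd motion with diffusion adaptation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crowdadapt)
```

## The model and its assumptions

`crowdadapt` simulates a crowd of `N` agents moving through a corridor
bounded by two wall curves toward a single shared target, as a
**decentralized adaptive network**: agents exchange position information
only within a one-hop neighborhood of radius `R` and coordinate through
diffusion adaptation in its adapt-then-combine (ATC) ordering. Each
combination step is a convex average over neighbors' intermediates with
weights that are non-negative, column-stochastic and zero outside the
neighborhood; convexity is what keeps the network stable.

Two estimates are diffused. The *target estimate* uses the geometric
simplification of the least-squares adaptation,
`psi_k = (1 - mu) tau_prev + mu tau_new`; because the standard scenario
fixes the target as known to every agent, this diffusion is off by default
(`tau_diffusion = FALSE`) and the general least-squares form is exposed as
`atc_adaptation_ls()` for completeness. The *center-of-gravity velocity*
estimate `v^g` is always diffused: each agent tracks an exponentially
weighted average of its own velocity (`phi_k = (1 - mu_v) v^g_k + mu_v v_k`)
and then averages its neighbors' intermediates. On a static connected
network with a shared velocity this contracts to consensus (verified to
1e-6 within 1000 iterations in the test suite).

The environment enters through the **inscribed-circle chord**: at the
agent's station, the circle tangent to both walls whose tangent-point chord
contains the agent defines the local corridor width `L`. Width regulates
speed affinely and inversely — `v^c` runs from `v_max = 3.6` m/s at
`L_min = 1` m down to `v_min = 0.6` m/s at `L_max = 10` m — so narrow
throats are cleared quickly. Speed in turn regulates the desired social
distance `r`, affinely from `r_max = 2` m (slow) down to `r_min = 1` m
(fast). Agents with disabilities walk at half the mapped speed and keep
twice the mapped distance (so `r` in [2, 4] m); the doubling is applied
after the base value is clamped to [1, 2] m, a choice we make explicit
because the ordering of clamping and doubling is otherwise ambiguous.

Each agent's velocity is the blend
`v = lambda * beta * v^a + (1 - lambda) * v^g + gamma * delta` of
individual drive, group consensus and cohesion. `v^a` points at the target
with magnitude `C = v^c` unless an obstacle's effective distance
`d_eff = ||w - p|| - alpha` falls below `R`, in which case the agent moves
directly away from the obstacle with magnitude `C (R/d_eff - 1)` — zero
exactly at the activation boundary, so the switch is continuous. The
obstacle margin `alpha` is treated isotropically (a scalar subtracted from
the distance), and the avoidance direction is `unit(w - p)`, away from the
obstacle; the sign convention is fixed by the requirement that avoidance
repels. The cohesion term is the standard spacing rule
`mean over neighbors of (||w_l - w_k|| - r) unit(w_l - w_k)`: attraction
beyond `r`, repulsion inside it.

## Geometry: walls, centerline, chords

Walls are represented as polylines resampled onto a uniform horizontal
grid (default step 0.05 m); analytic wall functions are sampled at
construction. This makes irregular measured corridors and smooth presets
uniform, and lets nearest-segment searches use index windows (a window of
half the maximum gap plus a buffer is provably sufficient, because the
nearest point's horizontal offset never exceeds the distance itself).

The centerline — the locus of centers equidistant from both walls — is
found by vectorized bisection on the difference of wall distances
(monotone in the vertical coordinate), cached per geometry at a default
resolution of 0.02 m. Each centerline sample carries its radius, tangent
points and chord. `chord_for_agent()` then selects the chord containing
the agent. Where chords cross (taper regions produce caustics), several
chords may contain the same point; we refine every candidate branch by
continuous 1-D minimization of the point-to-chord distance and keep the
*smallest* containing chord. The tie-break is deliberate: a smaller chord
means a narrower effective passage and a higher speed, and we let narrow
throats dominate local behaviour. Near the domain ends, where no full
tangent circle fits, queries clamp to the nearest valid centerline
station. Numerical tolerances: 1e-6 m for tangency and equidistance
residuals, 1e-3 m for chord solutions; chords outside [`L_min`, `L_max`]
are clamped before the speed law.

Walls are not in the obstacle list, so wall avoidance is enforced
geometrically: after each position update, any agent closer than the
clearance margin (default 0.3 m) — or outside the corridor — is projected
back to the margin along the direction from the nearest wall point toward
the centerline. This implements the "minimum predefined safe distance from
the walls" for which no force-based mechanism is specified.

## The standard scenario and the synthetic generator

`make_bottleneck_scenario()` generates the study conditions: a corridor
with a smooth (cosine-blend) taper from a wide end width down to a narrow
throat and back, a shared target near the right end, and agents placed
uniformly at random in the left entry region with pairwise spacing at
least `r_min` and wall clearance at least the margin (rejection sampling
with a capped attempt count). Defaults: 40 agents of which one — agent 5,
mirroring the reference layout — is a wheelchair user; corridor 60 m long,
10 m wide with a 2 m throat centred at x = 35 m; target at (58, 0);
200 iterations of `dt` = 1 s. The corridor dimensions, neighborhood radius
(`R` = 5 m) and noise levels (`sigma_speed` = 0.05 m/s on each velocity
component, `sigma_pos` = 0.02 m positional jitter emulating ranging error)
are this package's own choices of a realistic pedestrian setting: they are
stated here once and are not tuned. With these scales a general-public
agent crosses in roughly 100 steps while the half-speed, double-spacing
disabled agent is still approaching at iteration 200, which reproduces the
qualitative finding that people with disabilities fall behind the general
public.

The generator emulates: bounded walking speeds (0.6–3.6 m/s), the
bottleneck geometry, random start positions, and sensor-like noise. It
does **not** emulate contact forces, panic behaviour, heterogeneous
per-agent profiles beyond the two roles, counterflow, or real tracker
dropout; passing tests therefore certify the model's internal laws and
their coupling, not human behavioural realism.

## Simulation loop and numerical choices

Updates are synchronous: within an iteration every agent reads its
neighbors' previous-iteration states (neighborhoods and weights are
rebuilt from current positions each step, so the stochasticity contract on
the weights re-holds every iteration). Per iteration, per agent: chord
query → speed factor → goal/avoid velocity → social distance → cohesion →
composition → speed noise → role-specific speed cap (`v_max`, halved for
disabled agents; the blend can transiently exceed physical walking speed
otherwise) → position update with clearance projection → heading advisory;
then the network-wide velocity combination. A single seeded RNG drives
noise in fixed agent order, so identical `(scenario, config, seed)` give
bit-identical trajectories.

Agents within the arrival tolerance (0.5 m) of the target freeze: the
crowd does not collapse onto a single point, and frozen agents remain in
neighbors' neighborhoods for distance keeping. The per-agent chord lookup
inside the loop uses the cached 0.02 m centerline without continuous
refinement (error well under the chord tolerance relevant to the speed
law); the user-facing `chord_for_agent()` refines by default.

Degenerate inputs are handled explicitly: walls that touch raise an
invalid-geometry error; positions outside the corridor raise an error in
chord queries and are projected back in the simulation; coincident agents
skip their cohesion pair with a warning; a zero displacement yields an
`NA` advisory.

## Known limitations

* The all-or-nothing obstacle switch can trap an agent whose goal
  direction points straight back into the avoidance zone: it hovers at the
  activation boundary rather than flowing around. The test suite asserts
  the safety property (clearance is kept), not passage.
* Chord-based width estimation assumes walls representable as functions of
  a common horizontal coordinate; corridors that double back are out of
  scope, as is 3-D geometry.
* The advisory is an angle only; no route planning is performed.
* Crowd sizes in the hundreds are fine; the O(N^2) neighborhood scan and
  per-agent chord queries are not tuned beyond that.

## Problem sizes used in the checks

The bundled tests run the full 40-agent, 200-iteration standard scenario
once (twice for the determinism check), verify the chord solver against a
staged grid-search oracle on 100 random corridor positions plus 105
positions across three smaller geometries, and use reduced corridors
(8–10 agents, 20–80 iterations) for the remaining behavioural checks;
these sizes were chosen to exercise every code path at full default
parameters while keeping the suite comfortably reproducible on one CPU.
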