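---
title: "An integrated associative model of landmark learning in the water maze"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An integrated associative model of landmark learning in the water maze}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(landmaze)
```

`landmaze` simulates how a rat learns to find a hidden platform in the
Morris water maze from two extra-pool landmarks. It couples two classical
components: a Rescorla–Wagner (RW) associative learner that accumulates,
trial by trial, how much each cue is worth using and how well its vector
information (direction and distance to the platform) is known; and an
autoregressive directed random walk with proportional feedback control that
turns a desired heading into a swimming path. This vignette describes the
model, the choices behind every tunable parameter, and what the simulations
can and cannot say about real animals.

## The swimming model

Between samples separated by `dt` seconds the animal advances by a Rayleigh
step and turns by an AR(2)-filtered control signal:

$$
x_t = x_{t-\Delta t} + \Delta r_t \sin\alpha_t,\qquad
y_t = y_{t-\Delta t} + \Delta r_t \cos\alpha_t,\qquad
\alpha_t = \alpha_{t-\Delta t} + \Delta\alpha_t
$$
$$
\Delta\alpha_t = A_1\,\Delta\alpha_{t-\Delta t} + A_2\,\Delta\alpha_{t-2\Delta t} + u_t,
\qquad u_t = K\hat e_t + \nu_t,
$$
$$
\hat e_t = (1-F)\,\hat e_{t-\Delta t} + F\,(\alpha_{desired} - \alpha_t),
$$

with headings in degrees clockwise from North, $\Delta r_t$ Rayleigh
distributed, and $\nu_t$ zero-mean Gaussian heading noise. The error
$\alpha_{desired}-\alpha_t$ is always wrapped to $(-180^\circ, 180^\circ]$
so the controller steers the short way round. When no goal is active the
controller is disengaged — $\hat e$ is held at zero so the heading is a pure
AR noise process — rather than steering towards bearing zero; the literal
north-steering variant is available as
`swim_params(random_mode = "north")`.

### Parameter defaults and their calibration

The swim parameters are not observable quantities; they are the knobs of a
phenomenological movement model and must be calibrated jointly. We fixed
them by requiring, in order of priority:

1. an uninformed animal swims a meandering path that covers the pool but
   rarely finds the 9 cm platform within 60 s (day-1 behaviour);
2. a fully informed animal started on the rim escapes in a few seconds
   (plateau behaviour);
3. the four single-channel strategies (direction or distance of either cue,
   learned to 0.95) produce mean escape latencies in the regime of the
   cohort simulations the model is meant to reproduce, including both
   ordinal relations (Far-direction faster than Near-direction,
   Near-distance faster than Far-distance).

The defaults that satisfy all three are: `dt = 0.05` s (a 20 Hz tracking
rate; a 60 s trial is 1200 steps), `rayleigh_scale = 0.9255` cm (mean swim
speed ≈ 23 cm/s, in the normal range for adult rats), `noise_std = 8`
degrees per step, `A1 = 0.15`, `A2 = 0.05`, `K = 1.0`, `F = 0.8`. The
closed loop converges — a fixed desired heading is acquired, with a damped
oscillation, within about one second — which the test suite verifies
against direct iteration of the scalar linear recursion.

Three behavioural rules complete the walker; each is a modelling decision
worth stating explicitly:

* **Platform contact is tested against the swum segment.** The animal
  escapes when the segment between consecutive samples passes within
  `platform_radius + contact_margin` of the platform centre
  (`contact_margin = 7` cm, about half a rat's body width). A point-in-disc
  test at sampled positions would let the path step over a 4.5 cm platform,
  which a swimming animal cannot physically do.
* **The wall clamps.** A step that would exit the pool is radially clamped
  to the wall with heading preserved (`boundary = "clamp"`; reflection is
  available).
* **Unreachable goals end early.** If the current goal lies outside the
  pool and the animal has reached the wall towards it, the closest feasible
  approach has been attained and the approach episode ends.

## The learning model

Each cue `i` carries three associative strengths, updated once per trial.
Learning to *use* the cues is competitive — both increments share one error
term computed from the pre-update total $V_\Sigma = \sum_i V_{i,use}$:

$$\Delta V_{i,use} = \alpha_i\,\beta_{use}\,(\lambda_{use} - V_\Sigma),$$

so the cues divide a fixed capacity $\lambda_{use}$ in proportion to their
saliences $\alpha_i$; if one cue reaches 0.7 the other can never exceed
0.3. This competition is the substrate of overshadowing. Learning a cue's
*direction* and *distance* information is independent — each channel relaxes
to its own asymptote:

$$\Delta V_{i,dir} = \alpha_i\,\beta_{dir}\,(\lambda_{dir} - V_{i,dir}),$$

and likewise for distance; both cues can reach full knowledge
simultaneously. Updates are simultaneous across cues within a trial
(both increments see the same $V_\Sigma$), and if an aggressive rate would
overshoot the shared capacity in one trial the increments are rescaled
proportionally, preserving the salience ratio. All strengths start at zero
(a naive animal), and every cue updates on every trial whether or not it
was used — the update rule is unconditional.

Defaults: all rates 0.15 per trial, all asymptotes 1. With two cues of
salience 0.5 these place total cue usage at 99.8% of capacity and each
information channel at ≈ 0.956 after the standard 40-trial protocol — i.e.
the training course ends just where the single-channel analyses (strength
0.95) are conducted, and learning plateaus at about day 5 of 10 as
acquisition curves do.

## From strengths to platform guesses

Uncertainty is the complement of strength, $\sigma_{dist} = 1 - V_{i,dist}$
and $\sigma_{dir} = 1 - V_{i,dir}$. A platform guess from cue `i` perturbs
the true cue-to-platform polar offset $(r, \varphi)$:

$$\vec p = \vec p_{cue} + \big(r + \epsilon_{dist},\ \varphi + \epsilon_{dir}\big),
\qquad \epsilon_{dist} \sim N(0, (200\,\sigma_{dist})^2)\ \text{cm},\quad
\epsilon_{dir} \sim N(0, (75\,\sigma_{dir})^2)\ \text{degrees}.$$

The multipliers 200 cm and 75° scale the standard deviation (not the
variance); the test suite recovers both slopes by regression on sampled
errors. A negative perturbed radius is reflected through the cue
(radius $|r+\epsilon|$, bearing flipped), keeping the polar map total;
truncation at zero is available.

Two further decisions matter here:

* **Cue-centred frames.** The learned offset bearing is carried relative to
  the cue's own bearing around the pool. For inference from a cue at its
  own position this changes nothing; but when a learned relationship is
  *assigned to a different cue* (the generalisation and misinterpretation
  scenarios below), the inferred location is rotated by the cues' angular
  separation. With cues at NE and NW and the platform on the NE cue's
  radial, reading the Near cue as the Far one therefore rotates the search
  target 90° clockwise into the SE quadrant, and reading Far as Near
  rotates it into the NW — the displaced-search signature of the cue-removal
  experiments. A purely translational re-anchoring cannot produce the SE
  displacement at all: with both cues mounted at the same radius the
  translated target always keeps a positive north component, so its bearing
  stays below 90°.
* **Acting on guesses.** `infer_platform()` returns the raw guess
  distribution, which extends beyond the pool when uncertainty is high. The
  *navigator*, however, redraws guesses that fall outside the pool
  (`guess_in_pool = TRUE`): the animal knows the platform stands in the
  water, so an inference beyond the wall is implausible as a swim target.
  Without this rule the simulated animal spends most of a trial swimming to
  unreachable wall targets whenever a channel is poorly learned.

## The integration algorithm

Each trial is a loop of short behavioural episodes:

1. pick cue `i` with probability $V_{i,use}$, or no cue with probability
   $1 - \sum_i V_{i,use}$ (a single mutually exclusive draw);
2. if no cue was picked, swim randomly for `n_steps = 7` steps, then return
   to 1;
3. if a cue was picked, swim towards it for `n_steps = 7` steps, re-aiming
   at the cue every step;
4. draw a fresh platform guess from the picked cue and swim to it, re-aiming
   every step, until within `goal_tolerance = 5` cm of the guess or an
   episode budget (`goal_step_factor * n_steps` steps, 8.4 s by default)
   runs out;
5. return to 1.

The trial ends at platform contact or at 60 s (censored). A new guess is
drawn for *every* goal-approach episode, so a poorly known channel shows up
as scattered successive search targets within a single trial. Acquisition
runs permute the four rim start positions pseudorandomly within each day;
probes run 60 s without a platform from the novel SW start, with no
learning during the probe (evaluation only, no extinction).

Because the learning recursion is trial-level and unconditional, the
associative trajectory of a cohort is deterministic; only the swimming is
stochastic. `run_acquisition()` exploits this by computing the learning
history once and swimming each simulated rat under the state in effect at
each trial.

### Interpretation policies on probe trials

What a presented cue *means* to the animal after cue removal or relabelling
is governed by an `interpretation_policy`:

* `identity` — cues are fully discriminated; a presented cue is engaged
  with its own usage strength and its own relationship.
* `indistinguishable` — with the full training array present the
  configuration disambiguates the cues and the policy reduces to identity;
  with a partial array the animal engages with probability
  $\sum_i V_{i,use}$ and assigns one of the learned relationships at
  random, proportional to usage strengths, re-drawn each episode — the
  two-patch search of classic landmark-removal experiments.
* `generalize_to_salient` — the same machinery; at extreme salience splits
  (1:0) the usage weights degenerate and the dominant cue's relationship is
  always applied, and at 50:50 it coincides with `indistinguishable`
  (asserted bit-for-bit in the tests).
* `probabilistic_misinterpretation` — the animal recognises the cues but,
  presented with a designated poorly-learned cue alone, applies the other
  cue's relationship with a configured probability (0.5 in the standard
  setup), splitting the search between the correct region and the rotated
  one.

## Arena geometry

The pool is the experimental one: radius 85 cm, platform radius 4.5 cm in
the NE quadrant, 60 s trials, 4 trials/day for 10 days from N/S/E/W, probe
from SW. Three quantities the experimental description leaves unsized are
set as follows and exposed in `make_default_arena()`:

* cue mounting radius 120 cm (anywhere outside the pool preserves the
  geometry; this keeps the cues just inside a curtain around a 1.7 m pool);
* platform centre 47.5 cm from the pool centre at bearing 45° — near the
  areal centroid of the NE quadrant, a standard placement;
* probe scoring circle (`escape_region_radius`) 15 cm around the platform
  location. This radius desaturates the time-in-platform-area readout: a
  larger circle contains the trained animal's entire search cloud, pinning
  the measure near its ceiling and collapsing its across-rat variability
  below what probe data show.

Quadrants partition the pool by half-open bearing intervals
([0°, 90°) = NE and so on), so boundary points — including the pool centre —
classify deterministically. Occupancy weights each `dt` interval by the
quadrant of the segment midpoint.

## Randomness and reproducibility

Every cohort function takes a master seed. Rat `i` seeds its own stream
with `derive_seed(master, i)` (a two-round Lehmer mix modulo $2^{31}-1$),
so each rat's trajectory is bit-reproducible regardless of cohort size or
execution order. Scenario outputs are deterministic given (spec, seed);
the command-line driver records seeds and output checksums in a manifest.

## What the simulations do and do not show

The model reproduces, with one parameterisation: acquisition curves that
fall from ~30 s to ~4 s over ten days; the dissociation between cue
position and information channel (direction is the better channel of the
far cue, distance the better channel of the near cue); insensitivity of
acquisition speed to salience ratios; the reliability gap between one-shot
escape latencies and probe occupancy (CV ratio near an order of
magnitude); displaced and bimodal search after cue removal under the
respective interpretation policies; and direct overshadowing (single-cue
groups outperform compound-trained groups on the same probe, an ordering
that holds in essentially every seeded replicate at 50 rats per group).
The acceptance script (`scripts/acceptance.R`) recomputes the headline
numbers from scratch; the test suite asserts the qualitative signatures at
cohort sizes of 25–1000 simulated rats (the dissection and CV checks use
1000, the scenario batteries 40–50, matching the original cohort sizes
while keeping the default suite to a few minutes).

Limits worth keeping in mind: the pool wall is never an informative cue, so
thigmotaxis and wall-distance learning are outside the model; cues are
points with a scalar salience — no size, shape or configural compounds; swim
speed does not change with learning; probes cause no extinction; and the
swim parameters are a calibrated ensemble, not measurements — conclusions
should rest on the orderings and contrasts that are robust across the
calibration neighbourhood, not on absolute latencies.
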