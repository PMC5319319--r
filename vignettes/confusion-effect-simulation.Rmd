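---
title: "Simulating the confusion effect in 3D starling flocks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating the confusion effect in 3D starling flocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(confusim)
```

## The problem

The confusion effect is the decline in predator attack success as prey group
size grows, usually attributed to the difficulty of tracking one moving
object among many. `confusim` provides a controlled, fully scripted
virtual-predation system for studying it in three dimensions: a starling
flock simulator with topological coordination and calibrated density, a
steerable predator, a stochastic target-tracking surrogate that stands in
for a human participant, and the repeated-measures model-comparison pipeline
used to quantify how targeting error and hunting time depend on flock size
and density.

## The flock model

Each bird is a self-propelled agent with position, velocity and a body
frame. Its steering acceleration is the weighted sum of five terms:

* **separation** from topological neighbours closer than the separation
  radius $r_s$, with an inverse-distance ramp
  $w_{sep}(r_s/d - 1)/d$ along the offset — repulsion grows sharply at
  close range, so birds in denser flocks manoeuvre harder. This makes
  greater path curvature and linear acceleration an *emergent* property of
  dense flocks rather than a programmed one;
* **alignment** towards the mean heading of the $k = 7$ nearest neighbours
  (topological, not metric, interaction — the empirically observed
  coordination rule for starlings);
* **cohesion** towards the centroid of those neighbours, as *bounded*
  steering that saturates at $w_{coh}$: its magnitude does not grow with
  flock spacing, which keeps the kinematic contrast between density
  settings in the separation term;
* **speed regulation** towards the 10 m/s cruise speed typical of starling
  flight; and
* a weak damped **altitude spring** around the 50 m flight altitude — the
  only boundary condition; the world is otherwise unbounded.

The total acceleration is clamped at 2 g, integrated with semi-implicit
Euler at `dt` = 0.05 s (steering recomputed every `reaction_dt`, by default
each step), speeds are clamped to [6, 14] m/s, and the body frame is
re-orthonormalised with the lift vector tilted to support gravity plus the
lateral acceleration (banked turning). Neighbour queries use an exhaustive
$O(N^2)$ search with ties broken by lower bird index, so results are
deterministic and exactly reproducible; at the design's largest flock
(5000 birds) a step costs a few hundredths of a second, which is adequate
for desk-scale experiments without a spatial index.

### Density as an emergent, calibrated property

The design's three density settings are *achieved* average nearest-neighbour
distances (NND) of 0.8, 1.3 and 1.8 m, not model parameters.
`calibrate_density()` tunes the separation radius by bisection against the
equilibrium time-averaged mean NND (20 s burn-in, 10 s measurement window)
until it lands within ±10% of the target. At the default weights the
equilibrium NND is close to `separation_radius / 1.075` across
N = 50–1000, so default configurations start at that fixed point and
calibration usually returns immediately. The label mapping follows the
natural reading — `dense` → 0.8 m, `loose` → 1.8 m — with the inverted
literal mapping available via `density_labels(literal = TRUE)`.

Initial positions are drawn uniformly in a ball whose radius is chosen from
the Poisson nearest-neighbour formula
$E[\mathrm{NND}] = \Gamma(4/3)\,(4\pi\lambda/3)^{-1/3}$ so the flock starts
near its target spacing, with a common heading plus small angular noise.

## The predator and the trial protocol

The predator's flight is deliberately simpler than the birds': roll, pitch
and thrust commands in $[-1, 1]$ scale linearly to maximum rates; yaw
follows the coordinated-turn law $\dot\psi = g \tan\phi / v$; speed is
clamped to [4, 20] m/s. The paper-protocol constants are enforced exactly
by the trial engine: the predator starts 100 m from a uniformly chosen
target bird, both at 50 m altitude; the target's 1 s trail fades linearly
between 40 and 20 m predator–target distance; an unanswered trial times out
at 30 s; feedback uses the five printed bands with edges assigned to the
better band. Targeting error is always measured to the *true* target at the
moment of the click; trials with errors beyond 10 m are labelled out of
range but still recorded — exclusion is an analysis-stage decision.

## The scripted participant

Human participants are replaced by two pluggable components:

* `pursuit_controller()` — proportional pursuit of the believed target with
  a distance-scheduled speed: full speed in transit, decelerating to a
  shadowing speed just above prey cruise speed inside ~10 m, then clicking
  within the 0.5 m strike radius (or when the target starts receding inside
  the 3 m arm distance). The shadowing phase mimics the careful final
  approach participants adopt, and its duration is what gives late,
  close-range confusion events weight relative to rare long-range ones.
* `confusable_tracker()` — the confusion surrogate. At each 0.1 s decision,
  let $m$ be the number of non-target birds within angular radius $\theta$
  of the line of sight to the believed target; with probability
  $\min(1, h_0 m)$ the belief swaps to one of those $m$ distractors chosen
  uniformly at random. A singleton flock can never trigger a swap, so
  singleton trials measure pure motor/pursuit error.

The defaults ($h_0$, $\theta$, decision interval) were calibrated once,
qualitatively, against the directional findings of the human experiment —
mean targeting error increasing with flock size and larger in denser
flocks — not against any of its printed effect sizes. The regime that
reproduces the pattern is one of *rare, consequential* swaps (roughly
0.1–1.5 per trial depending on the cell): the hazard contrast between
densities follows the ~5× higher angular column density of a 0.8 m flock
over a 1.8 m flock, while each swap displaces the belief by a distance set
by the cone and flock geometry. With much larger hazards both densities
saturate (the belief mixes across the whole flock and the *looser* flock's
larger physical extent dominates the error), which inverts the density
direction; the package treats the human results as qualitative calibration
of this surrogate, so the defaults sit deliberately in the non-saturated
regime. Individual differences across synthetic participants are mimicked
by log-normal jitter of $h_0$ (sd 0.2 on the log scale).

## Experiment design and analysis

`generate_schedule()` builds the full factorial — sizes
{1, 50, 250, 1000, 5000} × three densities, 4 practice and 15 experimental
repetitions per cell — with a seeded permutation drawn independently per
participant and distinct per-trial seeds, and `run_full_experiment()`
executes it for any number of synthetic participants (25 matches the
original study).

The analysis pipeline applies, in order: filtering (practice trials,
timeouts, targeting errors > 20 m), per-participant normalization of
targeting error against the singleton baseline, and the natural-log
transform of flock size. Models are linear mixed models (`lme4`) with a
subject random intercept, fitted by maximum likelihood — not REML — so
deviances of nested fits are comparable; nested models are compared by the
change in deviance against a $\chi^2$ distribution with df equal to the
parameter-count difference. Size and density enter as orthogonal
polynomials (degree 2 or 1) of ln(size) and of the numeric NND; with three
distinct density values the quadratic basis spans the same space as a
three-level factor, which makes the reported degrees of freedom consistent
across all comparisons. `run_paper_analysis()` walks the decision tree:
choose quadratic vs linear for size, then for density, test the size ×
density interaction, and either break the size effect out per density
setting (interaction present) or test the two main effects (interaction
absent).

`within_subject_ci()` provides Cousineau–Morey repeated-measures intervals
for descriptive plots only; they play no inferential role.

## What the synthetic data do and do not show

Two generators exist at different levels. `simulate_results_table()` draws
trial tables directly from a known linear mixed model — it validates the
*statistical* machinery (type-I error near 0.05 in null simulations at
15 participants × 150 trials, parameter recovery within 2 SE at the full
study size, power for built-in interactions) but says nothing about flocking.
The full simulator validates the *mechanistic* chain end to end. Passing
tests demonstrate that the protocol, metrics and inference behave correctly
and that the surrogate predator reproduces the directional confusion
pattern; they cannot demonstrate anything about human perception, and the
quantitative effect sizes of the original experiment are out of reach by
design.

## Numerical choices and limitations

* Problem sizes in the test-suite: density calibration and cohesion checks
  use N = 40–250; the confusion battery uses 200 trials per cell over
  sizes {1, 50, 250} × {0.8, 1.8} m. These are the smallest sizes at which
  the quantities of interest are stable.
* Calibration tolerance ±10% (relative), bisection budget 12 iterations,
  bracket 0.25–3× the default radius ratio.
* Curvature uses central differences with $\kappa = |v \times a|/|v|^3$;
  zero-speed frames are excluded from curvature summaries. "Variation" is
  reported as both variance and SD.
* Tie-breaks in neighbour queries go to the lower bird index; feedback band
  edges go to the better band; the trail-opacity ramp is closed at both
  ends.
* The flock does not react to the predator in any way, matching the
  original design; predator-avoidance, full fixed-wing aerodynamics, and
  rendering are out of scope.
* The tracker's swap-target choice is uniform among cone distractors; a
  perceptually weighted choice (e.g. by angular proximity) is a natural
  extension the plug-in contract supports.
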