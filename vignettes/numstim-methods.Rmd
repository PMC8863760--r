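---
title: "Generating numerosity stimuli with controlled continuous variables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating numerosity stimuli with controlled continuous variables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(numstim)
```

## The control problem

A numerosity stimulus is a set of n shaped elements in a bounded arena. Six
continuous variables summarise its non-numerical content: mean
inter-distance (ID), convex hull area (CH), density (D = n/CH), element size
(R), total area (TA) and total perimeter (TP). Geometry couples them: TA
grows with R², TP with R, and D is determined by CH at fixed n. The feasible
joint controls are therefore one *spatial* variable (ID, CH or D) together
with one *magnitude* variable (TA or TP) and a radius policy; fixing TA and
TP together is impossible for a common shape family, and `numstim` rejects
it at validation time rather than failing during a long sampling run.

All constraint mathematics lives in continuous Cartesian stimulus units with
the origin at the arena centre and the y-axis up; nothing is quantised to
pixels until rendering. "Pixel" targets quoted for generated sets are simply
these abstract units; the renderer maps units to pixels through the physical
canvas settings, so both the constraint math and the on-screen size remain
exact.

A variable counts as satisfied when its relative error,
|achieved − target| / target × 100, is at or below the `accepted_error`
percentage. The default is 0.01%, a practical operating point at which
generation remains fast while errors stay at the sub-pixel level for
typically sized canvases; the benchmark runs below tighten it to 0.0001% to
demonstrate headroom.

## Stage one: centre sampling

Centres are drawn uniformly in the arena shrunk by an edge margin equal to
the expected maximum element radius (derived from the radius policy and the
magnitude target), so that stage two can shape elements around the points
without ever crossing the boundary. An optional `min_gap` rejects draws
whose centres come closer than a set distance — dot stimuli must not fuse,
or the perceived numerosity itself changes — and `max_gap` bounds the
nearest-neighbour distance when a scattered-but-connected look is wanted.
Both default to off (0 and ∞): the method itself imposes no hidden
neighbour rule.

When a spatial target is set, a raw uniform draw is *calibrated*: the whole
configuration is rescaled about its centroid by the factor that maps its
spatial statistic onto the target. ID is homogeneous of degree one in that
rescaling and the hull area of the bare centres of degree two, so the factor
is target/raw for ID and √(target/raw) for CH. The calibrated configuration
is kept only if it still lies inside the margined arena and respects the gap
settings; otherwise it is rejected and redrawn. Calibration is a closed-form
map applied to an unbiased uniform draw — not an optimisation and not a
Markov chain — and it is what makes tolerances like 0.0001% reachable at
all: accepting raw draws only when a continuous statistic happens to fall
inside a ±10⁻⁶ relative window would essentially never terminate, while the
calibrated sampler satisfies any tolerance at machine precision and spends
its rejections purely on containment. A density target is first rewritten as
the equivalent hull target (CH = n/D, with n fixed), so the sampler only
ever handles ID and CH.

Feasibility is pre-checked: a CH target above the arena area, or an ID
target above the arena diameter (diagonal for square arenas), raises a typed
infeasible-geometry error before any sampling. A per-configuration budget
(10⁶ raw draws by default) turns pathological-but-not-impossible requests
into a loud budget-exhausted error carrying the best candidate found, rather
than a hang.

## Stage two: shaping

Radii are drawn under the policy — identical (`equal`), Gaussian with
optional truncation (`gaussian`), or uniform (`free`; bounds default to 2%
and 10% of the arena radius when unset, a range that keeps elements visible
but clearly smaller than the arena) — and, when `fixed_min`/`fixed_max` pins
are set, the smallest and largest draws are replaced by the pin values
exactly. Assigning pins to the extreme draws distorts the Gaussian sample
least, and makes the achieved Rmin/Rmax reproducible across arrays to
machine precision.

A magnitude target is then met in closed form: all free radii are multiplied
by target/current for TP or √(target/current) for TA, with pinned radii held
fixed and the scale solved on the residual target. If the pins alone exceed
the target the fit fails (typed error); if rescaling would push a free
radius past a pin, the configuration is discarded and resampled, because
silently unpinning would break the Rmin/Rmax contract.

Shaping elements around centres whose bare-centre hull equals the CH target
necessarily *enlarges* the effective hull — outlines extend outward from the
centres. The effective CH is therefore re-measured on the element outlines
and the positions are moved toward their centre of mass until it matches the
target: each iteration shrinks every centre's distance to the centre of mass
by a constant fraction (default 0.005), and once a full step would cross the
target the homothety factor is bisected until the hull lands inside the
tolerance. Fractional homothetic steps preserve the configuration's shape
(all pairwise distance ratios), never reorder the hull, and make the
achieved CH monotonically non-increasing across iterations; the bisection
tail is what lets a 0.5% step size converge to a 10⁻⁴% tolerance instead of
overshooting around it. The centre of mass is the unweighted mean of the
centres — the simplest definition, and the one under which the shrink is an
exact homothety. Radii never change during refinement, so a previously met
TA/TP target survives it untouched.

Hard constraints are enforced, not assumed: after refinement, any pairwise
outline intersection (separating-axis tests for the convex polygons,
distance tests for discs) or arena crossing discards the configuration with
a recorded reason, and the generator keeps sampling until the requested
number of arrays exists. Discard counts are part of the result object —
`glance()` reports them — because a high discard rate is itself evidence
that the requested conditions are close to geometric infeasibility.

Degenerate inputs follow the descriptor definitions: ID and D are undefined
for n = 1 and raise a typed error rather than returning NaN (sentinels
propagate silently into constraint checks); a single-element array's CH is
the element's own area.

## Numerical choices

* **Hull measurement.** CH is the shoelace area of the convex hull
  (`grDevices::chull`) of points sampled along every element outline, 256
  per element by default, with polygonal shapes always contributing their
  exact vertices. A regular 256-gon underestimates a disc's area by
  (2π/256)²/6 ≈ 1.0 × 10⁻⁴ of its value, i.e. ~0.01%, and the test suite
  checks that doubling the sampling moves a mixed-shape hull by less than
  0.01%. Because the refinement targets the same measured quantity, sampling
  bias cancels between generation and audit; it matters only when comparing
  against the analytic area of an isolated disc, where it stays below 0.1%.
* **Tolerance landing.** The bisection bracket is maintained on the
  homothety factor with the hull monotone inside it, so refinement
  terminates for any positive tolerance; iteration count is capped at 10⁴.
* **Tie-breaks.** With both pins set and n = 2, both radii are pins; the
  magnitude fit then has no free radii and fails loudly if the target is not
  already met.
* **Determinism.** Every stochastic step (centre draws, radius draws,
  exemplar shuffles, side counterbalancing) runs inside a stream seeded from
  the constraint set's `seed`, and rendering is purely deterministic, so
  identical inputs reproduce outputs bit for bit.

## What the generator does and does not emulate

The generated arrays reproduce the *geometric* conditions of visual
numerosity experiments: counts, spacing statistics, occupied field, summed
area/contour, and their congruent/incongruent couplings with number. They do
not model luminance calibration, spatial-frequency content, element shape
heterogeneity within one array (one shape per array), or 3-D cues. Tests
passing on these arrays therefore certify the constraint engine and the
rendering scale, not any perceptual property of a particular display.

## Benchmark configurations used by the tests

The packaged benchmarks run at sizes chosen to exercise the engine across
its range while remaining comfortable on a laptop:

* joint CH + TA control: equal-radius circles, CH = 150,000 units²,
  TA = 20,000 units², tolerance 0.0001%, 20 arrays at each of n = 5, 10, 20,
  on a circular arena of radius 350 units with `min_gap` set to three
  element radii. The arena radius gives the 150,000-unit² hull room to float
  (the margined arena area is ≈ 2.2× the hull target) and the gap keeps
  equal-sized dots visibly separate after the refinement shrink; both are
  stated here once as the benchmark's conditions.
* congruency suite: 40-dot arrays at the total-area targets derived from a
  20-dot, TA = 600 units² reference (balanced 600, congruent 1200,
  incongruent 300), Gaussian radii (σ = 0.3 units) at 0.01% tolerance, 10
  arrays per condition.
* feasibility grid: all 30 combinations of {ID, D, CH} × {TA, TP} ×
  {R_min, R_max, R_min+max, R_equal, R_free} at n = 6 on a radius-100 arena,
  5 seeds each, every array audited by an independent descriptor pass.

## Known limitations

* The calibrated sampler draws centre configurations uniformly *given*
  containment and gaps; conditioning on the calibrated configuration fitting
  the arena slightly favours draws whose raw statistic is near the target.
  For hypothesis-neutral stimuli this is harmless (the spatial statistic is
  fixed anyway), but the residual shape distribution is not characterised.
* Non-overlap is enforced pairwise on outlines; there is no minimum *visual*
  gap between outlines unless `min_gap` provides one at the centre level.
* Very tight joint constraints (e.g. a small hull with large mandatory
  radii) fail by discard-budget exhaustion rather than by an a-priori
  infeasibility proof; the error carries the partial results.
* `autoplot()` draws circles as 90-gons for display; only the renderer's
  supersampled rasteriser is pixel-exact.
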