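# numstim

Controlled numerosity stimulus arrays for non-symbolic number experiments.

## The problem

Experiments on the approximate number system — in humans, chicks, fish or
bees — present arrays of discrete elements and ask whether behaviour tracks
the *number* of elements. But numerosity naturally co-varies with continuous
physical magnitudes: more dots usually means more total surface, more
contour, a wider occupied field or a higher density. Any of these can act as
a non-numerical cue. The standard remedy is to generate stimuli in which the
continuous variables are fixed, randomized, or deliberately pitted against
number (congruent / incongruent designs), so that they become uninformative.

`numstim` generates such stimuli. For an array of *n* shaped elements inside
a circular or square arena it controls, to a user-chosen percent tolerance:

| symbol | variable | definition |
|---|---|---|
| ID | inter-distance | mean Euclidean distance between element centres over all n(n−1)/2 pairs |
| CH | convex hull | area of the smallest convex polygon containing all element outlines |
| D | density | n / CH |
| R | element size | circle radius, or side length for squares, diamonds, equilateral triangles |
| TA | total area | Σ per-element areas |
| TP | total perimeter | Σ per-element contours |

At most one *spatial* variable (ID, CH or D) can be combined with at most
one *magnitude* variable (TA or TP) plus a radius policy (equal radii, free,
or Gaussian with exactly pinned minimum/maximum sizes). TA and TP can never
be fixed together — area scales with the square of element size, perimeter
linearly — and D is just n/CH, so the feasible combinations form a
3 × 2 × 5 grid that the package validates up front.

Generation is two-staged, mirroring how the constraints factor:

1. **centre sampling** — seeded uniform draws of centre configurations in the
   (margined) arena, homothetically calibrated about their centroid so the
   spatial statistic of the bare centres hits its target, and rejected if the
   calibrated configuration leaves the arena or violates neighbour-gap
   settings;
2. **shaping** — radii are drawn under the policy and rescaled in closed form
   to meet TA or TP exactly; because shaped elements extend beyond their
   centres, the effective hull is then re-measured on the element outlines
   and the positions are shrunk toward their centre of mass (small homothetic
   steps, then bisection) until the achieved CH is inside the tolerance.
   Overlapping or boundary-crossing configurations are discarded and
   resampled; discard counts are reported.

A rendering layer rasterizes arrays to PNG with exact physical scaling
(canvas pixels ↔ centimetres), and a sequencing layer builds
habituation/dishabituation and simultaneous dual-choice trial tables with
counterbalanced sides and seeded exemplar randomization.

## Worked example

Ten equal-radius circles with the convex hull fixed at 150,000 units² and
the total area at 20,000 units², tolerance 0.0001%:

```r
library(numstim)

cs <- constraint_set(
  10, arena("circular", 350), shape = "circle",
  CH = 150000, TA = 20000,
  radius_policy = radius_policy("equal"),
  accepted_error = 1e-4, generations = 3, seed = 11,
  min_gap = 3 * sqrt(20000 / (10 * pi))   # keep dots from fusing
)
set <- generate_stimuli(cs)
tidy(set)
#> # A tibble: 3 × 13
#>      id     n shape     ID      CH         D    TA    TP  Rmin  Rmax  seed
#>   <int> <int> <chr>  <dbl>   <dbl>     <dbl> <dbl> <dbl> <dbl> <dbl> <dbl>
#> 1     1    10 circle  254. 150000. 0.0000667 20000 1585.  25.2  25.2    11
#> 2     2    10 circle  277. 150000. 0.0000667 20000 1585.  25.2  25.2    11
#> 3     3    10 circle  259. 150000. 0.0000667 20000 1585.  25.2  25.2    11
#>       err_CH err_TA
#>        <dbl>  <dbl>
#> 1 0.0000959       0
#> 2 0.00000852      0
#> 3 0.0000795       0
```

Every array hits both targets: the relative error on CH is below the set
0.0001% and TA is met exactly (equal radii solve it in closed form — here
each radius is √(20000/10π) ≈ 25.2 units). The un-targeted variables (ID,
TP) vary freely from array to array, which is exactly what makes them
uninformative cues. `glance(set)` summarises the set (array count, discards,
mean achieved values); `autoplot(set$arrays[[1]])` draws an array;
`save_stimulus_set(set, "out/", render = render_spec(canvas_px = c(800, 800),
arena_cm = 20))` writes PNGs, a `metadata.csv` and a reloadable `set.json`.

Congruency designs use `derive_congruency_target()`: from a 20-dot reference
with TA = 600, the 40-dot balanced / congruent / incongruent targets are
600 / 1200 / 300.

A thin command-line wrapper is installed as `exec/numstim`:

```sh
numstim create --config cfg.yaml --out stim/ --canvas 800x800 --cm 20
numstim sequence --paradigm dual_choice --sets a/set.json b/set.json --trials 20 --seed 7 --out log.csv
```

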