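# Shaping stage: radius policies, magnitude fitting, hull refinement and the
# composed pipeline.

test_that("radius policies produce the promised draws", {
  eq <- draw_radii(radius_policy("equal", mean = 3), 20, seed = 1)
  expect_true(all(eq == 3))
  g0 <- draw_radii(radius_policy("gaussian", mean = 5, sigma = 0), 4, seed = 1)
  expect_equal(as.numeric(g0), rep(5, 4))
  pinned <- draw_radii(radius_policy("gaussian", mean = 5, sigma = 1.5,
                                     fixed_min = 2, fixed_max = 8), 5, seed = 2)
  expect_identical(min(pinned), 2)
  expect_identical(max(pinned), 8)
  expect_error(
    draw_radii(radius_policy("gaussian", mean = 1, sigma = 0.01, fixed_min = 50),
               5, seed = 1),
    class = "numstim_budget_exhausted"
  )
})

test_that("magnitude fitting solves equal-radius circles in closed form", {
  for (spec in list(list(n = 20, TA = 600), list(n = 40, TA = 600), list(n = 40, TA = 1200))) {
    r <- draw_radii(radius_policy("equal"), spec$n, seed = 1)
    fit <- fit_magnitude(r, "circle", "TA", spec$TA)
    expect_equal(as.numeric(fit), rep(sqrt(spec$TA / (spec$n * pi)), spec$n))
    expect_equal(sum(pi * fit^2), spec$TA)
  }
  r <- draw_radii(radius_policy("equal"), 6, seed = 1)
  tp <- fit_magnitude(r, "circle", "TP", 120)
  expect_equal(sum(2 * pi * tp), 120)
})

test_that("pinned radii are preserved and pins alone may exceed the target", {
  r <- structure(c(2, 4, 8), pinned = c(TRUE, FALSE, TRUE))
  fit <- fit_magnitude(r, "circle", "TA", 250)
  expect_identical(fit[1], 2)
  expect_identical(fit[3], 8)
  expect_equal(sum(pi * fit^2), 250)
  # pinned discs alone contribute 68*pi > 100
  expect_error(fit_magnitude(r, "circle", "TA", 100),
               class = "numstim_pins_exceed_target")
})

test_that("hull refinement is the identity inside tolerance and monotone otherwise", {
  el <- circle_elements(c(-60, 60, 0), c(-40, -40, 60), rep(2, 3))
  ch0 <- convex_hull_area(el)
  same <- refine_to_hull(el, ch0 * (1 + 5e-5), accepted_error = 0.01)
  expect_identical(same$iterations, 0L)
  expect_identical(same$elements, el)
  shrunk <- refine_to_hull(el, ch0 * 0.98, accepted_error = 0.01, trace = TRUE)
  expect_lt(abs(shrunk$CH - ch0 * 0.98) / (ch0 * 0.98) * 100, 0.01)
  tr <- attr(shrunk, "trace")
  expect_true(all(diff(tr) <= 1e-9))
  # tight tolerance converges too
  tight <- refine_to_hull(el, ch0 * 0.98, accepted_error = 1e-4)
  expect_lt(abs(tight$CH - ch0 * 0.98) / (ch0 * 0.98) * 100, 1e-4)
})

test_that("refinement refuses to grow the hull and detects forced overlap", {
  el <- circle_elements(c(-60, 60, 0), c(-40, -40, 60), rep(2, 3))
  ch0 <- convex_hull_area(el)
  expect_error(refine_to_hull(el, ch0 * 1.5), class = "numstim_infeasible_geometry")
  # two R = 10 discs: the hull at tangency (centres 20 apart) is 400 + 100*pi;
  # any smaller target forces them to intersect
  two <- circle_elements(c(-15, 15), c(0, 0), c(10, 10))
  tangency_hull <- 400 + 100 * pi
  expect_error(refine_to_hull(two, tangency_hull * 0.7),
               class = "numstim_overlap_before_convergence")
})

test_that("congruency targets scale with and against numerosity", {
  expect_identical(derive_congruency_target(600, 20, 40, "balanced"), 600)
  expect_identical(derive_congruency_target(600, 20, 40, "congruent"), 1200)
  expect_identical(derive_congruency_target(600, 20, 40, "incongruent"), 300)
  expect_error(derive_congruency_target(600, 20, 40, "sideways"))
})

test_that("the composed pipeline meets joint hull and area constraints", {
  cs <- comparison_cs(10, generations = 2, seed = 31)
  set <- generate_stimuli(cs)
  for (arr in set$arrays) {
    audit <- describe_elements(arr$elements)
    expect_lt(abs(audit$CH - 150000) / 150000 * 100, 1e-4)
    expect_lt(abs(audit$TA - 20000) / 20000 * 100, 1e-4)
    expect_false(numstim:::any_overlap(arr$elements))
  }
})

test_that("a single-element array satisfies a total-area target with CH = TA", {
  cs <- constraint_set(1, arena("circular", 100), TA = 600,
                       radius_policy = radius_policy("equal"), seed = 4)
  set <- generate_stimuli(cs)
  arr <- set$arrays[[1]]
  expect_equal(arr$elements$R[1], sqrt(600 / pi))
  expect_equal(arr$achieved$CH, arr$achieved$TA)
  expect_null(arr$achieved$ID)
  expect_null(arr$achieved$D)
})

test_that("an ID-only target leaves CH free but reported", {
  cs <- small_cs(n = 6, ID = 60, generations = 2, seed = 9,
                 radius_policy = radius_policy("free", lo = 1, hi = 3))
  set <- generate_stimuli(cs)
  for (arr in set$arrays) {
    audit <- describe_elements(arr$elements)
    expect_lt(abs(audit$ID - 60) / 60 * 100, 0.01)
    expect_true(is.numeric(audit$CH) && audit$CH > 0)
  }
})

test_that("radius pins survive the whole pipeline exactly", {
  cs <- small_cs(
    n = 6, ID = 60, TA = 300, generations = 3, seed = 17,
    radius_policy = radius_policy("gaussian", mean = 4, sigma = 1,
                                  fixed_min = 2.5, fixed_max = 6)
  )
  set <- generate_stimuli(cs)
  for (arr in set$arrays) {
    expect_equal(arr$achieved$Rmin, 2.5, tolerance = 1e-12)
    expect_equal(arr$achieved$Rmax, 6, tolerance = 1e-12)
    expect_lt(abs(arr$achieved$TA - 300) / 300 * 100, 0.01)
  }
})

test_that("translating the whole configuration leaves the descriptors unchanged", {
  cs <- small_cs(n = 5, TA = 200, generations = 1, seed = 3,
                 radius_policy = radius_policy("free", lo = 1, hi = 4))
  arr <- generate_stimuli(cs)$arrays[[1]]
  d0 <- describe_elements(arr$elements)
  moved <- arr$elements
  moved$x <- moved$x + 31.4
  moved$y <- moved$y - 8.1
  d1 <- describe_elements(moved)
  for (nm in c("ID", "CH", "D", "TA", "TP")) {
    expect_equal(d1[[nm]], d0[[nm]], tolerance = 1e-9)
  }
})

test_that("discards are counted, never hidden", {
  pcs <- sample_points(small_cs(n = 4, generations = 6, seed = 8,
                                radius_policy = radius_policy("equal", mean = 30)))
  results <- lapply(pcs, shape_elements,
                    cs = small_cs(n = 4, radius_policy = radius_policy("equal", mean = 30)))
  n_keep <- sum(!vapply(results, `[[`, logical(1), "discarded"))
  n_drop <- sum(vapply(results, `[[`, logical(1), "discarded"))
  expect_identical(n_keep + n_drop, 6L)
})

test_that("generation is deterministic under a fixed seed", {
  cs <- comparison_cs(5, generations = 2, seed = 77)
  s1 <- generate_stimuli(cs)
  s2 <- generate_stimuli(cs)
  expect_identical(lapply(s1$arrays, `[[`, "elements"),
                   lapply(s2$arrays, `[[`, "elements"))
})
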