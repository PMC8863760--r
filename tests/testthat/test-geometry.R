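# Descriptor layer: per-shape geometry and the six physical variables.

test_that("shape areas and perimeters match closed forms", {
  expect_equal(shape_area("circle", 1), pi)
  expect_equal(shape_area("square", 2), 4)
  expect_equal(shape_area("diamond", 2), 4)
  expect_equal(shape_area("triangle", 2), sqrt(3))
  expect_equal(shape_perimeter("circle", 1), 2 * pi)
  expect_equal(shape_perimeter("diamond", 3), 12)
  expect_equal(shape_perimeter("triangle", 3), 9)
  expect_error(shape_area("circle", -1), class = "numstim_invalid_parameter")
  expect_error(shape_perimeter("square", 0), class = "numstim_invalid_parameter")
})

test_that("area and perimeter obey the scaling laws for every shape", {
  for (shape in c("circle", "square", "diamond", "triangle")) {
    for (k in c(0.5, 2, 7.3)) {
      expect_equal(shape_area(shape, k * 1.7), k^2 * shape_area(shape, 1.7))
      expect_equal(shape_perimeter(shape, k * 1.7), k * shape_perimeter(shape, 1.7))
    }
  }
})

test_that("inter-distance is the mean over all unordered pairs", {
  expect_equal(inter_distance(rbind(c(0, 0), c(3, 4))), 5)
  tri <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2)) # unit equilateral
  expect_equal(inter_distance(tri), 1)
  expect_error(inter_distance(rbind(c(0, 0))), class = "numstim_undefined_descriptor")
})

test_that("inter-distance is translation- and rotation-invariant", {
  set.seed(42)
  pts <- matrix(rnorm(20), ncol = 2)
  base <- inter_distance(pts)
  shifted <- sweep(pts, 2, c(13.7, -2.2), "+")
  th <- 0.83
  rot <- pts %*% matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  expect_equal(inter_distance(shifted), base)
  expect_equal(inter_distance(rot), base)
})

test_that("convex hull of a single element equals its area", {
  el <- circle_elements(0, 0, 10)
  expect_equal(convex_hull_area(el), 100 * pi)
  sq <- circle_elements(3, -2, 4, shape = "square")
  expect_equal(convex_hull_area(sq), 16)
})

test_that("convex hull matches analytic value for two distant discs", {
  # hull of two unit discs 10 apart: 10 x 2 rectangle plus two half-discs
  el <- circle_elements(c(0, 10), c(0, 0), c(1, 1))
  analytic <- 20 + pi
  got <- convex_hull_area(el, boundary_samples = 256)
  expect_lt(abs(got - analytic) / analytic, 1e-3)
  # dense-sampling oracle at 16x the default density agrees even closer
  oracle <- convex_hull_area(el, boundary_samples = 4096)
  expect_lt(abs(got - oracle) / oracle, 2e-4)
})

test_that("hull of four axis-aligned squares is the outer square", {
  el <- tibble::tibble(
    shape = "square",
    x = c(-5, 5, 5, -5), y = c(-5, -5, 5, 5), R = 2
  )
  expect_equal(convex_hull_area(el), 144)
})

test_that("element hull always contains the centre hull", {
  set.seed(7)
  for (i in 1:10) {
    n <- sample(3:8, 1)
    el <- circle_elements(runif(n, -50, 50), runif(n, -50, 50), runif(n, 1, 5),
                          shape = sample(c("circle", "square", "diamond", "triangle"), 1))
    centre_hull <- numstim:::points_hull_area(cbind(el$x, el$y))
    expect_gte(convex_hull_area(el), centre_hull)
  }
})

test_that("hull area converges as boundary sampling is refined", {
  el <- circle_elements(c(0, 12, 5), c(0, 0, 9), c(2, 3, 1.5))
  a256 <- convex_hull_area(el, 256)
  a512 <- convex_hull_area(el, 512)
  expect_lt(abs(a512 - a256) / a256, 1e-4) # < 0.01%
})

test_that("density is n/CH and undefined for a single element", {
  expect_equal(density_of(10, 150000), 10 / 150000)
  expect_equal(density_of(2, 1), 2)
  expect_error(density_of(1, 100), class = "numstim_undefined_descriptor")
})

test_that("total area and perimeter are additive over mixed shapes", {
  el <- tibble::tibble(shape = c("circle", "square"), x = c(0, 10), y = 0, R = c(1, 2))
  expect_equal(total_area(el), pi + 4)
  expect_equal(total_perimeter(el), 2 * pi + 8)
  n <- 20
  eq <- circle_elements(seq(0, 190, by = 10), rep(0, n), rep(sqrt(600 / (n * pi)), n))
  expect_equal(total_area(eq), 600)
  expect_error(total_area(tibble::tibble()), class = "numstim_invalid_parameter")
})

test_that("describe omits ID and D for n = 1 and satisfies D*CH = n", {
  one <- describe_elements(circle_elements(0, 0, 3))
  expect_named(one, c("CH", "TA", "TP", "Rmin", "Rmax"))
  set.seed(3)
  for (i in 1:8) {
    n <- sample(2:9, 1)
    el <- circle_elements(runif(n, -40, 40), runif(n, -40, 40), runif(n, 0.5, 3))
    d <- describe_elements(el)
    expect_named(d, c("ID", "CH", "D", "TA", "TP", "Rmin", "Rmax"))
    expect_equal(d$D * d$CH, n, tolerance = 1e-9)
    expect_equal(d$Rmin, min(el$R))
    expect_equal(d$Rmax, max(el$R))
  }
})
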