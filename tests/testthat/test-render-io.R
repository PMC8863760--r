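# Rasterisation and persistence.

one_disc_array <- function(R = 10, arena_r = 50) {
  stim_array(circle_elements(0, 0, R), arena("circular", arena_r))
}

test_that("rendered disc covers the expected pixel count", {
  arr <- one_disc_array(R = 10, arena_r = 50)
  # canvas 200 px over a 100-unit arena diameter: 2 px per unit
  spec <- render_spec(canvas_px = c(200, 200), arena_cm = 10, antialias = FALSE,
                      element_rgb = c(255, 255, 255), arena_rgb = c(0, 0, 0))
  img <- render_image(arr, spec)
  n_white <- sum(img[, , 1] == 1)
  expected <- pi * (10 * 2)^2
  expect_lt(abs(n_white - expected) / expected, 0.02)
})

test_that("doubling the canvas doubles the rendered diameter", {
  arr <- one_disc_array(R = 10, arena_r = 50)
  width_of <- function(px) {
    spec <- render_spec(canvas_px = c(px, px), arena_cm = 10, antialias = FALSE)
    img <- render_image(arr, spec)
    cols <- which(apply(img[, , 1] == 1, 2, any))
    diff(range(cols)) + 1
  }
  w200 <- width_of(200)
  w400 <- width_of(400)
  expect_lte(abs(w400 - 2 * w200), 2)
})

test_that("rendering is deterministic to the byte", {
  arr <- one_disc_array()
  spec <- render_spec(canvas_px = c(120, 120), arena_cm = 8)
  f1 <- withr::local_tempfile(fileext = ".png")
  f2 <- withr::local_tempfile(fileext = ".png")
  write_stimulus_png(render_image(arr, spec), f1)
  write_stimulus_png(render_image(arr, spec), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)), readBin(f2, "raw", file.size(f2)))
})

test_that("paired layouts compose two panels with the gap between", {
  a <- one_disc_array(R = 5)
  b <- one_disc_array(R = 8)
  spec_h <- render_spec(canvas_px = c(100, 80), arena_cm = 10,
                        layout = "pair_horizontal", gap_px = 10)
  img_h <- render_image(list(a, b), spec_h)
  expect_equal(dim(img_h), c(80, 210, 3))
  spec_v <- render_spec(canvas_px = c(100, 80), arena_cm = 10,
                        layout = "pair_vertical", gap_px = 6)
  expect_equal(dim(render_image(list(a, b), spec_v)), c(166, 100, 3))
  expect_error(render_image(a, spec_h), class = "numstim_invalid_parameter")
  expect_error(render_image(list(a, b), render_spec(layout = "single")),
               class = "numstim_invalid_parameter")
})

test_that("polygonal shapes render with the right area too", {
  arr <- stim_array(circle_elements(0, 0, 20, shape = "diamond"), arena("circular", 50))
  spec <- render_spec(canvas_px = c(200, 200), arena_cm = 10, antialias = FALSE)
  img <- render_image(arr, spec)
  n_white <- sum(img[, , 1] == 1)
  expect_lt(abs(n_white - 400 * 4) / (400 * 4), 0.02) # R^2 units * (2 px/unit)^2
})

test_that("autoplot draws an array as a fixed-aspect ggplot", {
  arr <- one_disc_array()
  p <- ggplot2::autoplot(arr)
  expect_s3_class(p, "ggplot")
  expect_no_error(ggplot2::ggplot_build(p))
})

test_that("saving writes one image and one metadata row per stimulus", {
  cs <- small_cs(n = 4, TA = 120, generations = 3, seed = 21,
                 radius_policy = radius_policy("free", lo = 1, hi = 4))
  set <- generate_stimuli(cs)
  dir <- withr::local_tempdir()
  paths <- save_stimulus_set(set, dir, render = render_spec(canvas_px = c(80, 80)))
  expect_length(paths$images, 3)
  expect_true(all(file.exists(paths$images)))
  md <- readr::read_csv(paths$metadata, show_col_types = FALSE)
  expect_equal(nrow(md), 3)
  # in-memory metadata repeats the stored achieved values exactly (no
  # recomputation drift); the CSV text round-trips to the last printed digit
  td <- tidy(set)
  expect_identical(td$CH, vapply(set$arrays, function(a) a$achieved$CH, numeric(1)))
  expect_identical(td$TA, vapply(set$arrays, function(a) a$achieved$TA, numeric(1)))
  expect_equal(md$CH, td$CH, tolerance = 1e-12)
  expect_equal(md$TA, td$TA, tolerance = 1e-12)
})

test_that("a saved set reloads with achieved values intact", {
  cs <- small_cs(n = 5, CH = 8000, TA = 300, generations = 2, seed = 13,
                 radius_policy = radius_policy("equal"))
  set <- generate_stimuli(cs)
  dir <- withr::local_tempdir()
  paths <- save_stimulus_set(set, dir)
  back <- load_stimulus_set(paths$set)
  expect_length(back$arrays, 2)
  for (i in 1:2) {
    a0 <- set$arrays[[i]]; a1 <- back$arrays[[i]]
    expect_equal(a1$elements$x, a0$elements$x, tolerance = 1e-12)
    expect_equal(a1$elements$R, a0$elements$R, tolerance = 1e-12)
    for (nm in names(a0$achieved)) {
      expect_equal(a1$achieved[[nm]], a0$achieved[[nm]], tolerance = 1e-12)
    }
  }
  expect_equal(back$constraints$spatial_target, list(CH = 8000))
  expect_error(save_stimulus_set(list(arrays = list()), withr::local_tempdir()),
               class = "numstim_invalid_parameter")
})
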