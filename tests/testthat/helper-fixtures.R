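# Programmatic fixtures shared across test files.

circle_elements <- function(x, y, R, shape = "circle") {
  tibble::tibble(shape = shape, x = x, y = y, R = R)
}

# A small constraint set on a radius-100 circular arena.
small_cs <- function(n = 6, shape = "circle", ..., seed = 1) {
  constraint_set(n, arena("circular", 100), shape = shape, seed = seed, ...)
}

# The feasible combination grid: one spatial target x one magnitude target x
# one radius option. Returns a tibble of cell labels and constraint sets.
combination_grid <- function(seed = 1) {
  spatial <- list(ID = list(ID = 60), D = list(D = 6 / 9000), CH = list(CH = 8000))
  magnitude <- list(TA = list(TA = 300), TP = list(TP = 120))
  policies <- list(
    R_min = radius_policy("gaussian", mean = 4, sigma = 1, fixed_min = 2.5),
    R_max = radius_policy("gaussian", mean = 4, sigma = 1, fixed_max = 6),
    R_min_max = radius_policy("gaussian", mean = 4, sigma = 1,
                              fixed_min = 2.5, fixed_max = 6),
    R_equal = radius_policy("equal"),
    R_free = radius_policy("free", lo = 2, hi = 6)
  )
  cells <- list()
  for (sp in names(spatial)) {
    for (mg in names(magnitude)) {
      for (rp in names(policies)) {
        args <- c(
          list(n = 6, arena = arena("circular", 100), shape = "circle",
               radius_policy = policies[[rp]], generations = 1, seed = seed),
          spatial[[sp]], magnitude[[mg]]
        )
        cells[[paste(sp, mg, rp, sep = "+")]] <- do.call(constraint_set, args)
      }
    }
  }
  cells
}

# The comparison-simulation configuration: equal-radius circles, convex hull
# and total area both fixed across numerosities.
comparison_cs <- function(n, generations = 20, seed = 1,
                          CH = 150000, TA = 20000, tolerance = 1e-4) {
  R <- sqrt(TA / (n * pi))
  constraint_set(
    n, arena("circular", 350), shape = "circle", CH = CH, TA = TA,
    radius_policy = radius_policy("equal"),
    accepted_error = tolerance, generations = generations, seed = seed,
    min_gap = 3 * R
  )
}
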