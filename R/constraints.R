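#' Radius policy for an array's element sizes
#'
#' Controls how element size parameters are drawn before magnitude fitting:
#' * `equal` — every element gets the same size (`mean`, default 1; a total
#'   area / perimeter target rescales it in closed form).
#' * `gaussian` — sizes are drawn from Normal(`mean`, `sigma`), truncated to
#'   `[fixed_min, fixed_max]` when pins are set. When a pin is set, the
#'   smallest (largest) draw is replaced by the pin value exactly, so the
#'   array's extreme sizes can be held fixed across arrays.
#' * `free` — sizes uniform in `[lo, hi]`; pins behave as for `gaussian`.
#'
#' @param mode `"free"`, `"equal"` or `"gaussian"`.
#' @param mean,sigma Gaussian parameters (`mean` doubles as the common value
#'   for `equal`).
#' @param fixed_min,fixed_max Optional exact pins for the smallest / largest
#'   element size in each array.
#' @param lo,hi Uniform bounds for `free` mode (defaults are filled from the
#'   arena at normalisation time: 2% and 10% of the arena radius).
#' @return An object of class `"radius_policy"`.
#' @export
radius_policy <- function(mode = c("free", "equal", "gaussian"),
                          mean = NULL, sigma = NULL,
                          fixed_min = NULL, fixed_max = NULL,
                          lo = NULL, hi = NULL) {
  mode <- match.arg(mode)
  structure(
    list(
      mode = mode, mean = mean, sigma = sigma,
      fixed_min = fixed_min, fixed_max = fixed_max, lo = lo, hi = hi
    ),
    class = "radius_policy"
  )
}

#' Specify the constraints for a stimulus set
#'
#' A constraint set holds everything the generator needs: numerosity, arena,
#' shape, at most one spatial target (`ID`, `CH` or `D`), at most one
#' magnitude target (`TA` or `TP`), a radius policy, the accepted percent
#' error, how many arrays to generate, and the seed. A variable is considered
#' satisfied when `|achieved - target| / target * 100 <= accepted_error`.
#'
#' @param n Numerosity (elements per array), >= 1.
#' @param arena An [arena()].
#' @param shape Element shape, see [shape_area()].
#' @param ID,CH,D At most one spatial target: mean inter-distance (units),
#'   convex hull area (units^2), or density (elements / unit^2; converted
#'   internally to the equivalent `CH = n / D`).
#' @param TA,TP At most one magnitude target: total area (units^2) or total
#'   perimeter (units). Fixing both is geometrically impossible (area scales
#'   with the square of element size, perimeter linearly).
#' @param radius_policy A [radius_policy()].
#' @param accepted_error Percent tolerance, default 0.01.
#' @param generations Number of arrays to generate, default 1.
#' @param seed Integer RNG seed.
#' @param min_gap,max_gap Optional neighbour-distance controls on element
#'   centres at the sampling stage: minimum pairwise centre distance and
#'   maximum nearest-neighbour distance (stimulus units).
#' @param margin Edge margin reserved inside the arena so that shaped elements
#'   cannot cross the boundary; `NULL` (default) uses the expected maximum
#'   element radius implied by the radius policy and targets.
#' @param boundary_samples Outline points per element used for hull areas.
#' @return An object of class `"constraint_set"`.
#' @examples
#' cs <- constraint_set(10, arena("circular", 350), shape = "circle",
#'                      CH = 150000, TA = 20000,
#'                      radius_policy = radius_policy("equal"))
#' validate_constraints(cs)$ok
#' @export
constraint_set <- function(n, arena, shape = "circle",
                           ID = NULL, CH = NULL, D = NULL,
                           TA = NULL, TP = NULL,
                           radius_policy = numstim::radius_policy("free"),
                           accepted_error = 0.01, generations = 1, seed = 1,
                           min_gap = 0, max_gap = Inf, margin = NULL,
                           boundary_samples = 256) {
  structure(
    list(
      n = n, arena = arena, shape = shape,
      spatial_target = compact_list(list(ID = ID, CH = CH, D = D)),
      magnitude_target = compact_list(list(TA = TA, TP = TP)),
      radius_policy = radius_policy,
      accepted_error = accepted_error,
      generations = generations, seed = seed,
      min_gap = min_gap, max_gap = max_gap, margin = margin,
      boundary_samples = boundary_samples
    ),
    class = "constraint_set"
  )
}

compact_list <- function(x) x[!vapply(x, is.null, logical(1))]

#' @export
print.constraint_set <- function(x, ...) {
  tgt <- c(unlist(x$spatial_target), unlist(x$magnitude_target))
  cat(sprintf(
    "<constraint_set> n = %s %s(s), %s arena r = %g, radius policy '%s'\n",
    x$n, x$shape, x$arena$kind, x$arena$radius, x$radius_policy$mode
  ))
  if (length(tgt)) {
    cat("  targets:", paste(sprintf("%s = %g", names(tgt), tgt), collapse = ", "),
        sprintf(" (tolerance %g%%)\n", x$accepted_error))
  } else {
    cat("  no targets (unconstrained placement)\n")
  }
  invisible(x)
}

#' Validate the geometric feasibility of a constraint set
#'
#' Checks the combination rules dictated by geometry: total area and total
#' perimeter can never be fixed together (one scales quadratically with
#' element size, the other linearly); at most one of inter-distance, convex
#' hull and density may be targeted (density determines the hull via
#' `D = n / CH`, so giving both is redundant or contradictory); targets must
#' be positive; pins must be ordered; an `equal` policy cannot carry two
#' different pins. The function is total: it always returns a report, never
#' throws for unusual-but-feasible values.
#'
#' @param cs A [constraint_set()].
#' @return A list with `ok` (logical) and `violations` (character vector,
#'   empty when `ok`).
#' @export
validate_constraints <- function(cs) {
  v <- character(0)
  if (!is.numeric(cs$n) || length(cs$n) != 1 || cs$n < 1 || cs$n != round(cs$n)) {
    v <- c(v, "`n` must be a positive integer.")
  }
  if (!inherits(cs$arena, "stim_arena")) v <- c(v, "`arena` must be an arena object.")
  if (!cs$shape %in% SHAPE_KINDS) v <- c(v, "unknown element shape.")
  st <- cs$spatial_target
  mt <- cs$magnitude_target
  if (length(st) > 1) {
    v <- c(v, sprintf(
      "at most one spatial target may be fixed; got {%s} (D determines CH via D = n/CH).",
      paste(names(st), collapse = ", ")
    ))
  }
  if (length(mt) > 1) {
    v <- c(v, "total area and total perimeter can never be fixed simultaneously.")
  }
  for (nm in names(st)) {
    if (!is.numeric(st[[nm]]) || st[[nm]] <= 0) v <- c(v, sprintf("target %s must be positive.", nm))
  }
  for (nm in names(mt)) {
    if (!is.numeric(mt[[nm]]) || mt[[nm]] <= 0) v <- c(v, sprintf("target %s must be positive.", nm))
  }
  if (isTRUE(cs$n == 1) && any(c("ID", "D") %in% names(st))) {
    v <- c(v, "ID and D are not defined for one element.")
  }
  if (!is.numeric(cs$accepted_error) || cs$accepted_error < 0) {
    v <- c(v, "`accepted_error` must be a percentage >= 0.")
  }
  if (!is.numeric(cs$generations) || cs$generations < 1) {
    v <- c(v, "`generations` must be >= 1.")
  }
  rp <- cs$radius_policy
  if (!inherits(rp, "radius_policy")) {
    v <- c(v, "`radius_policy` must be a radius_policy object.")
  } else {
    if (!is.null(rp$fixed_min) && !is.null(rp$fixed_max) && rp$fixed_min > rp$fixed_max) {
      v <- c(v, "fixed_min must not exceed fixed_max.")
    }
    if (rp$mode == "equal" && !is.null(rp$fixed_min) && !is.null(rp$fixed_max) &&
        rp$fixed_min != rp$fixed_max) {
      v <- c(v, "equal-radius policy cannot carry two different pinned radii.")
    }
    if (rp$mode == "gaussian" && (is.null(rp$mean) || !is.numeric(rp$mean) || rp$mean <= 0)) {
      v <- c(v, "gaussian radius policy requires a positive `mean`.")
    }
    if (rp$mode == "gaussian" && !is.null(rp$sigma) && rp$sigma < 0) {
      v <- c(v, "gaussian `sigma` must be >= 0.")
    }
    if (!is.null(rp$fixed_min) && rp$fixed_min <= 0) v <- c(v, "fixed_min must be positive.")
  }
  if (cs$min_gap < 0) v <- c(v, "`min_gap` must be >= 0.")
  if (cs$max_gap <= 0) v <- c(v, "`max_gap` must be positive.")
  list(ok = length(v) == 0, violations = v)
}

# Validate and throw a typed error on failure.
assert_valid <- function(cs) {
  rep <- validate_constraints(cs)
  if (!rep$ok) {
    cls <- if (any(grepl("simultaneously|at most one", rep$violations))) {
      stop_infeasible_combination(
        paste(rep$violations, collapse = "\n"),
        pair = rep$violations[1]
      )
    } else {
      stop_invalid_parameter(paste(rep$violations, collapse = "\n"))
    }
  }
  invisible(cs)
}

#' Normalise a constraint set to canonical form
#'
#' Rewrites a density target as the equivalent convex-hull target
#' (`CH = n / D`), collapses a degenerate Gaussian (`sigma = 0`, no distinct
#' pins) to the equal-radius policy, and fills `free`-policy bounds from the
#' arena (2% and 10% of the arena radius). Idempotent; requires a valid
#' constraint set.
#'
#' @param cs A [constraint_set()] that passes [validate_constraints()].
#' @return A canonical `constraint_set` in which the spatial target is one of
#'   `ID` / `CH`.
#' @export
normalize_constraints <- function(cs) {
  assert_valid(cs)
  st <- cs$spatial_target
  if ("D" %in% names(st)) {
    cs$spatial_target <- list(CH = cs$n / st$D)
  }
  rp <- cs$radius_policy
  if (rp$mode == "gaussian" && !is.null(rp$sigma) && rp$sigma == 0 &&
      is.null(rp$fixed_min) && is.null(rp$fixed_max)) {
    cs$radius_policy <- radius_policy("equal", mean = rp$mean)
  }
  if (cs$radius_policy$mode == "free") {
    cs$radius_policy$lo <- cs$radius_policy$lo %||% (0.02 * cs$arena$radius)
    cs$radius_policy$hi <- cs$radius_policy$hi %||% (0.10 * cs$arena$radius)
  }
  cs
}

# --- config file serialization ----------------------------------------------

cs_to_list <- function(cs) {
  list(
    n = cs$n,
    arena = list(kind = cs$arena$kind, radius = cs$arena$radius, colour = cs$arena$colour),
    shape = cs$shape,
    spatial_target = if (length(cs$spatial_target)) cs$spatial_target else NULL,
    magnitude_target = if (length(cs$magnitude_target)) cs$magnitude_target else NULL,
    radius_policy = compact_list(unclass(cs$radius_policy)),
    accepted_error = cs$accepted_error,
    generations = cs$generations,
    seed = cs$seed,
    min_gap = cs$min_gap,
    max_gap = if (is.finite(cs$max_gap)) cs$max_gap else NULL,
    margin = cs$margin,
    boundary_samples = cs$boundary_samples
  )
}

cs_from_list <- function(x) {
  rp <- x$radius_policy %||% list(mode = "free")
  st <- x$spatial_target %||% list()
  mt <- x$magnitude_target %||% list()
  constraint_set(
    n = x$n,
    arena = arena(x$arena$kind, x$arena$radius,
                  colour = unlist(x$arena$colour) %||% c(0, 0, 0)),
    shape = x$shape %||% "circle",
    ID = st$ID, CH = st$CH, D = st$D, TA = mt$TA, TP = mt$TP,
    radius_policy = radius_policy(
      rp$mode %||% "free", mean = rp$mean, sigma = rp$sigma,
      fixed_min = rp$fixed_min, fixed_max = rp$fixed_max,
      lo = rp$lo, hi = rp$hi
    ),
    accepted_error = x$accepted_error %||% 0.01,
    generations = x$generations %||% 1,
    seed = x$seed %||% 1,
    min_gap = x$min_gap %||% 0,
    max_gap = x$max_gap %||% Inf,
    margin = x$margin,
    boundary_samples = x$boundary_samples %||% 256
  )
}

#' Read / write a constraint set as a config file
#'
#' YAML (`.yaml` / `.yml`) or JSON (`.json`), field names matching the
#' `constraint_set` structure.
#'
#' @param cs A [constraint_set()].
#' @param path File path; the extension selects the format.
#' @return `write_constraints()` returns `path` invisibly;
#'   `read_constraints()` returns a `constraint_set`.
#' @export
write_constraints <- function(cs, path) {
  x <- cs_to_list(cs)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname write_constraints
#' @export
read_constraints <- function(path) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  cs_from_list(x)
}
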