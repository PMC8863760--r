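# Stage one of generation: seeded sampling of centre configurations whose
# spatial statistic (mean inter-distance, or convex hull area of the bare
# centres) matches the target. Raw configurations are drawn uniformly in the
# margined arena; a draw is then homothetically calibrated about its centroid
# so the statistic matches the target exactly (ID scales linearly with the
# homothety factor, the centre-hull area quadratically), and rejected if the
# calibrated points leave the arena or violate the neighbour-gap settings.

#' Geometric upper bound for a spatial target
#'
#' The convex hull of element centres can never exceed the arena area, and no
#' pair of centres can be further apart than the arena diameter (circular) or
#' diagonal (square).
#'
#' @param cs A [constraint_set()] (only the arena and target kind are used).
#' @return Named numeric upper bound for the set spatial target, or `Inf`
#'   when no spatial target is set.
#' @export
max_spatial_target <- function(cs) {
  st <- normalize_constraints(cs)$spatial_target
  if (!length(st)) return(Inf)
  kind <- names(st)[1]
  val <- switch(kind,
    CH = arena_area(cs$arena),
    ID = arena_diameter(cs$arena)
  )
  stats::setNames(val, kind)
}

# One uniform point in the margined arena.
draw_point <- function(arena, r_eff) {
  if (arena$kind == "circular") {
    repeat {
      p <- stats::runif(2, -r_eff, r_eff)
      if (sum(p^2) <= r_eff^2) return(p)
    }
  }
  stats::runif(2, -r_eff, r_eff)
}

# Expected maximum element radius implied by the policy/targets; used as the
# default edge margin so that shaped elements stay inside the arena.
expected_max_radius <- function(cs) {
  if (!is.null(cs$margin)) return(cs$margin)
  rp <- cs$radius_policy
  mt <- cs$magnitude_target
  guess <- switch(rp$mode,
    equal = {
      if (length(mt)) equal_radius_for(cs$shape, cs$n, names(mt)[1], mt[[1]])
      else rp$mean %||% 1
    },
    gaussian = rp$fixed_max %||% ((rp$mean %||% 1) + 3 * (rp$sigma %||% 0)),
    free = rp$hi %||% (0.10 * cs$arena$radius)
  )
  max(guess, rp$fixed_max %||% 0)
}

# Closed-form equal radius for n identical elements hitting a TA or TP target.
equal_radius_for <- function(shape, n, kind, value) {
  if (kind == "TA") sqrt(value / (n * shape_area(shape, 1)))
  else value / (n * shape_perimeter(shape, 1))
}

# Draw one raw configuration of n centres honouring min_gap, or NULL if the
# per-configuration retry budget is exhausted.
draw_configuration <- function(n, arena, r_eff, min_gap, tries_per_point = 200L) {
  pts <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (t in seq_len(tries_per_point)) {
      p <- draw_point(arena, r_eff)
      if (i == 1 || min_gap == 0) { ok <- TRUE; break }
      d2 <- (pts[seq_len(i - 1), 1] - p[1])^2 + (pts[seq_len(i - 1), 2] - p[2])^2
      if (all(d2 >= min_gap^2)) { ok <- TRUE; break }
    }
    if (!ok) return(NULL)
    pts[i, ] <- p
  }
  pts
}

spatial_statistic <- function(centres, kind) {
  switch(kind,
    ID = inter_distance(centres),
    CH = points_hull_area(centres)
  )
}

check_gaps <- function(centres, min_gap, max_gap) {
  if (nrow(centres) < 2) return(TRUE)
  d <- as.matrix(stats::dist(centres))
  diag(d) <- Inf
  if (min_gap > 0 && min(d) < min_gap) return(FALSE)
  if (is.finite(max_gap) && max(apply(d, 1, min)) > max_gap) return(FALSE)
  TRUE
}

# Draw + calibrate until one acceptable configuration is found (or budget
# runs out). Returns list(centres, achieved, attempts) or NULL.
sample_one_configuration <- function(cs, kind, target, r_eff, attempt_cap) {
  attempts <- 0L
  best <- NULL
  best_err <- Inf
  tol <- cs$accepted_error
  while (attempts < attempt_cap) {
    attempts <- attempts + 1L
    pts <- draw_configuration(cs$n, cs$arena, r_eff, cs$min_gap)
    if (is.null(pts)) next
    if (is.null(kind)) {
      if (!check_gaps(pts, cs$min_gap, cs$max_gap)) next
      return(list(centres = pts, achieved = list(), attempts = attempts))
    }
    raw <- spatial_statistic(pts, kind)
    if (raw <= 0) next
    s <- if (kind == "ID") target / raw else sqrt(target / raw)
    ctr <- colMeans(pts)
    cal <- sweep(sweep(pts, 2, ctr), 1, rep(s, nrow(pts)), "*")
    cal <- sweep(cal, 2, ctr, "+")
    if (!all(points_in_arena(cal, cs$arena, margin = r_margin_of(cs, r_eff)))) next
    if (!check_gaps(cal, 0, cs$max_gap)) next
    achieved <- spatial_statistic(cal, kind)
    err <- abs(achieved - target) / target * 100
    if (err < best_err) {
      best_err <- err
      best <- list(centres = cal, achieved = stats::setNames(list(achieved), kind),
                   attempts = attempts)
    }
    if (err <= tol) return(best)
  }
  if (is.null(best)) return(NULL)
  attr(best, "exhausted") <- TRUE
  best
}

r_margin_of <- function(cs, r_eff) cs$arena$radius - r_eff

#' Sample centre configurations satisfying the spatial target
#'
#' Generates `cs$generations` point configurations inside the arena (shrunk by
#' an edge margin equal to the expected maximum element radius, so that later
#' shaping cannot cross the boundary). When a spatial target (`ID`, `CH` or
#' `D`, the latter converted to `CH = n/D`) is set, every returned
#' configuration matches it within `cs$accepted_error` percent, evaluated on
#' the bare centres. Fully reproducible from `cs$seed`.
#'
#' @param cs A valid [constraint_set()].
#' @param attempt_cap Maximum raw draws per configuration before failing with
#'   a budget-exhausted error that carries the best candidate found.
#' @return A list of `point_config` objects, each with `centres` (n x 2
#'   matrix), `spatial_achieved` (named list) and `attempts`.
#' @export
sample_points <- function(cs, attempt_cap = 1e6) {
  cs <- normalize_constraints(cs)
  st <- cs$spatial_target
  kind <- if (length(st)) names(st)[1] else NULL
  target <- if (length(st)) st[[1]] else NULL
  if (!is.null(kind)) {
    if (cs$n < 2) stop_invalid_parameter("Spatial targets require n >= 2.")
    bound <- max_spatial_target(cs)
    if (target > bound) {
      stop_infeasible_geometry(sprintf(
        "%s target %g exceeds the arena bound %g.", kind, target, bound
      ))
    }
  }
  margin <- expected_max_radius(cs)
  r_eff <- cs$arena$radius - margin
  if (r_eff <= 0) {
    stop_infeasible_geometry("Arena too small for the expected element size.")
  }
  set.seed(cs$seed)
  out <- vector("list", cs$generations)
  for (g in seq_len(cs$generations)) {
    conf <- sample_one_configuration(cs, kind, target, r_eff, attempt_cap)
    if (is.null(conf) || isTRUE(attr(conf, "exhausted"))) {
      stop_budget_exhausted(
        sprintf("No acceptable configuration within %g raw draws.", attempt_cap),
        best = conf
      )
    }
    out[[g]] <- structure(
      list(centres = conf$centres, spatial_achieved = conf$achieved,
           attempts = conf$attempts),
      class = "point_config"
    )
  }
  out
}
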