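# Stage two of generation: give each accepted point configuration shaped,
# sized elements that hit the magnitude target (total area or perimeter) under
# the radius policy, then homothetically refine the positions so the convex
# hull computed on the element outlines matches the CH target.

#' Draw element size parameters under a radius policy
#'
#' `equal` returns `n` identical values; `gaussian` draws from
#' Normal(mean, sigma) truncated to positive values and to
#' `[fixed_min, fixed_max]` when pins are set; `free` draws uniformly in
#' `[lo, hi]`. When `fixed_min` (`fixed_max`) is set, the smallest (largest)
#' draw is replaced by the pin value exactly, so the extreme element sizes are
#' identical across arrays.
#'
#' @param policy A [radius_policy()].
#' @param n Number of elements.
#' @param seed Optional seed; omit to draw from the current RNG stream.
#' @param draw_cap Truncation retry budget (total draws) before a
#'   budget-exhausted error.
#' @return Numeric vector of `n` sizes; attribute `"pinned"` flags the entries
#'   fixed by pins.
#' @export
draw_radii <- function(policy, n, seed = NULL, draw_cap = 1000 * n) {
  if (!is.null(seed)) set.seed(seed)
  lo_pin <- policy$fixed_min
  hi_pin <- policy$fixed_max
  if (policy$mode == "equal") {
    r <- rep(policy$mean %||% lo_pin %||% hi_pin %||% 1, n)
    pinned <- rep(FALSE, n)
  } else {
    lo <- lo_pin %||% .Machine$double.eps
    hi <- hi_pin %||% Inf
    r <- numeric(0)
    used <- 0L
    while (length(r) < n) {
      need <- n - length(r)
      cand <- if (policy$mode == "gaussian") {
        stats::rnorm(need, policy$mean, policy$sigma %||% 0)
      } else {
        stats::runif(need, policy$lo %||% lo, policy$hi %||% max(1, lo))
      }
      used <- used + need
      r <- c(r, cand[cand > 0 & cand >= lo & cand <= hi])
      if (used > draw_cap) {
        stop_budget_exhausted(
          "Truncated radius distribution yielded too few acceptable draws."
        )
      }
    }
    pinned <- rep(FALSE, n)
    if (!is.null(lo_pin)) {
      i <- which.min(r); r[i] <- lo_pin; pinned[i] <- TRUE
    }
    if (!is.null(hi_pin)) {
      i <- which.max(replace(r, pinned, -Inf))
      r[i] <- hi_pin; pinned[i] <- TRUE
    }
  }
  structure(r, pinned = pinned)
}

#' Rescale radii to meet a total-area or total-perimeter target
#'
#' Total perimeter is linear in element size, total area quadratic, so free
#' radii are rescaled by `target/current` (TP) or `sqrt(target/current)` (TA).
#' Pinned radii (exact `fixed_min` / `fixed_max` values) are left untouched
#' and the scale is solved on the residual target; the fit fails when the
#' pinned elements alone already exceed the target.
#'
#' @param radii Numeric vector from [draw_radii()] (the `"pinned"` attribute
#'   marks pins; absent means none).
#' @param shape Element shape.
#' @param kind `"TA"` or `"TP"`.
#' @param value Target value.
#' @return Radii meeting the target exactly (up to floating point), with the
#'   `"pinned"` attribute preserved.
#' @export
fit_magnitude <- function(radii, shape, kind = c("TA", "TP"), value) {
  kind <- match.arg(kind)
  if (!is.numeric(value) || value <= 0) stop_invalid_parameter("target must be positive.")
  pinned <- attr(radii, "pinned") %||% rep(FALSE, length(radii))
  unit <- if (kind == "TA") shape_area(shape, 1) else shape_perimeter(shape, 1)
  pow <- if (kind == "TA") 2 else 1
  contrib <- unit * radii^pow
  pinned_total <- sum(contrib[pinned])
  resid <- value - pinned_total
  if (resid <= 0) {
    stop_pins_exceed_target(sprintf(
      "Pinned radii alone give %s = %g, at or above the target %g.",
      kind, pinned_total, value
    ))
  }
  free_total <- sum(contrib[!pinned])
  if (free_total == 0) {
    stop_invalid_parameter("No free radii left to meet the residual target.")
  }
  s <- (resid / free_total)^(1 / pow)
  out <- radii
  out[!pinned] <- radii[!pinned] * s
  structure(as.numeric(out), pinned = pinned)
}

#' Shrink element positions until the shaped convex hull meets its target
#'
#' Shaping elements around accepted centre points can only enlarge the
#' effective convex hull beyond the centre-stage value, so the positions are
#' moved towards their (unweighted) centre of mass until the hull computed on
#' the element outlines matches the target. Each iteration shrinks every
#' centre's distance to the centre of mass by the fraction `step` (a
#' homothety, which preserves the configuration's shape); once a full step
#' would cross the target, the homothety factor is bisected so the final hull
#' lands inside the tolerance. The hull is non-increasing across iterations.
#'
#' @param elements Element tibble (`shape`, `x`, `y`, `R`).
#' @param CH_target Target hull area (units^2).
#' @param accepted_error Percent tolerance.
#' @param step Fractional move per iteration towards the centre of mass
#'   (default 0.005, i.e. 0.5% of the current distance).
#' @param max_iter Iteration cap.
#' @param boundary_samples Outline sampling density for the hull.
#' @param trace If `TRUE`, attach the per-iteration hull areas as attribute
#'   `"trace"`.
#' @param check_overlap If `TRUE` (default), raise an
#'   overlap-before-convergence error when the shrink forces two elements to
#'   intersect (positions are scaled, never reordered, so overlap can only
#'   appear at the final, smallest homothety factor).
#' @return List with `elements` (refined tibble), `iterations`, `CH`.
#' @export
refine_to_hull <- function(elements, CH_target, accepted_error = 0.01,
                           step = 0.005, max_iter = 1e4,
                           boundary_samples = 256, trace = FALSE,
                           check_overlap = TRUE) {
  if (CH_target <= 0) stop_invalid_parameter("`CH_target` must be positive.")
  tol <- accepted_error / 100
  com <- c(mean(elements$x), mean(elements$y))
  at_lambda <- function(lam) {
    el <- elements
    el$x <- com[1] + lam * (elements$x - com[1])
    el$y <- com[2] + lam * (elements$y - com[2])
    el
  }
  ch_of <- function(lam) convex_hull_area(at_lambda(lam), boundary_samples)
  iter <- 0L
  tr <- numeric(0)
  lam <- 1
  ch <- ch_of(1)
  if (trace) tr <- ch
  if (abs(ch - CH_target) / CH_target <= tol) {
    res <- list(elements = elements, iterations = 0L, CH = ch)
    if (trace) attr(res, "trace") <- tr
    return(res)
  }
  if (ch < CH_target) {
    stop_infeasible_geometry(
      "Shaped hull is already below the CH target; cannot shrink to meet it."
    )
  }
  lo <- NULL # bracket: ch(lo) < target <= ch(hi)
  hi <- lam
  ch_hi <- ch
  repeat {
    iter <- iter + 1L
    if (iter > max_iter) stop_max_iterations("CH refinement exceeded max_iter.")
    if (is.null(lo)) {
      cand <- hi * (1 - step)
      ch_c <- ch_of(cand)
      if (ch_c >= CH_target) {
        hi <- cand; ch_hi <- ch_c
        if (trace) tr <- c(tr, ch_c)
        if (abs(ch_c - CH_target) / CH_target <= tol) { lam <- cand; ch <- ch_c; break }
      } else {
        lo <- cand
      }
    } else {
      cand <- (lo + hi) / 2
      ch_c <- ch_of(cand)
      if (ch_c >= CH_target) {
        hi <- cand; ch_hi <- ch_c
        if (trace) tr <- c(tr, ch_c)
        if (abs(ch_c - CH_target) / CH_target <= tol) { lam <- cand; ch <- ch_c; break }
      } else {
        if (abs(ch_c - CH_target) / CH_target <= tol) {
          if (trace) tr <- c(tr, ch_c)
          lam <- cand; ch <- ch_c; break
        }
        lo <- cand
      }
      if (hi - lo < 1e-15) stop_max_iterations("CH refinement bisection stalled.")
    }
  }
  refined <- at_lambda(lam)
  if (check_overlap && any_overlap(refined)) {
    stop_overlap("Shrinking to the CH target forced two elements to intersect.")
  }
  res <- list(elements = refined, iterations = iter, CH = ch)
  if (trace) attr(res, "trace") <- tr
  res
}

#' Derive a magnitude target for a congruent / incongruent / balanced stimulus
#'
#' Given a base array's magnitude value (for example total area) at base
#' numerosity, returns the target for a new numerosity under the three
#' classical conditions: `balanced` keeps the value constant, `congruent`
#' scales it with numerosity (value doubles when numerosity doubles),
#' `incongruent` scales it against numerosity (value halves when numerosity
#' doubles).
#'
#' @param base_value Magnitude value of the reference condition (> 0).
#' @param base_n,new_n Reference and new numerosities (>= 1).
#' @param mode `"balanced"`, `"congruent"` or `"incongruent"`.
#' @return The derived target value.
#' @examples
#' derive_congruency_target(600, 20, 40, "balanced")    # 600
#' derive_congruency_target(600, 20, 40, "congruent")   # 1200
#' derive_congruency_target(600, 20, 40, "incongruent") # 300
#' @export
derive_congruency_target <- function(base_value, base_n, new_n,
                                     mode = c("balanced", "congruent", "incongruent")) {
  mode <- match.arg(mode)
  if (base_value <= 0 || base_n < 1 || new_n < 1) {
    stop_invalid_parameter("base_value must be positive and numerosities >= 1.")
  }
  switch(mode,
    balanced = base_value,
    congruent = base_value * new_n / base_n,
    incongruent = base_value * base_n / new_n
  )
}

discard_result <- function(reason) {
  structure(
    list(array = NULL, refinement_iterations = 0L, discarded = TRUE, reason = reason),
    class = "shaping_result"
  )
}

#' Shape an accepted point configuration into a stimulus array
#'
#' Draws radii under the policy, rescales them to the magnitude target, places
#' the shaped elements on the sampled centres, and (when a CH target is set)
#' refines positions until the outline hull matches it. Configurations whose
#' elements overlap, leave the arena, or cannot meet a constraint are returned
#' as discarded results with a reason, never silently dropped.
#'
#' @param points A `point_config` from [sample_points()].
#' @param cs The originating [constraint_set()].
#' @param seed Optional seed for the radius draw; omit to use the current
#'   stream.
#' @param allow_overlap If `TRUE`, overlapping elements are not discarded.
#' @return A `shaping_result`: list with `array` (`stim_array` or `NULL`),
#'   `refinement_iterations`, `discarded`, `reason`.
#' @export
shape_elements <- function(points, cs, seed = NULL, allow_overlap = FALSE) {
  cs <- normalize_constraints(cs)
  st <- cs$spatial_target
  mt <- cs$magnitude_target
  n <- cs$n
  radii <- tryCatch(
    draw_radii(cs$radius_policy, n, seed = seed),
    numstim_budget_exhausted = function(e) e
  )
  if (inherits(radii, "condition")) return(discard_result(conditionMessage(radii)))
  if (length(mt)) {
    radii <- tryCatch(
      fit_magnitude(radii, cs$shape, names(mt)[1], mt[[1]]),
      error = function(e) e
    )
    if (inherits(radii, "condition")) return(discard_result(conditionMessage(radii)))
    pins <- c(cs$radius_policy$fixed_min, cs$radius_policy$fixed_max)
    if (!is.null(cs$radius_policy$fixed_min) && min(radii) < cs$radius_policy$fixed_min) {
      return(discard_result("magnitude fit pushed a free radius below fixed_min"))
    }
    if (!is.null(cs$radius_policy$fixed_max) && max(radii) > cs$radius_policy$fixed_max) {
      return(discard_result("magnitude fit pushed a free radius above fixed_max"))
    }
  }
  el <- tibble::tibble(
    shape = cs$shape,
    x = points$centres[, 1], y = points$centres[, 2],
    R = as.numeric(radii)
  )
  inside <- all(vapply(seq_len(n), function(i) {
    element_in_arena(el$shape[i], el$x[i], el$y[i], el$R[i], cs$arena)
  }, logical(1)))
  if (!inside) return(discard_result("shaped element crossed the arena boundary"))
  iters <- 0L
  if ("CH" %in% names(st) && n >= 2) {
    ref <- tryCatch(
      refine_to_hull(el, st$CH, cs$accepted_error,
                     boundary_samples = cs$boundary_samples),
      error = function(e) e
    )
    if (inherits(ref, "condition")) return(discard_result(conditionMessage(ref)))
    el <- ref$elements
    iters <- ref$iterations
  }
  if (!allow_overlap && any_overlap(el)) {
    return(discard_result("elements overlap"))
  }
  arr <- stim_array(el, cs$arena, seed = cs$seed,
                    constraint_ref = cs_label(cs),
                    boundary_samples = cs$boundary_samples)
  targets <- c(st, mt)
  errs <- list()
  for (nm in names(targets)) {
    ach <- arr$achieved[[nm]]
    errs[[nm]] <- abs(ach - targets[[nm]]) / targets[[nm]] * 100
  }
  arr$errors <- errs
  if (length(errs) && any(unlist(errs) > cs$accepted_error + 1e-12)) {
    bad <- names(errs)[unlist(errs) > cs$accepted_error + 1e-12]
    return(discard_result(sprintf(
      "constrained variable(s) %s outside tolerance", paste(bad, collapse = ", ")
    )))
  }
  structure(
    list(array = arr, refinement_iterations = iters, discarded = FALSE, reason = NA_character_),
    class = "shaping_result"
  )
}

cs_label <- function(cs) {
  tgt <- c(unlist(cs$spatial_target), unlist(cs$magnitude_target))
  paste0(
    "n", cs$n, "_", cs$shape, "_", cs$radius_policy$mode,
    if (length(tgt)) paste0("_", paste(names(tgt), signif(tgt, 6), sep = "", collapse = "_"))
  )
}
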