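#' Generate a set of constraint-satisfying stimulus arrays
#'
#' The main entry point: runs the two-stage pipeline (centre sampling, then
#' shaping and hull refinement) until `cs$generations` arrays satisfy every
#' constrained variable within `cs$accepted_error` percent. Configurations
#' that fail shaping (element overlap, boundary crossing, infeasible radius
#' pins) are counted as discards and re-sampled; the discard count is reported
#' on the result, never hidden. The whole run is reproducible from `cs$seed`.
#'
#' @param cs A [constraint_set()].
#' @param max_attempts Cap on shaping attempts (default `100 * generations`);
#'   exceeding it raises a budget-exhausted error carrying the arrays
#'   collected so far.
#' @param attempt_cap Raw-draw budget per centre configuration, passed to the
#'   sampler.
#' @return A `stim_set`: list with `constraints`, `arrays` (list of
#'   [stim_array()]), `n_discarded`, `seed`, `version`.
#' @examples
#' cs <- constraint_set(5, arena("circular", 100), shape = "circle",
#'                      TA = 300, radius_policy = radius_policy("equal"),
#'                      generations = 2, seed = 42)
#' set <- generate_stimuli(cs)
#' tidy(set)
#' @export
generate_stimuli <- function(cs, max_attempts = 100 * cs$generations,
                             attempt_cap = 1e6) {
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
  if (r_eff <= 0) stop_infeasible_geometry("Arena too small for the expected element size.")
  set.seed(cs$seed)
  arrays <- list()
  discarded <- 0L
  attempts <- 0L
  while (length(arrays) < cs$generations) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop_budget_exhausted(
        sprintf("Only %d/%d arrays after %d shaping attempts.",
                length(arrays), cs$generations, max_attempts),
        best = arrays
      )
    }
    conf <- sample_one_configuration(cs, kind, target, r_eff, attempt_cap)
    if (is.null(conf) || isTRUE(attr(conf, "exhausted"))) {
      stop_budget_exhausted("Centre sampling budget exhausted.", best = arrays)
    }
    pc <- structure(
      list(centres = conf$centres, spatial_achieved = conf$achieved,
           attempts = conf$attempts),
      class = "point_config"
    )
    res <- shape_elements(pc, cs)
    if (res$discarded) {
      discarded <- discarded + 1L
    } else {
      arrays[[length(arrays) + 1L]] <- res$array
    }
  }
  structure(
    list(
      constraints = cs,
      arrays = arrays,
      n_discarded = discarded,
      seed = cs$seed,
      version = as.character(utils::packageVersion("numstim"))
    ),
    class = "stim_set"
  )
}

#' @export
print.stim_set <- function(x, ...) {
  cat(sprintf(
    "<stim_set> %d array(s) of n = %d (%d discarded during generation)\n",
    length(x$arrays), x$constraints$n, x$n_discarded
  ))
  print(tidy(x), n = 5)
  invisible(x)
}

#' Tidy a stimulus set into a per-array metadata tibble
#'
#' One row per array with numerosity, achieved physical variables, relative
#' errors of the constrained ones, and seed.
#'
#' @param x A `stim_set`.
#' @param ... Unused.
#' @return A tibble with one row per array and an `id` column.
#' @export
tidy.stim_set <- function(x, ...) {
  rows <- purrr::map_dfr(x$arrays, tidy)
  dplyr::bind_cols(tibble::tibble(id = seq_len(nrow(rows))), rows)
}

#' One-row summary of a stimulus set
#'
#' @param x A `stim_set`.
#' @param ... Unused.
#' @return A tibble with the array count, discard count, and mean achieved
#'   values across arrays.
#' @export
glance.stim_set <- function(x, ...) {
  td <- tidy(x)
  tibble::tibble(
    n_arrays = nrow(td),
    n_discarded = x$n_discarded,
    n = x$constraints$n,
    mean_CH = mean(td$CH),
    mean_TA = mean(td$TA),
    mean_TP = mean(td$TP),
    mean_ID = mean(td$ID),
    max_err = if (any(grepl("^err_", names(td)))) {
      max(as.matrix(td[grepl("^err_", names(td))]))
    } else {
      NA_real_
    },
    seed = x$seed
  )
}
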