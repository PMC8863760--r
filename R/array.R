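#' Construct a stimulus array
#'
#' A stimulus array couples an element table with its arena and the achieved
#' values of the physical variables. Most users never call this directly:
#' arrays are produced by [generate_stimuli()].
#'
#' @param elements Tibble with columns `shape`, `x`, `y`, `R` (one row per
#'   element, n >= 1).
#' @param arena A [arena()] object.
#' @param seed Integer seed recorded for provenance.
#' @param constraint_ref Identifier of the constraint set that produced the
#'   array.
#' @param errors Named list of relative errors in percent for the constrained
#'   variables (may be empty).
#' @param boundary_samples Outline sampling density used for the achieved CH.
#' @return An object of class `"stim_array"` with fields `elements`, `arena`,
#'   `achieved`, `errors`, `seed`, `constraint_ref`.
#' @export
stim_array <- function(elements, arena, seed = NA_integer_,
                       constraint_ref = NA_character_, errors = list(),
                       boundary_samples = 256) {
  elements <- tibble::as_tibble(elements)
  stopifnot(all(c("shape", "x", "y", "R") %in% names(elements)))
  if (nrow(elements) < 1) stop_invalid_parameter("An array needs at least one element.")
  check_R(elements$R)
  for (i in seq_len(nrow(elements))) {
    check_shape(elements$shape[i])
    if (!element_in_arena(elements$shape[i], elements$x[i], elements$y[i],
                          elements$R[i], arena)) {
      stop_invalid_parameter(sprintf("Element %d lies outside the arena.", i))
    }
  }
  structure(
    list(
      elements = elements[, c("shape", "x", "y", "R")],
      arena = arena,
      achieved = describe_elements(elements, boundary_samples),
      errors = errors,
      seed = seed,
      constraint_ref = constraint_ref
    ),
    class = "stim_array"
  )
}

#' @export
print.stim_array <- function(x, ...) {
  a <- x$achieved
  cat(sprintf(
    "<stim_array> n = %d %s(s), %s arena r = %g\n",
    nrow(x$elements), x$elements$shape[1], x$arena$kind, x$arena$radius
  ))
  cat("  achieved:", paste(sprintf("%s = %.6g", names(a), unlist(a)), collapse = ", "), "\n")
  invisible(x)
}

achieved_row <- function(array) {
  a <- array$achieved
  tibble::tibble(
    n = nrow(array$elements),
    shape = array$elements$shape[1],
    ID = a$ID %||% NA_real_,
    CH = a$CH,
    D = a$D %||% NA_real_,
    TA = a$TA,
    TP = a$TP,
    Rmin = a$Rmin,
    Rmax = a$Rmax
  )
}

#' Tidy a stimulus array into a one-row tibble of achieved values
#'
#' @param x A `stim_array`.
#' @param ... Unused.
#' @return A tibble with columns `n`, `shape`, `ID`, `CH`, `D`, `TA`, `TP`,
#'   `Rmin`, `Rmax` plus one `err_*` column per constrained variable.
#' @export
tidy.stim_array <- function(x, ...) {
  row <- achieved_row(x)
  if (length(x$errors)) {
    err <- tibble::as_tibble(stats::setNames(
      as.list(unlist(x$errors)), paste0("err_", names(x$errors))
    ))
    row <- dplyr::bind_cols(row, err)
  }
  dplyr::mutate(row, seed = x$seed, .after = "Rmax")
}

#' Plot a stimulus array
#'
#' Draws the arena outline and every element as a filled polygon (circles are
#' drawn as fine polygons), on a fixed-aspect coordinate system in stimulus
#' units.
#'
#' @param object A `stim_array`.
#' @param ... Unused.
#' @param fill Element fill colour.
#' @return A ggplot object.
#' @export
autoplot.stim_array <- function(object, ..., fill = "grey20") {
  el <- object$elements
  poly <- purrr::map_dfr(seq_len(nrow(el)), function(i) {
    p <- boundary_points(el$shape[i], el$x[i], el$y[i], el$R[i], n = 90)
    tibble::tibble(id = i, x = p[, 1], y = p[, 2])
  })
  ar <- object$arena
  outline <- if (ar$kind == "circular") {
    th <- seq(0, 2 * pi, length.out = 181)
    tibble::tibble(x = ar$radius * cos(th), y = ar$radius * sin(th))
  } else {
    r <- ar$radius
    tibble::tibble(x = c(-r, r, r, -r, -r), y = c(-r, -r, r, r, -r))
  }
  ggplot2::ggplot(poly, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(data = outline, colour = "grey60") +
    ggplot2::geom_polygon(ggplot2::aes(group = .data$id), fill = fill) +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
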