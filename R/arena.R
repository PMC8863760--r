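#' Define the arena that bounds a stimulus array
#'
#' The arena is the field in which elements are placed: a disc of the given
#' radius centred at the origin, or a square of half-side `radius` (so the
#' bounding box is `[-radius, radius]^2` in both cases). All constraint
#' mathematics happens in continuous stimulus units with the origin at the
#' arena centre and the y-axis pointing up; conversion to pixels happens only
#' at render time.
#'
#' @param kind `"circular"` or `"square"`.
#' @param radius Arena radius in stimulus units; for a square arena, half the
#'   side length. Must be positive.
#' @param colour RGB triple in `[0, 255]` used as the arena fill at render
#'   time.
#' @return An object of class `"stim_arena"`.
#' @examples
#' arena("circular", 350)
#' arena("square", 100, colour = c(128, 128, 128))
#' @export
arena <- function(kind = c("circular", "square"), radius, colour = c(0, 0, 0)) {
  kind <- match.arg(kind)
  if (!is.numeric(radius) || length(radius) != 1 || !is.finite(radius) || radius <= 0) {
    stop_invalid_parameter("`radius` must be a single positive number.")
  }
  if (!is.numeric(colour) || length(colour) != 3 || any(colour < 0 | colour > 255)) {
    stop_invalid_parameter("`colour` must be an RGB triple in [0, 255].")
  }
  structure(
    list(kind = kind, radius = as.numeric(radius), colour = as.numeric(colour)),
    class = "stim_arena"
  )
}

#' @export
print.stim_arena <- function(x, ...) {
  cat(sprintf("<stim_arena> %s, radius %g units\n", x$kind, x$radius))
  invisible(x)
}

arena_area <- function(arena) {
  switch(arena$kind,
    circular = pi * arena$radius^2,
    square   = (2 * arena$radius)^2
  )
}

# Largest centre-to-centre distance the arena can host.
arena_diameter <- function(arena) {
  switch(arena$kind,
    circular = 2 * arena$radius,
    square   = 2 * arena$radius * sqrt(2)
  )
}

# TRUE if every point (matrix nx2) lies inside the arena shrunk by `margin`.
points_in_arena <- function(xy, arena, margin = 0) {
  r <- arena$radius - margin
  if (r <= 0) return(rep(FALSE, nrow(xy)))
  if (arena$kind == "circular") {
    rowSums(xy^2) <= r^2 + 1e-12
  } else {
    abs(xy[, 1]) <= r + 1e-12 & abs(xy[, 2]) <= r + 1e-12
  }
}
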