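# The six continuous physical variables of a stimulus array:
#   ID  mean inter-distance between element centres (all unordered pairs)
#   CH  convex hull area of the union of element outlines
#   D   density, n / CH
#   TA  total (summed) element area
#   TP  total (summed) element perimeter
#   R   element size (reported as Rmin / Rmax)

#' Mean inter-distance between element centres
#'
#' The average over all \eqn{n(n-1)/2} unordered pairs of the Euclidean
#' distance between element centres. Undefined for a single element.
#'
#' @param centres A two-column matrix or data frame of centre coordinates.
#' @return Mean pairwise distance in stimulus units.
#' @examples
#' inter_distance(rbind(c(0, 0), c(3, 4))) # 5
#' @export
inter_distance <- function(centres) {
  centres <- as.matrix(centres)
  if (!is.numeric(centres) || ncol(centres) != 2) {
    stop_invalid_parameter("`centres` must be an n x 2 numeric matrix.")
  }
  if (nrow(centres) < 2) {
    stop_undefined_descriptor("ID is not defined for one element.")
  }
  mean(stats::dist(centres))
}

# Shoelace area of a polygon given by hull-ordered vertices.
polygon_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  j <- c(2:nrow(v), 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# Hull area of a bare point set.
points_hull_area <- function(xy) {
  if (nrow(xy) < 3) return(0)
  h <- grDevices::chull(xy)
  if (length(h) < 3) return(0)
  polygon_area(xy[h, , drop = FALSE])
}

#' Convex hull area of a stimulus array
#'
#' Area of the smallest convex polygon containing every element, computed from
#' points sampled along each element's outline (polygonal shapes always
#' contribute their true vertices). For a single element the hull is the
#' element itself, so its area is returned.
#'
#' @param elements A data frame with columns `shape`, `x`, `y`, `R`.
#' @param boundary_samples Outline points sampled per element (>= 16). The
#'   default 256 keeps the polygonal underestimate of a circular outline below
#'   0.011%.
#' @return Hull area in squared stimulus units.
#' @export
convex_hull_area <- function(elements, boundary_samples = 256) {
  if (is.null(elements) || nrow(elements) == 0) {
    stop_invalid_parameter("`elements` must contain at least one element.")
  }
  if (boundary_samples < 16) {
    stop_invalid_parameter("`boundary_samples` must be at least 16.")
  }
  if (nrow(elements) == 1) {
    return(shape_area(elements$shape[1], elements$R[1]))
  }
  pts <- do.call(rbind, lapply(seq_len(nrow(elements)), function(i) {
    boundary_points(
      elements$shape[i], elements$x[i], elements$y[i], elements$R[i],
      n = boundary_samples
    )
  }))
  points_hull_area(pts)
}

#' Density of a stimulus array
#'
#' The number of elements divided by the occupied area, `D = n / CH`.
#' Undefined for a single element.
#'
#' @param n Number of elements (>= 2).
#' @param CH Convex hull area (> 0).
#' @return Density in elements per squared stimulus unit.
#' @examples
#' density_of(10, 150000)
#' @export
density_of <- function(n, CH) {
  if (n == 1) stop_undefined_descriptor("D is not defined for one element.")
  if (!is.numeric(n) || n < 2 || n != round(n)) {
    stop_invalid_parameter("`n` must be an integer >= 2.")
  }
  if (!is.numeric(CH) || CH <= 0) stop_invalid_parameter("`CH` must be positive.")
  n / CH
}

#' Total element area and perimeter
#'
#' Sums of the per-element areas (surfaces) and perimeters (contours).
#'
#' @inheritParams convex_hull_area
#' @return Total area / total perimeter in stimulus units.
#' @export
total_area <- function(elements) {
  if (is.null(elements) || nrow(elements) == 0) {
    stop_invalid_parameter("`elements` must contain at least one element.")
  }
  sum(vapply(seq_len(nrow(elements)), function(i) {
    shape_area(elements$shape[i], elements$R[i])
  }, numeric(1)))
}

#' @rdname total_area
#' @export
total_perimeter <- function(elements) {
  if (is.null(elements) || nrow(elements) == 0) {
    stop_invalid_parameter("`elements` must contain at least one element.")
  }
  sum(vapply(seq_len(nrow(elements)), function(i) {
    shape_perimeter(elements$shape[i], elements$R[i])
  }, numeric(1)))
}

#' Compute all achieved physical variables of an element set
#'
#' Aggregates the descriptor functions into the achieved-value map stored on a
#' stimulus array: CH, TA, TP, Rmin and Rmax always; ID and D only when the
#' array has at least two elements (neither is defined for one element).
#'
#' @inheritParams convex_hull_area
#' @return A named list of achieved values.
#' @export
describe_elements <- function(elements, boundary_samples = 256) {
  if (is.null(elements) || nrow(elements) == 0) {
    stop_invalid_parameter("`elements` must contain at least one element.")
  }
  n <- nrow(elements)
  CH <- convex_hull_area(elements, boundary_samples)
  out <- list(
    CH = CH,
    TA = total_area(elements),
    TP = total_perimeter(elements),
    Rmin = min(elements$R),
    Rmax = max(elements$R)
  )
  if (n >= 2) {
    out$ID <- inter_distance(cbind(elements$x, elements$y))
    out$D <- n / CH
    out <- out[c("ID", "CH", "D", "TA", "TP", "Rmin", "Rmax")]
  }
  out
}

#' @describeIn describe_elements Achieved values of a `stim_array` object.
#' @param array A `stim_array`.
#' @export
describe_array <- function(array, boundary_samples = 256) {
  stopifnot(inherits(array, "stim_array"))
  describe_elements(array$elements, boundary_samples)
}
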