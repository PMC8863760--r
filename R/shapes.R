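# Element geometry. Four convex shapes are supported; the size parameter R is
# the circle radius, or the side length for square, diamond (a square rotated
# 45 degrees) and equilateral triangle. Shapes are centred at their centroid.

SHAPE_KINDS <- c("circle", "square", "diamond", "triangle")

check_shape <- function(shape) {
  if (!is.character(shape) || length(shape) != 1 || !shape %in% SHAPE_KINDS) {
    stop_invalid_parameter(
      paste0("`shape` must be one of: ", paste(SHAPE_KINDS, collapse = ", "), ".")
    )
  }
  shape
}

check_R <- function(R) {
  if (!is.numeric(R) || any(!is.finite(R)) || any(R <= 0)) {
    stop_invalid_parameter("Size parameter `R` must be positive and finite.")
  }
  as.numeric(R)
}

#' Area of a single element
#'
#' @param shape One of `"circle"`, `"square"`, `"diamond"`, `"triangle"`.
#' @param R Size parameter (vectorised): circle radius, or side length for the
#'   polygonal shapes.
#' @return Area in squared stimulus units: \eqn{\pi R^2} for circles, \eqn{R^2}
#'   for squares and diamonds, \eqn{(\sqrt{3}/4) R^2} for equilateral
#'   triangles.
#' @examples
#' shape_area("circle", 1)   # pi
#' shape_area("triangle", 2) # sqrt(3)
#' @export
shape_area <- function(shape, R) {
  check_shape(shape)
  R <- check_R(R)
  switch(shape,
    circle   = pi * R^2,
    square   = R^2,
    diamond  = R^2,
    triangle = sqrt(3) / 4 * R^2
  )
}

#' Perimeter of a single element
#'
#' @inheritParams shape_area
#' @return Contour length: \eqn{2\pi R} for circles, \eqn{4R} for squares and
#'   diamonds, \eqn{3R} for triangles.
#' @examples
#' shape_perimeter("circle", 1) # 2*pi
#' shape_perimeter("diamond", 3) # 12
#' @export
shape_perimeter <- function(shape, R) {
  check_shape(shape)
  R <- check_R(R)
  switch(shape,
    circle   = 2 * pi * R,
    square   = 4 * R,
    diamond  = 4 * R,
    triangle = 3 * R
  )
}

# Vertices of a polygonal shape centred at the origin (matrix kx2, CCW).
shape_vertices <- function(shape, R) {
  switch(shape,
    square = {
      h <- R / 2
      cbind(c(-h, h, h, -h), c(-h, -h, h, h))
    },
    diamond = {
      d <- R / sqrt(2)
      cbind(c(d, 0, -d, 0), c(0, d, 0, -d))
    },
    triangle = {
      rc <- R / sqrt(3) # circumradius of equilateral triangle, apex up
      ang <- c(pi / 2, pi / 2 + 2 * pi / 3, pi / 2 + 4 * pi / 3)
      cbind(rc * cos(ang), rc * sin(ang))
    },
    stop_invalid_parameter("circle has no vertices")
  )
}

# Points on the element boundary, centred at (cx, cy). Polygonal shapes always
# include their true vertices, so axis-aligned hull corners are exact.
boundary_points <- function(shape, cx, cy, R, n = 256) {
  if (shape == "circle") {
    th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
    return(cbind(cx + R * cos(th), cy + R * sin(th)))
  }
  v <- shape_vertices(shape, R)
  k <- nrow(v)
  per_edge <- max(1L, ceiling(n / k))
  pts <- vector("list", k)
  for (i in seq_len(k)) {
    a <- v[i, ]
    b <- v[if (i == k) 1L else i + 1L, ]
    t <- seq(0, 1, length.out = per_edge + 1)[seq_len(per_edge)]
    pts[[i]] <- cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
  }
  out <- do.call(rbind, pts)
  cbind(out[, 1] + cx, out[, 2] + cy)
}

# --- containment and overlap -------------------------------------------------

# TRUE if an element lies entirely inside the arena.
element_in_arena <- function(shape, cx, cy, R, arena) {
  if (arena$kind == "circular") {
    if (shape == "circle") {
      return(sqrt(cx^2 + cy^2) + R <= arena$radius + 1e-9)
    }
    v <- shape_vertices(shape, R)
    return(all(sqrt((v[, 1] + cx)^2 + (v[, 2] + cy)^2) <= arena$radius + 1e-9))
  }
  # square arena: bounding-box test (exact for these shapes)
  if (shape == "circle") {
    xs <- c(cx - R, cx + R); ys <- c(cy - R, cy + R)
  } else {
    v <- shape_vertices(shape, R)
    xs <- range(v[, 1] + cx); ys <- range(v[, 2] + cy)
  }
  all(abs(c(xs, ys)) <= arena$radius + 1e-9)
}

# Squared distance from point p to segment ab.
point_segment_dist2 <- function(px, py, ax, ay, bx, by) {
  abx <- bx - ax; aby <- by - ay
  t <- ((px - ax) * abx + (py - ay) * aby) / (abx^2 + aby^2)
  t <- pmin(1, pmax(0, t))
  (ax + t * abx - px)^2 + (ay + t * aby - py)^2
}

point_in_convex_polygon <- function(px, py, v) {
  k <- nrow(v)
  s <- 0
  for (i in seq_len(k)) {
    j <- if (i == k) 1L else i + 1L
    cr <- (v[j, 1] - v[i, 1]) * (py - v[i, 2]) - (v[j, 2] - v[i, 2]) * (px - v[i, 1])
    if (abs(cr) < 1e-12) next
    if (s == 0) s <- sign(cr) else if (sign(cr) != s) return(FALSE)
  }
  TRUE
}

# Separating-axis test for two convex polygons (matrices kx2).
polygons_overlap <- function(a, b) {
  axes_of <- function(v) {
    k <- nrow(v)
    e <- v[c(2:k, 1), ] - v
    n <- cbind(-e[, 2], e[, 1])
    n / sqrt(rowSums(n^2))
  }
  for (ax in list(axes_of(a), axes_of(b))) {
    for (i in seq_len(nrow(ax))) {
      pa <- a %*% ax[i, ]; pb <- b %*% ax[i, ]
      if (max(pa) <= min(pb) + 1e-12 || max(pb) <= min(pa) + 1e-12) return(FALSE)
    }
  }
  TRUE
}

# Interior overlap between two elements (tangency does not count).
elements_overlap_pair <- function(s1, c1, R1, s2, c2, R2) {
  if (s1 == "circle" && s2 == "circle") {
    d2 <- sum((c1 - c2)^2)
    return(d2 < (R1 + R2)^2 * (1 - 1e-12))
  }
  if (s1 == "circle" || s2 == "circle") {
    if (s1 == "circle") {
      cc <- c1; Rc <- R1; v <- shape_vertices(s2, R2); v <- cbind(v[, 1] + c2[1], v[, 2] + c2[2])
    } else {
      cc <- c2; Rc <- R2; v <- shape_vertices(s1, R1); v <- cbind(v[, 1] + c1[1], v[, 2] + c1[2])
    }
    if (point_in_convex_polygon(cc[1], cc[2], v)) return(TRUE)
    k <- nrow(v)
    j <- c(2:k, 1)
    d2 <- min(point_segment_dist2(cc[1], cc[2], v[, 1], v[, 2], v[j, 1], v[j, 2]))
    return(d2 < Rc^2 * (1 - 1e-12))
  }
  va <- shape_vertices(s1, R1); va <- cbind(va[, 1] + c1[1], va[, 2] + c1[2])
  vb <- shape_vertices(s2, R2); vb <- cbind(vb[, 1] + c2[1], vb[, 2] + c2[2])
  polygons_overlap(va, vb)
}

# TRUE if any pair of elements in the tibble overlaps.
any_overlap <- function(elements) {
  n <- nrow(elements)
  if (n < 2) return(FALSE)
  # cheap prefilter on circumradius distance
  circum <- ifelse(elements$shape == "circle", elements$R,
    ifelse(elements$shape == "triangle", elements$R / sqrt(3),
      ifelse(elements$shape == "diamond", elements$R / sqrt(2), elements$R / sqrt(2))
    )
  )
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d2 <- (elements$x[i] - elements$x[j])^2 + (elements$y[i] - elements$y[j])^2
      if (d2 >= (circum[i] + circum[j])^2) next
      if (elements_overlap_pair(
        elements$shape[i], c(elements$x[i], elements$y[i]), elements$R[i],
        elements$shape[j], c(elements$x[j], elements$y[j]), elements$R[j]
      )) {
        return(TRUE)
      }
    }
  }
  FALSE
}
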