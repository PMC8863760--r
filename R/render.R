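# Rasterisation. Stimulus units map to pixels through the physical canvas
# settings: px_per_cm = min(canvas_px) / canvas_cm, and the arena diameter
# (2 * radius units) spans arena_cm centimetres. Pixels live on an integer
# grid with the origin at the top-left corner; the centre of pixel (row i,
# col j) sits at (j - 0.5, i - 0.5) px, and the arena origin is at the canvas
# centre with the y-axis pointing up.

#' Rendering specification
#'
#' @param canvas_px Integer `c(width, height)` of one panel in pixels.
#' @param arena_cm Physical diameter (circular) or side (square) of the arena
#'   in centimetres.
#' @param canvas_cm Physical size that `min(canvas_px)` corresponds to, in
#'   centimetres; defaults to `arena_cm`, i.e. the arena spans the smaller
#'   canvas dimension.
#' @param background_rgb,element_rgb RGB triples in `[0, 255]`.
#' @param arena_rgb RGB triple for the arena fill, or `NULL` to use the
#'   arena's own colour.
#' @param layout `"single"`, `"pair_horizontal"` or `"pair_vertical"`.
#' @param gap_px Pixel gap between paired panels.
#' @param antialias If `TRUE` (default), 4x supersampling; `FALSE` produces a
#'   hard-edged binary-coverage mask (exact pixel-count areas).
#' @param supersample Supersampling factor per axis when `antialias = TRUE`.
#' @return An object of class `"render_spec"`.
#' @export
render_spec <- function(canvas_px = c(400, 400), arena_cm = 10,
                        canvas_cm = arena_cm,
                        background_rgb = c(0, 0, 0),
                        arena_rgb = NULL,
                        element_rgb = c(255, 255, 255),
                        layout = c("single", "pair_horizontal", "pair_vertical"),
                        gap_px = 0, antialias = TRUE, supersample = 4) {
  layout <- match.arg(layout)
  if (any(canvas_px <= 0) || length(canvas_px) != 2) {
    stop_invalid_parameter("`canvas_px` must be two positive integers.")
  }
  if (arena_cm <= 0 || canvas_cm <= 0) {
    stop_invalid_parameter("physical dimensions must be positive.")
  }
  structure(
    list(
      canvas_px = as.integer(round(canvas_px)), arena_cm = arena_cm,
      canvas_cm = canvas_cm, background_rgb = background_rgb,
      arena_rgb = arena_rgb, element_rgb = element_rgb, layout = layout,
      gap_px = as.integer(gap_px), antialias = isTRUE(antialias),
      supersample = as.integer(supersample)
    ),
    class = "render_spec"
  )
}

# Pixels per stimulus unit for a given array under a spec.
px_per_unit <- function(stim, spec) {
  px_per_cm <- min(spec$canvas_px) / spec$canvas_cm
  (spec$arena_cm * px_per_cm) / (2 * stim$arena$radius)
}

# Coverage of one shape over the subsampled grid restricted to its bounding
# box; adds alpha into the h x w accumulator `acc`.
add_shape_coverage <- function(acc, shape, cx, cy, R, s, w, h, k) {
  # bounding half-extent in units
  ext <- switch(shape,
    circle = R,
    triangle = R / sqrt(3),
    R / sqrt(2) # square (half-diagonal R/sqrt(2)) and diamond
  )
  # pixel-space centre (x right, y down), origin top-left
  pcx <- w / 2 + cx * s
  pcy <- h / 2 - cy * s
  rpx <- ext * s
  j0 <- max(1L, floor(pcx - rpx)); j1 <- min(w, ceiling(pcx + rpx) + 1L)
  i0 <- max(1L, floor(pcy - rpx)); i1 <- min(h, ceiling(pcy + rpx) + 1L)
  if (j0 > j1 || i0 > i1) return(acc)
  cols <- j0:j1
  rows <- i0:i1
  # subpixel sample offsets within a pixel
  off <- (seq_len(k) - 0.5) / k
  subx <- as.vector(outer(off, cols - 1, "+")) # length k*nc, px coords
  suby <- as.vector(outer(off, rows - 1, "+"))
  # unit coordinates of subsamples
  ux <- (subx - w / 2) / s
  uy <- (h / 2 - suby) / s
  nx <- length(ux); ny <- length(uy)
  X <- matrix(ux, ny, nx, byrow = TRUE)
  Y <- matrix(uy, ny, nx)
  inside <- if (shape == "circle") {
    (X - cx)^2 + (Y - cy)^2 <= R^2
  } else {
    v <- shape_vertices(shape, R)
    kv <- nrow(v)
    m <- matrix(TRUE, ny, nx)
    for (e in seq_len(kv)) {
      f <- if (e == kv) 1L else e + 1L
      ex <- v[f, 1] - v[e, 1]; ey <- v[f, 2] - v[e, 2]
      # CCW polygon: inside iff cross >= 0 for all edges
      m <- m & (ex * (Y - cy - v[e, 2]) - ey * (X - cx - v[e, 1]) >= 0)
    }
    m
  }
  # average the k x k subsamples per pixel
  idx_r <- rep(seq_along(rows), each = k)
  idx_c <- rep(seq_along(cols), each = k)
  cov <- rowsum(inside + 0, idx_r)
  cov <- t(rowsum(t(cov), idx_c)) / (k * k)
  acc[rows, cols] <- pmin(1, acc[rows, cols] + cov)
  acc
}

render_panel <- function(stim, spec) {
  w <- spec$canvas_px[1]; h <- spec$canvas_px[2]
  k <- if (spec$antialias) spec$supersample else 1L
  s <- px_per_unit(stim, spec)
  img <- base::array(0, dim = c(h, w, 3))
  for (ch in 1:3) img[, , ch] <- spec$background_rgb[ch] / 255
  # arena fill
  arena_rgb <- spec$arena_rgb %||% stim$arena$colour
  acc <- matrix(0, h, w)
  ar <- stim$arena
  if (ar$kind == "circular") {
    acc <- add_shape_coverage(acc, "circle", 0, 0, ar$radius, s, w, h, k)
  } else {
    acc <- add_shape_coverage(acc, "square", 0, 0, 2 * ar$radius, s, w, h, k)
  }
  for (ch in 1:3) {
    img[, , ch] <- img[, , ch] * (1 - acc) + (arena_rgb[ch] / 255) * acc
  }
  # elements
  el <- stim$elements
  acc <- matrix(0, h, w)
  for (i in seq_len(nrow(el))) {
    acc <- add_shape_coverage(acc, el$shape[i], el$x[i], el$y[i], el$R[i], s, w, h, k)
  }
  for (ch in 1:3) {
    img[, , ch] <- img[, , ch] * (1 - acc) + (spec$element_rgb[ch] / 255) * acc
  }
  img
}

#' Render one array, or a pair of arrays, to an RGB raster
#'
#' Deterministic rasterisation (no randomness): the same array and spec always
#' produce identical pixels. An element of size R units covers
#' \eqn{\pi (R s)^2} pixels (up to the anti-aliasing margin), where `s` is the
#' derived pixel-per-unit scale. Paired layouts place two equally sized panels
#' side by side (`pair_horizontal`) or stacked (`pair_vertical`) separated by
#' `gap_px` background pixels.
#'
#' @param array A [stim_array()], or a list of two arrays for paired layouts.
#' @param spec A [render_spec()].
#' @return A numeric `height x width x 3` array in `[0, 1]`.
#' @export
render_image <- function(array, spec = render_spec()) {
  pair <- is.list(array) && !inherits(array, "stim_array")
  if (spec$layout == "single") {
    if (pair) stop_invalid_parameter("single layout takes one array.")
    return(render_panel(array, spec))
  }
  if (!pair || length(array) != 2) {
    stop_invalid_parameter("paired layouts need a list of exactly two arrays.")
  }
  a <- render_panel(array[[1]], spec)
  b <- render_panel(array[[2]], spec)
  h <- dim(a)[1]; w <- dim(a)[2]
  bg <- spec$background_rgb / 255
  if (spec$layout == "pair_horizontal") {
    out <- base::array(0, dim = c(h, 2 * w + spec$gap_px, 3))
    for (ch in 1:3) {
      gap <- matrix(bg[ch], h, spec$gap_px)
      out[, , ch] <- cbind(a[, , ch], gap, b[, , ch])
    }
  } else {
    out <- base::array(0, dim = c(2 * h + spec$gap_px, w, 3))
    for (ch in 1:3) {
      gap <- matrix(bg[ch], spec$gap_px, w)
      out[, , ch] <- rbind(a[, , ch], gap, b[, , ch])
    }
  }
  out
}

#' Write a rendered raster as an 8-bit RGB PNG
#'
#' @param img Raster from [render_image()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stimulus_png <- function(img, path) {
  png::writePNG(img, path)
  invisible(path)
}
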