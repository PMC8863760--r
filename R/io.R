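# Persistence: a stimulus set serialises to a JSON file any presentation
# software can consume, plus a CSV metadata table (one row per stimulus) and
# one PNG per array when a render spec is supplied. Achieved values are stored
# at full double precision so load(save(x)) reproduces them exactly.

set_to_list <- function(set) {
  list(
    version = set$version,
    seed = set$seed,
    n_discarded = set$n_discarded,
    constraints = cs_to_list(set$constraints),
    arrays = lapply(set$arrays, function(a) {
      list(
        elements = as.list(a$elements),
        arena = list(kind = a$arena$kind, radius = a$arena$radius, colour = a$arena$colour),
        achieved = a$achieved,
        errors = a$errors,
        seed = a$seed,
        constraint_ref = a$constraint_ref
      )
    })
  )
}

set_from_list <- function(x) {
  arrays <- lapply(x$arrays, function(a) {
    ar <- arena(a$arena$kind, a$arena$radius, colour = unlist(a$arena$colour))
    arr <- structure(
      list(
        elements = tibble::tibble(
          shape = unlist(a$elements$shape),
          x = unlist(a$elements$x),
          y = unlist(a$elements$y),
          R = unlist(a$elements$R)
        ),
        arena = ar,
        achieved = lapply(a$achieved, function(v) unlist(v)),
        errors = lapply(a$errors %||% list(), function(v) unlist(v)),
        seed = a$seed %||% NA_integer_,
        constraint_ref = a$constraint_ref %||% NA_character_
      ),
      class = "stim_array"
    )
    arr
  })
  structure(
    list(
      constraints = cs_from_list(x$constraints),
      arrays = arrays,
      n_discarded = x$n_discarded %||% 0L,
      seed = x$seed,
      version = x$version %||% NA_character_
    ),
    class = "stim_set"
  )
}

#' Save a stimulus set: images, metadata table and set file
#'
#' Writes `set.json` (the full serialized set), `metadata.csv` (one row per
#' stimulus: numerosity, achieved ID/CH/D/TA/TP, Rmin, Rmax, the relative
#' errors of the constrained variables, seed and image filename) and, when
#' `render` is given, one PNG per array (`stim_001.png`, ...). Metadata values
#' are the stored achieved values — nothing is recomputed at save time.
#'
#' @param set A `stim_set` from [generate_stimuli()].
#' @param dir Output directory (created if missing).
#' @param render Optional [render_spec()]; when given, PNGs are written.
#' @param prefix Image filename prefix.
#' @return Invisibly, a list with the paths written (`set`, `metadata`,
#'   `images`).
#' @export
save_stimulus_set <- function(set, dir, render = NULL, prefix = "stim") {
  if (length(set$arrays) == 0) stop_invalid_parameter("Cannot save an empty set.")
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop_invalid_parameter(sprintf("Cannot create directory '%s'.", dir))
  }
  files <- character(0)
  if (!is.null(render)) {
    files <- vapply(seq_along(set$arrays), function(i) {
      f <- file.path(dir, sprintf("%s_%03d.png", prefix, i))
      write_stimulus_png(render_image(set$arrays[[i]], render), f)
      f
    }, character(1))
  }
  md <- tidy(set)
  md$file <- if (length(files)) basename(files) else NA_character_
  md_path <- file.path(dir, "metadata.csv")
  readr::write_csv(md, md_path)
  set_path <- file.path(dir, "set.json")
  jsonlite::write_json(set_to_list(set), set_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(list(set = set_path, metadata = md_path, images = files))
}

#' @rdname save_stimulus_set
#' @param path Path to a `set.json` written by [save_stimulus_set()].
#' @export
load_stimulus_set <- function(path) {
  if (!file.exists(path)) stop_invalid_parameter(sprintf("No such file: '%s'.", path))
  set_from_list(jsonlite::read_json(path, simplifyVector = FALSE))
}
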