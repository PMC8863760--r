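# Trial sequencing for the two classical paradigms, display-agnostic: the
# sequencer emits a trial table that any presentation layer (or a printout)
# can execute, plus a CSV export. No on-screen code lives here.

#' Presentation timing settings
#'
#' @param duration Stimulus presentation time in seconds.
#' @param pause Inter-trial pause in seconds.
#' @param advance `"timed"` (auto-advance after `duration`) or `"keyboard"`.
#' @return A named list.
#' @export
trial_timing <- function(duration = 5, pause = 1,
                         advance = c("timed", "keyboard")) {
  advance <- match.arg(advance)
  if (duration <= 0 || pause < 0) {
    stop_invalid_parameter("`duration` must be positive and `pause` >= 0.")
  }
  list(duration = duration, pause = pause, advance = advance)
}

set_numerosity <- function(set) {
  if (inherits(set, "stim_set")) return(set$constraints$n)
  if (is.list(set) && !is.null(set$n)) return(set$n)
  stop_invalid_parameter("sets must be stim_set objects or lists with `n` and `ids`.")
}

set_ids <- function(set) {
  if (inherits(set, "stim_set")) {
    if (length(set$arrays) == 0) stop_invalid_parameter("empty stimulus set.")
    return(seq_along(set$arrays))
  }
  if (is.list(set) && length(set$ids)) return(set$ids)
  stop_invalid_parameter("empty stimulus set.")
}

# Sample `k` exemplars without replacement within a cycle; when a cycle is
# exhausted the pool is reshuffled, so physical properties change every trial
# for as long as distinct exemplars last.
cycle_sample <- function(ids, k) {
  out <- integer(0)
  while (length(out) < k) {
    out <- c(out, sample(ids, min(length(ids), k - length(out))))
  }
  out[seq_len(k)]
}

new_trial_sequence <- function(trials, paradigm, sets, seed) {
  structure(
    list(trials = trials, paradigm = paradigm, sets = sets, seed = seed),
    class = "trial_sequence"
  )
}

#' @export
print.trial_sequence <- function(x, ...) {
  cat(sprintf("<trial_sequence> %s, %d trial(s)\n", x$paradigm, nrow(x$trials)))
  print(x$trials, n = 6)
  invisible(x)
}

#' Build a habituation/dishabituation trial sequence
#'
#' Habituation trials repeatedly present exemplars of one numerosity whose
#' physical properties change from trial to trial (exemplars are sampled
#' without replacement until the pool is exhausted, then reshuffled) while
#' the numerosity stays constant; dishabituation trials then present a novel
#' numerosity. The two sets must therefore differ in numerosity.
#'
#' @param hab_set,dishab_set Stimulus sets (`stim_set`, or a list with fields
#'   `n` and `ids`). `dishab_set` may be `NULL` when `n_dishab = 0`.
#' @param n_hab,n_dishab Trial counts for the two phases.
#' @param timing A [trial_timing()].
#' @param seed Integer seed (exemplar order is reproducible).
#' @return A `trial_sequence` whose `trials` tibble has columns `trial`,
#'   `phase`, `set`, `numerosity`, `stimulus`, `duration`, `pause`, `advance`.
#' @export
build_habituation <- function(hab_set, dishab_set = NULL, n_hab, n_dishab = 0,
                              timing = trial_timing(), seed = 1) {
  if (n_hab < 1) stop_invalid_parameter("`n_hab` must be >= 1.")
  n_h <- set_numerosity(hab_set)
  ids_h <- set_ids(hab_set)
  if (n_dishab > 0) {
    if (is.null(dishab_set)) stop_invalid_parameter("dishabituation set missing.")
    n_d <- set_numerosity(dishab_set)
    if (n_d == n_h) {
      stop_invalid_parameter(
        "habituation and dishabituation sets must differ in numerosity."
      )
    }
    ids_d <- set_ids(dishab_set)
  }
  set.seed(seed)
  hab <- tibble::tibble(
    phase = "habituation", set = "habituation", numerosity = n_h,
    stimulus = cycle_sample(ids_h, n_hab)
  )
  trials <- hab
  if (n_dishab > 0) {
    dis <- tibble::tibble(
      phase = "dishabituation", set = "dishabituation", numerosity = n_d,
      stimulus = cycle_sample(ids_d, n_dishab)
    )
    trials <- dplyr::bind_rows(hab, dis)
  }
  trials <- dplyr::mutate(trials,
    trial = dplyr::row_number(),
    duration = timing$duration, pause = timing$pause, advance = timing$advance,
    .before = 1
  )
  new_trial_sequence(trials, "habituation_dishabituation",
                     sets = c("habituation", if (n_dishab > 0) "dishabituation"),
                     seed = seed)
}

#' Build a simultaneous dual-choice trial sequence
#'
#' Each trial presents one exemplar from each of two sets side by side.
#' Exemplars are randomized (without replacement within cycles) and the
#' left/right assignment of the two sets is counterbalanced across the
#' session: over `n_trials` trials, set A appears on the left
#' `ceiling(n/2)` or `floor(n/2)` times (`|#left - #right| <= 1`), in
#' shuffled order.
#'
#' @param set_a,set_b Stimulus sets (as in [build_habituation()]).
#' @param n_trials Number of trials (>= 1).
#' @param timing A [trial_timing()].
#' @param seed Integer seed.
#' @return A `trial_sequence` whose `trials` tibble has columns `trial`,
#'   `phase`, `left_set`, `right_set`, `left_stimulus`, `right_stimulus`,
#'   `left_numerosity`, `right_numerosity`, `duration`, `pause`, `advance`.
#' @export
build_dual_choice <- function(set_a, set_b, n_trials,
                              timing = trial_timing(), seed = 1) {
  if (n_trials < 1) stop_invalid_parameter("`n_trials` must be >= 1.")
  n_a <- set_numerosity(set_a); ids_a <- set_ids(set_a)
  n_b <- set_numerosity(set_b); ids_b <- set_ids(set_b)
  set.seed(seed)
  a_left <- sample(rep(c(TRUE, FALSE), length.out = n_trials))
  ex_a <- cycle_sample(ids_a, n_trials)
  ex_b <- cycle_sample(ids_b, n_trials)
  trials <- tibble::tibble(
    trial = seq_len(n_trials),
    phase = "choice",
    left_set = ifelse(a_left, "A", "B"),
    right_set = ifelse(a_left, "B", "A"),
    left_stimulus = ifelse(a_left, ex_a, ex_b),
    right_stimulus = ifelse(a_left, ex_b, ex_a),
    left_numerosity = ifelse(a_left, n_a, n_b),
    right_numerosity = ifelse(a_left, n_b, n_a),
    duration = timing$duration, pause = timing$pause, advance = timing$advance
  )
  new_trial_sequence(trials, "dual_choice", sets = c("A", "B"), seed = seed)
}

#' Export a trial sequence (session log) as CSV
#'
#' One row per trial, all fields included; the file can be re-read with
#' [readr::read_csv()] to recover the sequence table exactly.
#'
#' @param sequence A `trial_sequence`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_session_log <- function(sequence, path) {
  if (!inherits(sequence, "trial_sequence") || nrow(sequence$trials) == 0) {
    stop_invalid_parameter("`sequence` must be a non-empty trial_sequence.")
  }
  readr::write_csv(sequence$trials, path)
  invisible(path)
}
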