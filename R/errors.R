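# Typed conditions. Every domain failure carries a condition class so callers
# (and the shaping pipeline, which converts some of them into discards) can
# react programmatically instead of matching message strings.

stop_invalid_parameter <- function(msg, ...) {
  rlang::abort(msg, class = "numstim_invalid_parameter", ...)
}

stop_undefined_descriptor <- function(msg, ...) {
  rlang::abort(msg, class = "numstim_undefined_descriptor", ...)
}

stop_infeasible_combination <- function(msg, pair = NULL, ...) {
  rlang::abort(msg, class = "numstim_infeasible_combination", pair = pair, ...)
}

stop_missing_parameter <- function(msg, ...) {
  rlang::abort(msg, class = "numstim_missing_parameter", ...)
}

stop_infeasible_geometry <- function(msg, ...) {
  rlang::abort(msg, class = "numstim_infeasible_geometry", ...)
}

stop_budget_exhausted <- function(msg, best = NULL, ...) {
  rlang::abort(msg, class = "numstim_budget_exhausted", best = best, ...)
}

stop_pins_exceed_target <- function(msg, ...) {
  rlang::abort(msg, class = "numstim_pins_exceed_target", ...)
}

stop_overlap <- function(msg, ...) {
  rlang::abort(msg, class = "numstim_overlap_before_convergence", ...)
}

stop_max_iterations <- function(msg, ...) {
  rlang::abort(msg, class = "numstim_max_iterations", ...)
}
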