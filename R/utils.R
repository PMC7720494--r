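# internal helpers shared across modules

`%||%` <- rlang::`%||%`

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
  invisible(TRUE)
}

assert_cols <- function(data, cols, what = "data") {
  missing <- setdiff(cols, names(data))
  assert_that(
    length(missing) == 0,
    sprintf("%s is missing required column(s): %s", what, paste(missing, collapse = ", "))
  )
}

is_whole <- function(x, tol = 1e-8) {
  is.numeric(x) & is.finite(x) & abs(x - round(x)) < tol
}

# survival time / event validation used by the survival primitives
check_surv_inputs <- function(times, events) {
  assert_that(length(times) > 0, "empty input: no observations supplied")
  assert_that(length(times) == length(events), "times and events must have equal length")
  assert_that(all(is.finite(times)) && all(times >= 0), "survival times must be finite and >= 0")
  assert_that(all(events %in% c(0, 1)), "event indicator must be 0 (censored) or 1 (event)")
  invisible(TRUE)
}
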