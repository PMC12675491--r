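# internal validation helpers; condition classes let callers distinguish
# bad-input errors from buoyancy and model-domain refusals

abort_validity <- function(msg, ...) {
  rlang::abort(msg, class = "sinkvel_error_validity", ...)
}

abort_buoyancy <- function(msg, ...) {
  rlang::abort(msg, class = "sinkvel_error_buoyancy", ...)
}

abort_domain <- function(msg, ...) {
  rlang::abort(msg, class = "sinkvel_error_domain", ...)
}

check_positive <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) == 0 || anyNA(x) || any(x <= 0) ||
      (finite && any(!is.finite(x)))) {
    abort_validity(sprintf("`%s` must be positive and finite.", name))
  }
  invisible(x)
}

check_range <- function(x, name, lo, hi) {
  if (!is.numeric(x) || anyNA(x) || any(x < lo) || any(x > hi)) {
    abort_validity(sprintf("`%s` must lie in [%g, %g].", name, lo, hi))
  }
  invisible(x)
}

# mean of repeated volume/weight measurements with the divergence QC rule:
# warn when the spread exceeds `tol` (fraction of the mean)
aggregate_measurements <- function(values, tol = 0.05) {
  values <- values[!is.na(values)]
  if (length(values) == 0) abort_validity("no measurements to aggregate")
  check_positive(values, "values")
  m <- mean(values)
  if (length(values) > 1 && diff(range(values)) > tol * m) {
    warning(sprintf(
      "replicate measurements diverge by more than %.0f%% of the mean",
      100 * tol
    ), call. = FALSE)
  }
  m
}
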