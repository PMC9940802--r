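# Shared validation helpers. All user-input failures signal a condition of
# class "cvm_validation_error" so callers (and the CLI) can distinguish bad
# input (exit 2) from programming errors.

abort_invalid <- function(msg, field = NULL, call = rlang::caller_env()) {
  rlang::abort(msg, class = "cvm_validation_error", field = field, call = call)
}

check_number <- function(x, field, min = NULL, max = NULL,
                         exclusive_min = FALSE, integer = FALSE,
                         call = rlang::caller_env()) {
  if (!rlang::is_scalar_double(x) && !rlang::is_scalar_integer(x)) {
    abort_invalid(sprintf("`%s` must be a single number", field), field, call)
  }
  x <- as.numeric(x)
  if (!is.finite(x)) {
    abort_invalid(sprintf("`%s` must be finite", field), field, call)
  }
  if (!is.null(min)) {
    bad <- if (exclusive_min) x <= min else x < min
    if (bad) {
      op <- if (exclusive_min) ">" else ">="
      abort_invalid(sprintf("`%s` must be %s %s", field, op, min), field, call)
    }
  }
  if (!is.null(max) && x > max) {
    abort_invalid(sprintf("`%s` must be <= %s", field, max), field, call)
  }
  if (integer && x != trunc(x)) {
    abort_invalid(sprintf("`%s` must be a whole number", field), field, call)
  }
  x
}

check_string <- function(x, field, call = rlang::caller_env()) {
  if (!rlang::is_scalar_character(x) || is.na(x) || !nzchar(x)) {
    abort_invalid(sprintf("`%s` must be a non-empty string", field), field, call)
  }
  x
}
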