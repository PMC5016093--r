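# Internal argument checks. All user-facing validation errors carry the
# condition class "mg_error_invalid" so callers can test for them.

mg_stop <- function(msg, class = "mg_error_invalid") {
  rlang::abort(msg, class = class)
}

# x must be numeric and finite (NA counts as non-finite)
check_finite <- function(x, name) {
  if (!is.numeric(x) || length(x) == 0L || any(!is.finite(x))) {
    mg_stop(sprintf("`%s` must be finite and numeric.", name))
  }
  invisible(x)
}

check_nonneg <- function(x, name) {
  check_finite(x, name)
  if (any(x < 0)) {
    mg_stop(sprintf("`%s` must be >= 0.", name))
  }
  invisible(x)
}

check_pos <- function(x, name) {
  check_finite(x, name)
  if (any(x <= 0)) {
    mg_stop(sprintf("`%s` must be > 0.", name))
  }
  invisible(x)
}

# path to a packaged data file
mg_extdata <- function(file) {
  path <- system.file("extdata", file, package = "magnetolimits")
  if (identical(path, "")) {
    mg_stop(sprintf("packaged data file '%s' not found", file), class = "mg_error_lookup")
  }
  path
}
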