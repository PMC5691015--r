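# Internal condition helpers. Domain errors (bad argument values) are a
# subclass of validation errors so the CLI can map both to exit code 2;
# numerical failures map to exit code 3.

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_domain <- function(msg, ...) {
  rlang::abort(msg,
    class = c("ebftools_domain_error", "ebftools_validation_error", "ebftools_error"),
    ...)
}

abort_validation <- function(msg, ...) {
  rlang::abort(msg, class = c("ebftools_validation_error", "ebftools_error"), ...)
}

abort_numeric <- function(msg, ...) {
  rlang::abort(msg, class = c("ebftools_numeric_error", "ebftools_error"), ...)
}

warn_validity <- function(msg) {
  rlang::warn(msg, class = "ebftools_validity_warning")
}

#' @noRd
is_strict <- function(strict = NULL) {
  isTRUE(strict %||% getOption("ebftools.strict", FALSE))
}

# Emit a validity notice: warning by default, error in strict mode.
validity_notice <- function(msg, strict = NULL) {
  if (is_strict(strict)) abort_domain(msg) else warn_validity(msg)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_domain(sprintf("`%s` must be a single finite number.", name))
  }
  if (strict_lower && x <= lower) {
    abort_domain(sprintf("`%s` must be > %g (got %g).", name, lower, x))
  }
  if (!strict_lower && x < lower) {
    abort_domain(sprintf("`%s` must be >= %g (got %g).", name, lower, x))
  }
  if (x > upper) {
    abort_domain(sprintf("`%s` must be <= %g (got %g).", name, upper, x))
  }
  invisible(x)
}

assert_numeric_vector <- function(x, name, lower = -Inf, strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) == 0L || anyNA(x) || any(!is.finite(x))) {
    abort_domain(sprintf("`%s` must be a finite numeric vector.", name))
  }
  bad <- if (strict_lower) x <= lower else x < lower
  if (any(bad)) {
    abort_domain(sprintf(
      "`%s` must be %s %g everywhere (first offending value: %g).",
      name, if (strict_lower) ">" else ">=", lower, x[which(bad)[1L]]))
  }
  invisible(x)
}

# Recycle length-1 arguments against each other (base arithmetic rules,
# but erroring on incompatible lengths instead of silently recycling).
recycle2 <- function(x, y, xname, yname) {
  nx <- length(x); ny <- length(y)
  if (nx == ny) return(list(x = x, y = y))
  if (nx == 1L) return(list(x = rep(x, ny), y = y))
  if (ny == 1L) return(list(x = x, y = rep(y, nx)))
  abort_domain(sprintf("`%s` and `%s` must have equal lengths (or length 1).",
                       xname, yname))
}
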