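#' Coefficient set for the backscatter enhancement model
#'
#' The empirical model of electron backscatter from a saturation-thickness
#' lead slab is parameterized by six positive constants. `c1`--`c4` describe
#' the interface electron backscatter factor (EBF) as a function of the mean
#' electron energy `Em` (MeV) at the interface,
#' \deqn{EBF(E_m) = 1 + c_1 e^{-c_2 E_m} - c_3 e^{-c_4 E_m},}
#' and `c5`--`c6` describe the log-linear dependence of the upstream decay
#' constant on energy, \eqn{k(E_m) = -c_5 \ln(E_m) + c_6} (per mm).
#'
#' Called with no arguments, the constructor returns the published default
#' set `(0.936, 0.089, 0.602, 0.375, 0.130, 0.413)` together with its 95%
#' confidence half-widths. The same values ship as a JSON file in
#' `system.file("extdata", "default_coefficients.json", package = "ebftools")`.
#'
#' @param c1,c3 Dimensionless amplitudes (positive).
#' @param c2,c4 Energy rates in 1/MeV (positive).
#' @param c5 Decay-model slope magnitude in 1/mm (positive).
#' @param c6 Decay-model intercept in 1/mm (positive).
#' @param ci_halfwidths Optional named numeric vector of 95% confidence
#'   half-widths with names `c1`..`c6` (same units as the coefficients).
#'
#' @return An object of class `ebf_coefficients`.
#' @examples
#' cf <- ebf_coefficients()
#' ebf_at_interface(4, cf)
#' @export
ebf_coefficients <- function(c1 = 0.936, c2 = 0.089, c3 = 0.602, c4 = 0.375,
                             c5 = 0.130, c6 = 0.413,
                             ci_halfwidths = if (missing(c1) && missing(c2) &&
                                                 missing(c3) && missing(c4) &&
                                                 missing(c5) && missing(c6)) {
                               c(c1 = 0.132, c2 = 0.012, c3 = 0.126,
                                 c4 = 0.065, c5 = 0.004, c6 = 0.006)
                             } else NULL) {
  vals <- c(c1 = c1, c2 = c2, c3 = c3, c4 = c4, c5 = c5, c6 = c6)
  for (nm in names(vals)) {
    assert_scalar_number(vals[[nm]], nm, lower = 0, strict_lower = TRUE)
  }
  if (!is.null(ci_halfwidths)) {
    if (!is.numeric(ci_halfwidths) || is.null(names(ci_halfwidths)) ||
        !all(names(ci_halfwidths) %in% names(vals))) {
      abort_domain("`ci_halfwidths` must be a numeric vector named with c1..c6.")
    }
    if (any(ci_halfwidths < 0, na.rm = TRUE)) {
      abort_domain("`ci_halfwidths` must be non-negative.")
    }
  }
  if (c2 >= c4) {
    rlang::warn(paste0(
      "c2 >= c4: the interface enhancement is negative near Em = 0; ",
      "the published coefficient ordering has c2 < c4."))
  }
  structure(
    list(c1 = c1, c2 = c2, c3 = c3, c4 = c4, c5 = c5, c6 = c6,
         ci_halfwidths = ci_halfwidths),
    class = "ebf_coefficients")
}

#' @export
print.ebf_coefficients <- function(x, ...) {
  cat("<ebf_coefficients>\n")
  vals <- unlist(x[c("c1", "c2", "c3", "c4", "c5", "c6")])
  ci <- x$ci_halfwidths
  for (nm in names(vals)) {
    if (!is.null(ci) && nm %in% names(ci)) {
      cat(sprintf("  %s = %.4g (+/- %.3g, 95%% CI)\n", nm, vals[[nm]], ci[[nm]]))
    } else {
      cat(sprintf("  %s = %.4g\n", nm, vals[[nm]]))
    }
  }
  invisible(x)
}

#' @export
coef.ebf_coefficients <- function(object, ...) {
  unlist(object[c("c1", "c2", "c3", "c4", "c5", "c6")])
}

#' Coerce to a coefficient set
#'
#' Accepts an `ebf_coefficients` object, a named list, or a named numeric
#' vector with elements `c1`..`c6`.
#'
#' @param x Object to coerce.
#' @return An `ebf_coefficients` object.
#' @export
as_ebf_coefficients <- function(x) {
  if (inherits(x, "ebf_coefficients")) return(x)
  if (is.numeric(x)) x <- as.list(x)
  if (is.list(x) && all(c("c1", "c2", "c3", "c4", "c5", "c6") %in% names(x))) {
    ci <- x$ci_halfwidths
    if (is.null(ci)) {
      ci_keys <- paste0("ci_c", 1:6)
      if (all(ci_keys %in% names(x))) {
        ci <- stats::setNames(unlist(x[ci_keys]), paste0("c", 1:6))
      }
    }
    return(ebf_coefficients(x$c1, x$c2, x$c3, x$c4, x$c5, x$c6,
                            ci_halfwidths = ci))
  }
  abort_domain("Cannot coerce `x` to ebf_coefficients: need fields c1..c6.")
}

#' Read / write a coefficient set as JSON
#'
#' The serialization uses keys `c1`..`c6` plus optional `ci_c1`..`ci_c6`
#' for the 95% confidence half-widths.
#'
#' @param path Path to a JSON file.
#' @param coefficients An `ebf_coefficients` object (or coercible).
#' @return `read_coefficients()` returns an `ebf_coefficients` object;
#'   `write_coefficients()` returns `path` invisibly.
#' @export
read_coefficients <- function(path) {
  if (!file.exists(path)) {
    abort_validation(sprintf("Coefficient file not found: '%s'.", path))
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_ebf_coefficients(raw)
}

#' @rdname read_coefficients
#' @export
write_coefficients <- function(coefficients, path) {
  cf <- as_ebf_coefficients(coefficients)
  out <- as.list(coef(cf))
  if (!is.null(cf$ci_halfwidths)) {
    ci <- cf$ci_halfwidths
    names(ci) <- paste0("ci_", names(ci))
    out <- c(out, as.list(ci))
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Path to the packaged default coefficient file
#'
#' @return File path of the JSON file carrying the published coefficient set.
#' @export
default_coefficients_path <- function() {
  system.file("extdata", "default_coefficients.json", package = "ebftools",
              mustWork = TRUE)
}
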