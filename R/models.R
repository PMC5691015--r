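# Closed-form backscatter models: the legacy single-exponential EBF relation,
# the legacy upstream-intensity decay, and the two-exponential interface model
# with its energy-dependent enhancement decay.

# Raw (unvalidated, warning-free) evaluators. Everything downstream --
# extraction, fitting, synthesis -- funnels through these so that validity
# warnings fire only at the user-facing surface.
.ebf_interface_raw <- function(em, cf) {
  1 + cf$c1 * exp(-cf$c2 * em) - cf$c3 * exp(-cf$c4 * em)
}

.decay_k_raw <- function(em, cf) {
  # em > 0; clamped below at 0 (raw value goes negative above exp(c6/c5) MeV)
  pmax(0, -cf$c5 * log(em) + cf$c6)
}

.ebf_upstream_raw <- function(em, t, cf) {
  enh <- .ebf_interface_raw(em, cf) - 1
  k <- ifelse(em > 0, .decay_k_raw(em, cf), Inf)
  fac <- exp(-k * t)
  fac[t == 0] <- 1  # covers k = Inf at em = 0
  1 + enh * fac
}

# Validity window of the two-exponential model (MeV).
EM_VALID <- c(0.2, 14)
# Validity window of the legacy single-exponential relation (MeV).
EM_VALID_LEGACY <- c(3, 35)

check_em_validity <- function(em, range, label, strict = NULL) {
  out <- em < range[1] | em > range[2]
  if (any(out)) {
    validity_notice(sprintf(
      "%d of %d mean-energy value(s) outside the %g-%g MeV range over which %s is valid.",
      sum(out), length(em), range[1], range[2], label), strict)
  }
}

#' Legacy single-exponential electron backscatter factor
#'
#' The historical ionization-chamber relation
#' `EBF = 1 + 0.735 * exp(-0.052 * Em)`, established over 3--35 MeV.
#' A warning (an error in strict mode) is emitted outside that window.
#'
#' @param em Mean electron energy at the interface, MeV (non-negative).
#' @param strict If `TRUE`, validity warnings become errors. Defaults to
#'   `getOption("ebftools.strict", FALSE)`.
#' @return EBF values (dimensionless ratio), same length as `em`.
#' @examples
#' suppressWarnings(ebf_klevenhagen(c(1, 10)))
#' @export
ebf_klevenhagen <- function(em, strict = NULL) {
  assert_numeric_vector(em, "em", lower = 0)
  check_em_validity(em, EM_VALID_LEGACY, "the legacy single-exponential relation",
                    strict)
  1 + 0.735 * exp(-0.052 * em)
}

#' Legacy upstream backscatter-intensity decay model
#'
#' `EBI(t) = A * exp(-k * t)` with energy-dependent constants `A`, `k`
#' taken from the historical literature; they are not bundled here and
#' must be supplied by the user.
#'
#' @param amplitude Dimensionless amplitude `A` (positive).
#' @param k Decay constant in 1/mm (positive).
#' @return An object of class `legacy_decay_model`.
#' @export
legacy_decay_model <- function(amplitude, k) {
  assert_scalar_number(amplitude, "amplitude", lower = 0, strict_lower = TRUE)
  assert_scalar_number(k, "k", lower = 0, strict_lower = TRUE)
  structure(list(amplitude = amplitude, k = k), class = "legacy_decay_model")
}

#' Evaluate the legacy upstream-intensity decay
#'
#' @param t Upstream distance(s) from the interface in mm (non-negative).
#' @param model A [legacy_decay_model()].
#' @return EBI values, same length as `t`.
#' @examples
#' ebi_legacy(5, legacy_decay_model(0.44, 0.413))
#' @export
ebi_legacy <- function(t, model) {
  if (!inherits(model, "legacy_decay_model")) {
    abort_domain("`model` must be a legacy_decay_model object.")
  }
  assert_numeric_vector(t, "t", lower = 0)
  model$amplitude * exp(-model$k * t)
}

#' Electron backscatter factor at the lead interface
#'
#' Two-exponential empirical model
#' `EBF(Em) = 1 + c1 exp(-c2 Em) - c3 exp(-c4 Em)`. With the default
#' coefficients the model is validated for `Em` in 0.2--14 MeV; outside
#' that window a warning is emitted (an error in strict mode).
#'
#' @inheritParams ebf_klevenhagen
#' @param coefficients An [ebf_coefficients()] set.
#' @return EBF values (ratio >= 1 over the validated domain).
#' @examples
#' ebf_at_interface(c(1, 4, 10))
#' @export
ebf_at_interface <- function(em, coefficients = ebf_coefficients(),
                             strict = NULL) {
  cf <- as_ebf_coefficients(coefficients)
  assert_numeric_vector(em, "em", lower = 0)
  check_em_validity(em, EM_VALID, "the two-exponential interface model", strict)
  .ebf_interface_raw(em, cf)
}

#' Energy-dependent upstream decay coefficient
#'
#' `k(Em) = -c5 * ln(Em) + c6` in 1/mm, clamped below at zero (the raw
#' value turns negative above `exp(c6/c5)` MeV, outside the validated
#' energy window; a warning reports the clamp).
#'
#' @inheritParams ebf_at_interface
#' @param em Mean energy, MeV (strictly positive).
#' @return Decay coefficients in 1/mm, non-increasing in `em`.
#' @examples
#' decay_coefficient(c(1, exp(1)))
#' @export
decay_coefficient <- function(em, coefficients = ebf_coefficients(),
                              strict = NULL) {
  cf <- as_ebf_coefficients(coefficients)
  assert_numeric_vector(em, "em", lower = 0, strict_lower = TRUE)
  raw <- -cf$c5 * log(em) + cf$c6
  if (any(raw < 0)) {
    validity_notice(sprintf(
      "decay coefficient clamped to 0 for %d energy value(s) above %.1f MeV.",
      sum(raw < 0), exp(cf$c6 / cf$c5)), strict)
  }
  pmax(0, raw)
}

#' Backscatter enhancement at an upstream distance
#'
#' Composed model: the interface enhancement decays exponentially with the
#' upstream distance `t`,
#' `EBF(Em, t) = 1 + (EBF(Em) - 1) * exp(-k(Em) * t)`.
#' Reduces to [ebf_at_interface()] at `t = 0` and tends to 1 as `t` grows.
#'
#' @inheritParams ebf_at_interface
#' @param t Upstream distance(s) in mm (non-negative).
#' @return EBF(t) values, same length as the recycled inputs.
#' @examples
#' ebf_upstream(1, c(0, 2, 5))
#' @export
ebf_upstream <- function(em, t, coefficients = ebf_coefficients(),
                         strict = NULL) {
  cf <- as_ebf_coefficients(coefficients)
  assert_numeric_vector(em, "em", lower = 0)
  assert_numeric_vector(t, "t", lower = 0)
  r <- recycle2(em, t, "em", "t")
  check_em_validity(r$x, EM_VALID, "the two-exponential interface model", strict)
  .ebf_upstream_raw(r$x, r$y, cf)
}

#' Normalized upstream backscatter intensity
#'
#' The upstream enhancement relative to its value at the interface,
#' `(EBF(Em, t) - 1) / (EBF(Em) - 1) = exp(-k(Em) * t)`; 1 at `t = 0`.
#'
#' @inheritParams ebf_upstream
#' @param em Mean energy, MeV (strictly positive, with non-zero interface
#'   enhancement).
#' @return Ratios in (0, 1].
#' @examples
#' normalized_ebi(exp(1), c(0, 10))
#' @export
normalized_ebi <- function(em, t, coefficients = ebf_coefficients(),
                           strict = NULL) {
  cf <- as_ebf_coefficients(coefficients)
  assert_numeric_vector(em, "em", lower = 0, strict_lower = TRUE)
  assert_numeric_vector(t, "t", lower = 0)
  r <- recycle2(em, t, "em", "t")
  enh <- .ebf_interface_raw(r$x, cf) - 1
  if (any(abs(enh) < 1e-12)) {
    abort_domain("Interface enhancement is zero: normalized intensity undefined.")
  }
  check_em_validity(r$x, EM_VALID, "the two-exponential interface model", strict)
  exp(-.decay_k_raw(r$x, cf) * r$y)
}

#' Energy of maximum interface enhancement
#'
#' Closed-form argmax of the two-exponential interface model,
#' `Em* = ln(c3 c4 / (c1 c2)) / (c4 - c2)`, valid when the logarithm's
#' argument is positive and the result is a positive energy.
#'
#' @inheritParams ebf_at_interface
#' @return The peak energy in MeV.
#' @examples
#' peak_enhancement_energy()
#' @export
peak_enhancement_energy <- function(coefficients = ebf_coefficients()) {
  cf <- as_ebf_coefficients(coefficients)
  if (abs(cf$c2 - cf$c4) < 1e-12) {
    abort_domain("Degenerate coefficient set: c2 = c4 has no interior peak.")
  }
  arg <- cf$c3 * cf$c4 / (cf$c1 * cf$c2)
  if (arg <= 0) abort_domain("Nonpositive log argument: model has no interior peak.")
  em_star <- log(arg) / (cf$c4 - cf$c2)
  if (!is.finite(em_star) || em_star <= 0) {
    abort_domain("Model has no interior enhancement peak for this coefficient set.")
  }
  em_star
}

#' Upstream distance at which the enhancement falls to a level
#'
#' Solves `EBF(Em, t) = 1 + epsilon` for `t`:
#' `t = ln((EBF(Em) - 1) / epsilon) / k(Em)`. A clinical query: how far
#' upstream of the shield the dose enhancement still exceeds `epsilon`.
#'
#' @inheritParams ebf_at_interface
#' @param em Mean energy at the interface, MeV.
#' @param epsilon Residual enhancement level (`0 < epsilon < EBF(Em) - 1`).
#' @return The distance in mm.
#' @examples
#' enhancement_range(1, 0.05)
#' @export
enhancement_range <- function(em, epsilon, coefficients = ebf_coefficients(),
                              strict = NULL) {
  cf <- as_ebf_coefficients(coefficients)
  assert_scalar_number(em, "em", lower = 0, strict_lower = TRUE)
  assert_scalar_number(epsilon, "epsilon", lower = 0, strict_lower = TRUE)
  enh <- .ebf_interface_raw(em, cf) - 1
  if (epsilon >= enh) {
    abort_domain(sprintf(
      "`epsilon` (%g) must be below the interface enhancement (%g).",
      epsilon, enh))
  }
  k <- .decay_k_raw(em, cf)
  if (k <= 0) {
    abort_domain("Decay coefficient is zero at this energy: infinite range.")
  }
  check_em_validity(em, EM_VALID, "the two-exponential interface model", strict)
  log(enh / epsilon) / k
}
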