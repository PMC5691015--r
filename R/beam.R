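# Beam-quality parameters and the linear mean-energy-with-depth relation.

# ICRU-style beam-quality constant: E0 [MeV] = 2.33 * R50 [cm].
C_MEV_PER_CM <- 2.33

#' Electron beam quality parameters
#'
#' Bundles the quantities needed to map depth to mean electron energy:
#' the mean energy at the phantom surface `E0`, the practical range `Rp`,
#' and (optionally) the half-value depth `R50` and nominal energy.
#'
#' @param e0 Mean surface energy in MeV (positive).
#' @param rp Practical range in mm (positive, `> r50`).
#' @param r50 Depth of the distal 50% dose level in mm (optional).
#' @param nominal Nominal accelerator energy label in MeV (optional).
#' @return An object of class `beam_parameters`.
#' @examples
#' b <- beam_parameters(e0 = 12, rp = 60)
#' mean_energy_at_depth(b, 30)
#' @export
beam_parameters <- function(e0, rp, r50 = NA_real_, nominal = NA_real_) {
  assert_scalar_number(e0, "e0", lower = 0, strict_lower = TRUE)
  assert_scalar_number(rp, "rp", lower = 0, strict_lower = TRUE)
  if (!is.na(r50)) {
    assert_scalar_number(r50, "r50", lower = 0, strict_lower = TRUE)
    if (r50 >= rp) abort_domain("`r50` must be smaller than `rp`.")
  }
  structure(list(e0 = e0, rp = rp, r50 = r50, nominal = nominal),
            class = "beam_parameters")
}

#' @export
print.beam_parameters <- function(x, ...) {
  cat(sprintf("<beam_parameters> E0 = %.3f MeV, Rp = %.1f mm, R50 = %s mm%s\n",
              x$e0, x$rp,
              if (is.na(x$r50)) "NA" else sprintf("%.1f", x$r50),
              if (is.na(x$nominal)) "" else sprintf(" (nominal %g MeV)", x$nominal)))
  invisible(x)
}

#' Mean surface energy from the half-value depth
#'
#' Applies the beam-quality relation `E0 = 2.33 * R50` with `R50` in cm
#' (the argument is in mm, consistent with every other depth in the package).
#'
#' @param r50 Half-value depth in mm (positive).
#' @return Mean surface energy in MeV.
#' @examples
#' e0_from_r50(38.6)
#' @export
e0_from_r50 <- function(r50) {
  assert_numeric_vector(r50, "r50", lower = 0, strict_lower = TRUE)
  C_MEV_PER_CM * r50 / 10
}

#' Mean electron energy at depth
#'
#' Linear approximation `Em = E0 * (1 - z / Rp)`, clamped at zero at and
#' beyond the practical range (no primary electrons remain there).
#'
#' @param beam A [beam_parameters()] object.
#' @param z Depth(s) in mm (non-negative).
#' @return Mean energy in MeV, same length as `z`.
#' @examples
#' mean_energy_at_depth(beam_parameters(e0 = 12, rp = 60), c(0, 30, 60))
#' @export
mean_energy_at_depth <- function(beam, z) {
  if (!inherits(beam, "beam_parameters")) {
    abort_domain("`beam` must be a beam_parameters object.")
  }
  assert_numeric_vector(z, "z", lower = 0)
  pmax(0, beam$e0 * (1 - z / beam$rp))
}
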