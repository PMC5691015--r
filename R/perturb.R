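# Extraction of backscatter observations from with/without-Pb curve pairs,
# and the inverse operation: perturbing a reference curve by a Pb slab.

#' Extract backscatter observations from a with/without-Pb curve pair
#'
#' For every voxel center strictly upstream of the interface, the
#' enhancement is the voxel-wise dose ratio with-Pb / without-Pb. Each
#' observation carries the (constant) mean energy at the interface depth,
#' computed from the beam parameters, and the geometric upstream distance
#' `t = interface depth - voxel center`. The observation with the smallest
#' `t` (half a voxel for an aligned grid) is flagged as the interface EBF,
#' following the convention that the interface value is attributed to the
#' center of the first upstream voxel.
#'
#' @param curve_pb Depth-dose curve scored with the Pb slab in place.
#' @param curve_ref Reference curve without Pb, on the same grid (or set
#'   `resample = TRUE` to linearly resample the reference onto the Pb
#'   grid; the Pb curve is never resampled, to preserve the sharp
#'   interface).
#' @param interface A [lead_interface()].
#' @param beam A [beam_parameters()] object used to map the interface
#'   depth to a mean energy.
#' @param resample Allow linear resampling of the reference curve.
#' @return A tibble of backscatter observations with columns `em_mev`,
#'   `t_mm`, `ebf` and logical `interface`, ordered by increasing `t_mm`.
#' @examples
#' cfg <- synthetic_config(preset = "9", noise_relative_sd = 0)
#' pair <- synth_pb_pair(cfg, lead_interface(20))
#' obs <- extract_backscatter(pair$pb, pair$ref, lead_interface(20),
#'                            beam_preset("9"))
#' head(obs)
#' @export
extract_backscatter <- function(curve_pb, curve_ref, interface, beam,
                                resample = FALSE) {
  curve_pb <- as_depth_dose(curve_pb)
  curve_ref <- as_depth_dose(curve_ref)
  if (!inherits(interface, "lead_interface")) {
    abort_domain("`interface` must be a lead_interface object.")
  }
  if (!inherits(beam, "beam_parameters")) {
    abort_domain("`beam` must be a beam_parameters object.")
  }

  same_grid <- nrow(curve_pb) == nrow(curve_ref) &&
    max(abs(curve_pb$depth_mm - curve_ref$depth_mm)) <= 1e-9
  if (!same_grid) {
    if (!resample) {
      abort_validation(paste0(
        "Depth grids differ (Pb curve: ", nrow(curve_pb), " voxels over ",
        min(curve_pb$depth_mm), "-", max(curve_pb$depth_mm), " mm; reference: ",
        nrow(curve_ref), " voxels over ", min(curve_ref$depth_mm), "-",
        max(curve_ref$depth_mm),
        " mm). Pass resample = TRUE to interpolate the reference curve."))
    }
    ref_dose <- stats::approx(curve_ref$depth_mm, curve_ref$dose,
                              xout = curve_pb$depth_mm, rule = 1)$y
    if (anyNA(ref_dose)) {
      abort_validation("Pb-curve grid extends beyond the reference curve; cannot resample.")
    }
    curve_ref <- depth_dose(curve_pb$depth_mm, ref_dose)
  }

  if (interface$depth > max(curve_pb$depth_mm) ||
      interface$depth <= min(curve_pb$depth_mm)) {
    abort_validation(sprintf(
      "Interface depth %g mm is outside the curve grid (%g-%g mm).",
      interface$depth, min(curve_pb$depth_mm), max(curve_pb$depth_mm)))
  }

  up <- curve_pb$depth_mm < interface$depth
  ref_dose <- curve_ref$dose[up]
  pb_dose <- curve_pb$dose[up]
  t <- interface$depth - curve_pb$depth_mm[up]

  keep <- ref_dose > 0
  if (any(!keep)) {
    rlang::warn(sprintf("Skipping %d voxel(s) with zero reference dose.",
                        sum(!keep)))
  }
  t <- t[keep]
  if (!length(t)) abort_validation("No usable upstream voxels before the interface.")

  em <- mean_energy_at_depth(beam, interface$depth)
  out <- tibble::tibble(
    em_mev = em,
    t_mm = t,
    ebf = pb_dose[keep] / ref_dose[keep],
    interface = t == min(t))
  dplyr::arrange(out, .data$t_mm)
}

#' Perturb a reference depth-dose curve by a lead slab
#'
#' Applies the composed enhancement model upstream of the interface and
#' zeroes the dose at and beyond it (a saturation-thickness slab is
#' treated as totally absorbing; transmission is out of scope). By
#' default the first upstream voxel receives the full interface EBF
#' (`t = 0` model value) rather than the value at its geometric offset,
#' mirroring the attribution convention used when interface EBF values
#' are scored at the first upstream voxel center; set
#' `interface_attribution = FALSE` for the purely geometric profile.
#' The output is not re-normalized.
#'
#' If the interface lies at or beyond the practical range, the mean
#' energy clamps to zero: no electrons reach the slab, so upstream doses
#' are unchanged (with a warning) and only the distal zeroing applies.
#'
#' @inheritParams extract_backscatter
#' @param coefficients An [ebf_coefficients()] set.
#' @param interface_attribution Attribute the `t = 0` interface EBF to the
#'   first upstream voxel (default `TRUE`).
#' @return The perturbed `depth_dose` tibble on the same grid.
#' @export
predict_perturbed_pdd <- function(curve_ref, interface, beam,
                                  coefficients = ebf_coefficients(),
                                  interface_attribution = TRUE) {
  curve_ref <- as_depth_dose(curve_ref)
  cf <- as_ebf_coefficients(coefficients)
  if (!inherits(interface, "lead_interface")) {
    abort_domain("`interface` must be a lead_interface object.")
  }
  if (!inherits(beam, "beam_parameters")) {
    abort_domain("`beam` must be a beam_parameters object.")
  }
  if (interface$depth > max(curve_ref$depth_mm)) {
    abort_validation(sprintf(
      "Interface depth %g mm is beyond the curve grid (max %g mm).",
      interface$depth, max(curve_ref$depth_mm)))
  }

  em <- mean_energy_at_depth(beam, interface$depth)
  up <- curve_ref$depth_mm < interface$depth
  out <- curve_ref
  if (em <= 0) {
    rlang::warn(paste0("Interface at or beyond the practical range: no ",
                       "electrons reach the slab, upstream doses unchanged."))
  } else if (any(up)) {
    t <- interface$depth - curve_ref$depth_mm[up]
    fac <- .ebf_upstream_raw(em, t, cf)
    if (interface_attribution) fac[which.min(t)] <- .ebf_interface_raw(em, cf)
    out$dose[up] <- out$dose[up] * fac
  }
  out$dose[!up] <- 0
  attr(out, "label") <- paste0(attr(curve_ref, "label") %||% "curve",
                               " + Pb at ", interface$depth, " mm")
  out
}
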