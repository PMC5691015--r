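# Central-axis depth-dose curves: construction, I/O, normalization,
# range scaling and beam-quality characterisation.

#' Central-axis depth-dose curve
#'
#' A depth-dose curve is a tibble with columns `depth_mm` (strictly
#' increasing voxel-center depths, mm) and `dose` (finite, non-negative,
#' on any positive scale; [normalize_to_dmax()] rescales to percent of
#' maximum). Depth 0 is the phantom surface.
#'
#' @param depth_mm Numeric vector of depths in mm.
#' @param dose Numeric vector of doses (same length).
#' @param label Optional free-text label stored as an attribute.
#' @return A tibble of class `depth_dose`.
#' @examples
#' depth_dose(c(0, 1, 2), c(85, 95, 100))
#' @export
depth_dose <- function(depth_mm, dose, label = NULL) {
  as_depth_dose(tibble::tibble(depth_mm = depth_mm, dose = dose), label = label)
}

#' @rdname depth_dose
#' @param x A data frame with columns `depth_mm` and `dose`.
#' @export
as_depth_dose <- function(x, label = NULL) {
  if (!is.data.frame(x)) abort_domain("`x` must be a data frame.")
  missing_cols <- setdiff(c("depth_mm", "dose"), names(x))
  if (length(missing_cols)) {
    abort_validation(sprintf("Missing required column(s): %s.",
                             paste(missing_cols, collapse = ", ")))
  }
  depth <- x$depth_mm
  dose <- x$dose
  if (!is.numeric(depth) || !is.numeric(dose) || anyNA(depth) || anyNA(dose) ||
      any(!is.finite(depth)) || any(!is.finite(dose))) {
    abort_validation("`depth_mm` and `dose` must be finite numeric columns.")
  }
  if (length(depth) && any(diff(depth) <= 0)) {
    row <- which(diff(depth) <= 0)[1L] + 1L
    abort_validation(sprintf(
      "Depths must be strictly increasing; row %d (depth %g mm) violates this.",
      row, depth[row]))
  }
  if (any(dose < 0)) {
    row <- which(dose < 0)[1L]
    abort_validation(sprintf("Negative dose at row %d (depth %g mm).",
                             row, depth[row]))
  }
  out <- tibble::tibble(depth_mm = depth, dose = dose)
  class(out) <- c("depth_dose", class(out))
  attr(out, "label") <- label %||% attr(x, "label", exact = TRUE)
  out
}

#' Grid spacing of a depth-dose curve
#'
#' @param curve A depth-dose curve.
#' @return The uniform spacing in mm, or `NA` if the grid is non-uniform
#'   (tolerance 1e-9) or has fewer than two points.
#' @export
voxel_size <- function(curve) {
  curve <- as_depth_dose(curve)
  d <- diff(curve$depth_mm)
  if (!length(d)) return(NA_real_)
  if (max(abs(d - d[1])) > 1e-9) return(NA_real_)
  d[1]
}

#' Read / write a depth-dose curve as CSV
#'
#' Files are comma-separated with header `depth_mm,dose`, one voxel per
#' row. Writing preserves full double precision, so a read/write round
#' trip reproduces values exactly.
#'
#' @param path File path.
#' @param curve A depth-dose curve.
#' @return `read_curve()` returns a `depth_dose` tibble (labelled with the
#'   file name); `write_curve()` returns `path` invisibly.
#' @export
read_curve <- function(path) {
  if (!file.exists(path)) abort_validation(sprintf("File not found: '%s'.", path))
  # base read.csv: correctly rounded double parsing, so %.17g output
  # round-trips bit-for-bit
  x <- utils::read.csv(path)
  as_depth_dose(tibble::as_tibble(x), label = basename(path))
}

#' @rdname read_curve
#' @export
write_curve <- function(curve, path) {
  curve <- as_depth_dose(curve)
  readr::write_csv(format_doubles(curve[c("depth_mm", "dose")]), path)
  invisible(path)
}

# Render double columns with 17 significant digits so that a write/read
# cycle reproduces every value bit-for-bit.
format_doubles <- function(df) {
  for (nm in names(df)) {
    if (is.double(df[[nm]])) df[[nm]] <- sprintf("%.17g", df[[nm]])
  }
  df
}

#' Normalize a curve to its maximum dose
#'
#' Rescales so the maximum dose equals 100 exactly (percentage depth
#' dose); the operation is idempotent and shape-preserving.
#'
#' @param curve A depth-dose curve with at least one positive dose.
#' @return The normalized `depth_dose` tibble.
#' @export
normalize_to_dmax <- function(curve) {
  curve <- as_depth_dose(curve)
  m <- max(curve$dose)
  if (m <= 0) abort_validation("Cannot normalize: no positive dose value.")
  curve$dose <- curve$dose / m * 100
  curve
}

#' Apply a range scaling correction
#'
#' Multiplies every depth by `factor`, converting depths measured in a
#' water-substitute phantom to water-equivalent depths; doses are
#' unchanged. Scaling by `f1` then `f2` equals scaling by `f1 * f2`.
#'
#' @param curve A depth-dose curve.
#' @param factor Positive scaling factor (a typical virtual-water value
#'   is about 1.02).
#' @return The rescaled `depth_dose` tibble.
#' @export
apply_range_scaling <- function(curve, factor) {
  assert_scalar_number(factor, "factor", lower = 0, strict_lower = TRUE)
  curve <- as_depth_dose(curve)
  curve$depth_mm <- curve$depth_mm * factor
  curve
}

#' Lead slab interface
#'
#' Position of the upstream face of a lead slab assumed thick enough for
#' saturation backscatter (so slab transmission is total absorption).
#'
#' @param depth Depth of the upstream face in mm (positive).
#' @param thickness Slab thickness in mm (positive; 5 mm is a typical
#'   saturation thickness for clinical energies).
#' @return An object of class `lead_interface`.
#' @export
lead_interface <- function(depth, thickness = 5) {
  assert_scalar_number(depth, "depth", lower = 0, strict_lower = TRUE)
  assert_scalar_number(thickness, "thickness", lower = 0, strict_lower = TRUE)
  structure(list(depth = depth, thickness = thickness), class = "lead_interface")
}

#' Characterise beam quality from a depth-dose curve
#'
#' Determines `R50` (distal 50% crossing, linear interpolation), the
#' practical range `Rp` (tangent at the steepest distal gradient
#' intersected with the extrapolated bremsstrahlung-tail level), and the
#' mean surface energy `E0 = 2.33 * R50` (R50 in cm). The curve is
#' normalized internally, so any positive dose scale is accepted.
#'
#' The tail level is estimated as the mean dose over the last
#' `tail_fraction` of the grid; the gradient uses central differences. A
#' non-monotone distal falloff triggers a warning and the steepest-descent
#' point is used regardless.
#'
#' @param curve A depth-dose curve whose distal falloff crosses 50%.
#' @param tail_fraction Fraction of the grid (from the deep end) averaged
#'   for the bremsstrahlung-tail level. Default 0.1.
#' @return A [beam_parameters()] object with `e0`, `rp` and `r50` filled in.
#' @export
beam_quality <- function(curve, tail_fraction = 0.1) {
  assert_scalar_number(tail_fraction, "tail_fraction", lower = 0, upper = 0.5,
                       strict_lower = TRUE)
  cv <- normalize_to_dmax(curve)
  z <- cv$depth_mm
  d <- cv$dose
  n <- length(z)
  if (n < 5) abort_validation("Curve too short to characterise (need >= 5 points).")
  imax <- which.max(d)

  # distal 50% crossing (last crossing from >= 50 to < 50)
  cross <- which(d[imax:(n - 1)] >= 50 & d[(imax + 1):n] < 50) + imax - 1L
  if (!length(cross)) {
    abort_validation("Curve does not fall below 50% of maximum: cannot locate R50.")
  }
  i <- cross[length(cross)]
  r50 <- z[i] + (50 - d[i]) * (z[i + 1] - z[i]) / (d[i + 1] - d[i])

  n_tail <- max(3L, ceiling(tail_fraction * n))
  tail_level <- mean(d[(n - n_tail + 1L):n])

  # non-monotone distal region (excluding the tail) -> warn, keep going
  fall <- d[imax:(n - n_tail)]
  if (length(fall) > 1 && any(diff(fall) > 0.5)) {
    rlang::warn(paste0("Non-monotone distal falloff; using the ",
                       "steepest-descent point for the practical range."))
  }

  # steepest distal gradient by central differences
  idx <- seq(max(imax + 1L, 2L), n - 1L)
  grad <- (d[idx + 1L] - d[idx - 1L]) / (z[idx + 1L] - z[idx - 1L])
  i_star <- idx[which.min(grad)]
  g <- min(grad)
  if (!is.finite(g) || g >= 0) {
    abort_numeric("No negative distal gradient found: cannot construct Rp.")
  }
  rp <- z[i_star] + (tail_level - d[i_star]) / g
  if (!is.finite(rp) || rp <= r50) {
    abort_numeric("Practical-range construction failed (Rp <= R50).")
  }
  beam_parameters(e0 = e0_from_r50(r50), rp = rp, r50 = r50)
}
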