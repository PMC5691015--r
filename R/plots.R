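# ggplot2 displays for curves, model shapes and fits.

#' Plot a depth-dose curve
#'
#' @param object A `depth_dose` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.depth_dose <- function(object, ...) {
  object <- as_depth_dose(object)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$depth_mm, y = .data$dose)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "depth (mm)", y = "relative dose (%)",
                  title = attr(object, "label", exact = TRUE)) +
    ggplot2::theme_minimal()
}

#' Overlay a with/without-Pb curve pair
#'
#' @param pb,ref Depth-dose curves with and without the Pb slab.
#' @return A ggplot object.
#' @export
plot_pdd_pair <- function(pb, ref) {
  df <- dplyr::bind_rows(
    dplyr::mutate(as_depth_dose(ref), curve = "without Pb"),
    dplyr::mutate(as_depth_dose(pb), curve = "with Pb"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$depth_mm, y = .data$dose,
                                   colour = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "depth (mm)", y = "relative dose (%)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the interface EBF model over energy
#'
#' Draws the two-exponential interface model, optionally overlaid with
#' the legacy single-exponential relation and with observed interface
#' values.
#'
#' @param coefficients An [ebf_coefficients()] set.
#' @param em_grid Energy grid in MeV.
#' @param legacy Overlay the legacy relation (default `TRUE`).
#' @param observations Optional observation tibble; its interface-flagged
#'   rows are drawn as points.
#' @return A ggplot object.
#' @export
plot_ebf_model <- function(coefficients = ebf_coefficients(),
                           em_grid = seq(0.2, 14, by = 0.1),
                           legacy = TRUE, observations = NULL) {
  cf <- as_ebf_coefficients(coefficients)
  tbl <- compare_interface_models(cf, em_grid) |>
    tidyr::pivot_longer(c("ebf_fitted", "ebf_legacy"), names_to = "model",
                        names_prefix = "ebf_", values_to = "ebf")
  if (!legacy) tbl <- dplyr::filter(tbl, .data$model != "legacy")
  p <- ggplot2::ggplot(tbl, ggplot2::aes(x = .data$em_mev, y = .data$ebf,
                                         colour = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "mean energy at interface (MeV)",
                  y = "electron backscatter factor", colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(observations) && "interface" %in% names(observations)) {
    pts <- dplyr::filter(observations, .data$interface)
    p <- p + ggplot2::geom_point(
      data = pts, ggplot2::aes(x = .data$em_mev, y = .data$ebf),
      inherit.aes = FALSE, alpha = 0.5)
  }
  p
}

#' Plot a fit: observed against fitted values
#'
#' @param object An `ebf_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ebf_fit <- function(object, ...) {
  if (is.null(object$fitted)) {
    abort_validation("This fit carries no fitted values to plot.")
  }
  df <- tibble::tibble(fitted = object$fitted,
                       observed = object$fitted + object$residuals)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fitted, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::labs(x = "fitted EBF", y = "observed EBF",
                  title = sprintf("%s model fit (RMSE %.3g)",
                                  object$model, object$rmse)) +
    ggplot2::theme_minimal()
}
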