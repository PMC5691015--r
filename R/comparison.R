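# Comparison of the fitted model against observations and against the
# legacy single-exponential equations.

#' Deviation statistics of observations against the model
#'
#' Computes per-observation ratios observed/predicted (the film-style
#' validation statistic) and summarizes them: mean ratio, standard
#' deviation (1 sigma), mean and maximum absolute percent deviation, and
#' the number of observations. Interface-flagged observations are
#' predicted at `t = 0`; all others at their geometric upstream distance.
#'
#' @param observed A non-empty data frame with columns `em_mev`, `t_mm`,
#'   `ebf` and optionally `interface`.
#' @param coefficients An [ebf_coefficients()] set.
#' @param exclude Optional data frame of series to drop before computing
#'   statistics: rows are removed by anti-join on the shared columns
#'   (e.g. a tibble of `preset`/`interface_depth_mm` pairs for a series
#'   measured under non-saturation conditions).
#' @return A one-row tibble: `mean_ratio`, `sd_ratio`,
#'   `mean_abs_percent_dev`, `max_abs_percent_dev`, `n`.
#' @examples
#' obs <- synth_observation_set(presets = "9", noise_relative_sd = 0)
#' deviation_stats(obs, ebf_coefficients())
#' @export
deviation_stats <- function(observed, coefficients = ebf_coefficients(),
                            exclude = NULL) {
  check_observations(observed)
  cf <- as_ebf_coefficients(coefficients)
  if (!is.null(exclude)) {
    shared <- intersect(names(observed), names(exclude))
    if (!length(shared)) {
      abort_validation("`exclude` shares no columns with `observed`.")
    }
    observed <- dplyr::anti_join(observed, exclude, by = shared)
    if (!nrow(observed)) abort_validation("All observations were excluded.")
  }
  pred <- predict_observations(observed, cf)
  if (any(pred <= 0)) abort_numeric("Model predictions must be positive.")
  ratio <- observed$ebf / pred
  pdev <- 100 * (observed$ebf - pred) / pred
  n <- length(ratio)
  tibble::tibble(
    mean_ratio = mean(ratio),
    sd_ratio = if (n > 1) stats::sd(ratio) else 0,
    mean_abs_percent_dev = mean(abs(pdev)),
    max_abs_percent_dev = max(abs(pdev)),
    n = n)
}

#' Compare the two-exponential and legacy interface models
#'
#' Tabulates the interface EBF of the two-exponential model beside the
#' legacy single-exponential relation over an energy grid, with the
#' percent difference `100 * (legacy - fitted) / fitted` (so a legacy
#' overestimate reads as positive). The attribute `mean_percent_diff`
#' carries the grid average.
#'
#' @param coefficients An [ebf_coefficients()] set.
#' @param em_grid Energy grid in MeV (positive).
#' @return A tibble with columns `em_mev`, `ebf_fitted`, `ebf_legacy`,
#'   `percent_diff`.
#' @examples
#' compare_interface_models(em_grid = c(1, 5, 10))
#' @export
compare_interface_models <- function(coefficients = ebf_coefficients(),
                                     em_grid = seq(0.2, 14, by = 0.2)) {
  cf <- as_ebf_coefficients(coefficients)
  assert_numeric_vector(em_grid, "em_grid", lower = 0, strict_lower = TRUE)
  fitted <- .ebf_interface_raw(em_grid, cf)
  legacy <- 1 + 0.735 * exp(-0.052 * em_grid)
  out <- tibble::tibble(
    em_mev = em_grid,
    ebf_fitted = fitted,
    ebf_legacy = legacy,
    percent_diff = 100 * (legacy - fitted) / fitted)
  attr(out, "mean_percent_diff") <- mean(out$percent_diff)
  out
}

#' Compare decay coefficients against legacy models
#'
#' Tabulates the fitted `k(Em)` beside user-supplied legacy decay models
#' over an energy grid. Each legacy model is a list with elements
#' `label`, `k` (a constant or a function of `Em`) and optionally
#' `validity = c(lo, hi)` in MeV; outside its validity range a model's
#' cells are `NA`. With no legacy models the fitted column stands alone.
#'
#' @param coefficients An [ebf_coefficients()] set.
#' @param legacy_models List of legacy model descriptions (may be empty;
#'   their constants are not bundled and must be supplied).
#' @param em_grid Energy grid in MeV (positive).
#' @return A tibble with `em_mev`, `k_fitted`, and one `k_<label>` column
#'   per legacy model.
#' @examples
#' compare_decay_coefficients(
#'   legacy_models = list(list(label = "const", k = 0.3, validity = c(1, 25))),
#'   em_grid = c(1, exp(1), 8))
#' @export
compare_decay_coefficients <- function(coefficients = ebf_coefficients(),
                                       legacy_models = list(),
                                       em_grid = seq(0.2, 14, by = 0.2)) {
  cf <- as_ebf_coefficients(coefficients)
  assert_numeric_vector(em_grid, "em_grid", lower = 0, strict_lower = TRUE)
  out <- tibble::tibble(em_mev = em_grid, k_fitted = .decay_k_raw(em_grid, cf))
  for (m in legacy_models) {
    if (is.null(m$label) || is.null(m$k)) {
      abort_validation("Each legacy model needs `label` and `k` elements.")
    }
    kv <- if (is.function(m$k)) m$k(em_grid) else rep(m$k, length(em_grid))
    if (!is.null(m$validity)) {
      kv[em_grid < m$validity[1] | em_grid > m$validity[2]] <- NA_real_
    }
    out[[paste0("k_", m$label)]] <- kv
  }
  out
}
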