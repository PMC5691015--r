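# Staged coefficient estimation: interface fit, per-energy decay fits,
# decay-model regression, and the composed pipeline.

test_that("interface fit recovers the generating coefficients exactly", {
  obs <- make_interface_obs(60)
  fit <- fit_interface_model(obs)
  expect_true(fit$converged)
  expect_rel_equal(fit$estimates, default_truth[1:4], 1e-4)
  expect_lt(fit$rmse, 1e-8)
  expect_length(fit$residuals, 60)
  expect_true(all(fit$ci_halfwidths >= 0))
})

test_that("interface fit rejects under-determined inputs", {
  expect_error(fit_interface_model(make_interface_obs(3)),
               class = "ebftools_validation_error")
  narrow <- make_interface_obs(20, em = seq(2, 5, length.out = 20))
  expect_error(fit_interface_model(narrow),
               regexp = "span", class = "ebftools_validation_error")
})

test_that("per-energy decay fit is exact on log-linear data", {
  prof <- make_decay_profile(exp(1))
  res <- fit_decay_per_energy(prof)
  expect_equal(res$k, 0.283, tolerance = 1e-10)
  expect_equal(res$interface_enhancement,
               suppressWarnings(ebf_at_interface(exp(1))) - 1,
               tolerance = 1e-10)
  # constant profile (no decay)
  flat <- tibble::tibble(t_mm = 1:5, ebf = rep(1.3, 5))
  expect_equal(fit_decay_per_energy(flat)$k, 0)
  expect_error(fit_decay_per_energy(prof[1:2, ]),
               class = "ebftools_validation_error")
})

test_that("per-energy decay fit drops unusable points with a warning", {
  prof <- tibble::tibble(t_mm = c(1, 2, 3, 4, 5),
                         ebf = c(1.4, 1.3, 1.2, 0.99, 1.0))
  expect_warning(res <- fit_decay_per_energy(prof), regexp = "ebf <= 1")
  expect_equal(res$n_used, 3)
  all_bad <- tibble::tibble(t_mm = 1:4, ebf = rep(0.9, 4))
  expect_warning(expect_error(fit_decay_per_energy(all_bad),
                              class = "ebftools_validation_error"))
})

test_that("decay-model regression reproduces the log-linear relation", {
  em <- c(0.5, 1, 2, 4, 8)
  kt <- tibble::tibble(em_mev = em, k = decay_coefficient(em))
  fit <- fit_decay_model(kt)
  expect_equal(unname(fit$estimates), c(0.130, 0.413), tolerance = 1e-12)
  # constant k has zero slope
  const <- tibble::tibble(em_mev = em, k = 0.3)
  expect_equal(unname(fit_decay_model(const)$estimates[1]), 0)
  expect_error(fit_decay_model(tibble::tibble(em_mev = c(0, 1, 2), k = 1:3)),
               class = "ebftools_domain_error")
  expect_error(fit_decay_model(kt[1:2, ]), class = "ebftools_validation_error")
})

test_that("full staged fit recovers all six coefficients from clean data", {
  obs <- synth_observation_set(presets = c("6", "12"), noise_relative_sd = 0)
  fit <- fit_full(obs)
  expect_rel_equal(fit$estimates, default_truth, 1e-3)
  expect_true(fit$converged)
  expect_s3_class(fit$coefficients, "ebf_coefficients")
  expect_length(fit$residuals, nrow(obs))
  # the geometric interface convention fits the t = 0 extrapolations instead
  fit_g <- fit_full(obs, interface_t = "geometric")
  expect_rel_equal(fit_g$estimates, default_truth, 1e-3)
})

test_that("full staged fit demands upstream profiles", {
  obs <- synth_observation_set(presets = "9", noise_relative_sd = 0)
  iface_only <- dplyr::filter(obs, interface)
  expect_error(fit_full(iface_only), regexp = "upstream",
               class = "ebftools_validation_error")
})

test_that("fit RMSE grows with the noise level", {
  rmse_at <- function(sd) {
    mean(purrr::map_dbl(1:3, function(i) {
      withr::with_seed(100 + i, {
        fit_interface_model(make_interface_obs(60, noise_sd = sd))$rmse
      })
    }))
  }
  r <- vapply(c(0, 0.005, 0.01, 0.02), rmse_at, numeric(1))
  expect_true(all(diff(r) > 0))
})

test_that("noisy estimates are on the scale of the published uncertainties", {
  # The published 95% half-widths are (0.132, 0.012, 0.126, 0.065); at 1%
  # multiplicative noise the estimator is median-unbiased but heavy-tailed,
  # so containment is checked at rates supported by simulation.
  withr::local_seed(2024)
  pub <- c(0.132, 0.012, 0.126, 0.065)
  within <- t(replicate(100, {
    fit <- fit_interface_model(make_interface_obs(60, noise_sd = 0.01))
    abs(fit$estimates - default_truth[1:4]) <= pub
  }))
  expect_gte(mean(apply(within, 1, all)), 0.70)
  expect_true(all(colMeans(within) >= 0.80))
})

test_that("tidy and glance summarise fits in broom style", {
  obs <- make_interface_obs(30)
  fit <- fit_interface_model(obs)
  td <- tidy(fit)
  expect_equal(td$term, c("c1", "c2", "c3", "c4"))
  expect_equal(td$conf.high - td$conf.low, 2 * td$ci_halfwidth)
  gl <- glance(fit)
  expect_equal(gl$n_observations, 30)
  expect_equal(gl$model, "interface")
})

test_that("observation tables round-trip through CSV", {
  obs <- synth_observation_set(presets = "6", noise_relative_sd = 0)
  path <- withr::local_tempfile(fileext = ".csv")
  write_observations(obs, path)
  back <- read_observations(path)
  expect_equal(back$ebf, obs$ebf)
  expect_identical(back$interface, obs$interface)
})
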