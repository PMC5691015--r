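# Closed-form model evaluations, their domain checks, and the analytic
# solvers cross-checked against brute-force oracles.

test_that("mean energy at depth is linear in z and clamps beyond Rp", {
  expect_equal(mean_energy_at_depth(beam_parameters(e0 = 12, rp = 60), 30), 6)
  expect_equal(mean_energy_at_depth(beam_parameters(e0 = 9, rp = 45), 0), 9)
  expect_equal(mean_energy_at_depth(beam_parameters(e0 = 6, rp = 30), 35), 0)
  expect_error(mean_energy_at_depth(beam_parameters(e0 = 6, rp = 30), -1),
               class = "ebftools_domain_error")
})

test_that("mean surface energy follows 2.33 * R50 with mm input", {
  expect_equal(e0_from_r50(10), 2.33)
  expect_equal(e0_from_r50(38.6), 8.9938)
  expect_error(e0_from_r50(0), class = "ebftools_domain_error")
})

test_that("legacy single-exponential EBF evaluates and warns outside 3-35 MeV", {
  expect_warning(v0 <- ebf_klevenhagen(0), class = "ebftools_validity_warning")
  expect_equal(v0, 1.735)
  expect_equal(ebf_klevenhagen(10), 1 + 0.735 * exp(-0.52))
  expect_lt(abs(ebf_klevenhagen(35) - 1), 0.12)
  expect_equal(ebf_klevenhagen(c(5, 20, 34)),
               1 + 0.735 * exp(-0.052 * c(5, 20, 34)))
  expect_error(ebf_klevenhagen(-1), class = "ebftools_domain_error")
  expect_error(ebf_klevenhagen(1, strict = TRUE),
               class = "ebftools_domain_error")
})

test_that("legacy upstream-intensity decay matches A exp(-kt)", {
  m <- legacy_decay_model(0.5, 0.3)
  expect_equal(ebi_legacy(0, m), 0.5)
  expect_equal(ebi_legacy(log(2) / 0.3, legacy_decay_model(1, 0.3)), 0.5)
  expect_equal(ebi_legacy(5, legacy_decay_model(0.44, 0.413)),
               0.44 * exp(-0.413 * 5))
  expect_error(ebi_legacy(-1, m), class = "ebftools_domain_error")
  expect_error(legacy_decay_model(-1, 0.3), class = "ebftools_domain_error")
})

test_that("two-exponential interface EBF reproduces hand-computed values", {
  expect_equal(ebf_at_interface(4), 1.521318, tolerance = 1e-6)
  expect_equal(ebf_at_interface(1), 1.442547, tolerance = 1e-6)
  expect_warning(v0 <- ebf_at_interface(0), class = "ebftools_validity_warning")
  expect_equal(v0, 1 + 0.936 - 0.602)
  expect_error(ebf_at_interface(-0.5), class = "ebftools_domain_error")
  # custom coefficient sets are honoured
  cf <- ebf_coefficients(0.8, 0.1, 0.3, 0.5)
  expect_equal(ebf_at_interface(2, cf),
               1 + 0.8 * exp(-0.2) - 0.3 * exp(-1))
})

test_that("decay coefficient is log-linear in energy, clamped at zero", {
  expect_equal(decay_coefficient(1), 0.413)
  expect_equal(decay_coefficient(exp(1)), 0.283)
  expect_warning(k30 <- decay_coefficient(30), class = "ebftools_validity_warning")
  expect_equal(k30, 0)
  expect_error(decay_coefficient(0), class = "ebftools_domain_error")
  # non-increasing over the validated energy range
  k <- decay_coefficient(seq(0.2, 14, by = 0.1))
  expect_true(all(diff(k) <= 0))
})

test_that("upstream enhancement reduces to the interface value at t = 0", {
  em <- seq(0.2, 14, by = 0.1)
  expect_identical(ebf_upstream(em, 0), ebf_at_interface(em))
})

test_that("upstream enhancement decays monotonically to 1 and stays >= 1", {
  expect_equal(ebf_upstream(1, 5), 1.056123, tolerance = 1e-6)
  expect_equal(ebf_upstream(1, 1e4), 1)
  for (em in c(0.2, 0.5, 1, 2, 4, 8, 14)) {
    prof <- ebf_upstream(em, seq(0, 25, by = 0.25))
    expect_true(all(diff(prof) <= 0))
    expect_true(all(prof >= 1))
  }
  expect_error(ebf_upstream(1, -1), class = "ebftools_domain_error")
})

test_that("both interface models approach unity at high energy", {
  expect_equal(suppressWarnings(ebf_klevenhagen(500)), 1, tolerance = 1e-6)
  expect_equal(suppressWarnings(ebf_at_interface(500)), 1, tolerance = 1e-6)
})

test_that("normalized upstream intensity is exp(-k t)", {
  expect_equal(normalized_ebi(1, 0), 1)
  expect_equal(normalized_ebi(1, log(2) / 0.413), 0.5)
  expect_equal(normalized_ebi(exp(1), 10), exp(-2.83), tolerance = 1e-9)
  # zero interface enhancement -> undefined
  cf <- suppressWarnings(ebf_coefficients(0.5, 0.2, 0.5, 0.2,
                                          ci_halfwidths = NULL))
  expect_error(normalized_ebi(3, 1, cf), class = "ebftools_domain_error")
})

test_that("closed-form peak energy matches a grid-search oracle", {
  em_star <- peak_enhancement_energy()
  expect_equal(em_star, log(0.602 * 0.375 / (0.936 * 0.089)) / (0.375 - 0.089))
  # independent oracle: dense grid argmax
  grid <- seq(0.2, 14, by = 1e-4)
  vals <- suppressWarnings(ebf_at_interface(grid))
  expect_lt(abs(em_star - grid[which.max(vals)]), 2e-4)
  expect_true(all(ebf_at_interface(em_star) >= vals))
  expect_equal(ebf_at_interface(em_star), 1.523453, tolerance = 1e-6)
  # degenerate and peak-free sets
  expect_error(
    peak_enhancement_energy(suppressWarnings(
      ebf_coefficients(1, 0.3, 0.5, 0.3, ci_halfwidths = NULL))),
    class = "ebftools_domain_error")
  expect_error(peak_enhancement_energy(ebf_coefficients(2, 0.3, 0.1, 0.35)),
               class = "ebftools_domain_error")
})

test_that("closed-form enhancement range matches a root-finding oracle", {
  # half-enhancement distance is the decay half-life
  enh1 <- ebf_at_interface(1) - 1
  expect_equal(enhancement_range(1, enh1 / 2), log(2) / 0.413)
  t_eps <- enhancement_range(1, 0.05)
  expect_equal(t_eps, 5.27972, tolerance = 1e-5)
  # independent oracle: bisection on the upstream model
  oracle <- uniroot(function(t) ebf_upstream(1, t) - 1.05,
                    c(0, 50), tol = 1e-12)$root
  expect_equal(t_eps, oracle, tolerance = 1e-6)
  # returned distance satisfies the defining identity
  expect_equal(ebf_upstream(1, t_eps), 1.05, tolerance = 1e-9)
  expect_error(enhancement_range(1, enh1 + 0.1), class = "ebftools_domain_error")
  expect_error(suppressWarnings(enhancement_range(30, 0.01)),
               class = "ebftools_domain_error")
})

test_that("coefficient sets validate, serialize and round-trip", {
  cf <- ebf_coefficients()
  expect_s3_class(cf, "ebf_coefficients")
  expect_equal(unname(coef(cf)), c(0.936, 0.089, 0.602, 0.375, 0.130, 0.413))
  expect_error(ebf_coefficients(c1 = -1), class = "ebftools_domain_error")
  expect_warning(ebf_coefficients(0.9, 0.5, 0.6, 0.3, ci_halfwidths = NULL))
  # packaged default file carries the published values
  packaged <- read_coefficients(default_coefficients_path())
  expect_equal(coef(packaged), coef(cf))
  expect_equal(packaged$ci_halfwidths, cf$ci_halfwidths)
  # JSON round trip
  path <- withr::local_tempfile(fileext = ".json")
  write_coefficients(cf, path)
  expect_equal(read_coefficients(path), cf)
})
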