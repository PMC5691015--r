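# Shared fixture builders. Everything is generated in code; no stored data.

default_truth <- coef(ebf_coefficients())

# Interface observations on an energy grid, EBF values from the default
# model, optional multiplicative Gaussian noise (draws from the current
# RNG state; callers seed with withr::local_seed).
make_interface_obs <- function(n = 60, noise_sd = 0,
                               em = seq(0.2, 14, length.out = n),
                               coefficients = ebf_coefficients()) {
  ebf <- suppressWarnings(ebf_at_interface(em, coefficients))
  if (noise_sd > 0) ebf <- ebf * (1 + stats::rnorm(length(em), 0, noise_sd))
  tibble::tibble(em_mev = em, ebf = ebf)
}

# Upstream decay profile at a single energy (noise-free model values).
make_decay_profile <- function(em, t = seq(0.5, 10, by = 0.5),
                               coefficients = ebf_coefficients()) {
  tibble::tibble(em_mev = em, t_mm = t,
                 ebf = suppressWarnings(ebf_upstream(em, t, coefficients)))
}

expect_rel_equal <- function(actual, expected, rel_tol) {
  expect_true(all(abs(actual - expected) <= rel_tol * abs(expected)),
              label = sprintf("max relative error %.3g <= %.3g",
                              max(abs(actual - expected) / abs(expected)),
                              rel_tol))
}
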