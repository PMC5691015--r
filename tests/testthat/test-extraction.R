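# Backscatter extraction from curve pairs and the inverse perturbation.

test_that("extraction is an exact voxel-wise ratio", {
  ref <- depth_dose(seq(0.5, 39.5, by = 1), rep(100, 40))
  profile <- 1 + 0.4 * exp(-0.3 * (30 - seq(0.5, 29.5, by = 1)))
  pb <- depth_dose(ref$depth_mm, c(ref$dose[1:30] * profile, rep(0, 10)))
  obs <- extract_backscatter(pb, ref, lead_interface(30),
                             beam_parameters(e0 = 8, rp = 40))
  expect_equal(nrow(obs), 30)
  # observations come back ordered by t; the imposed profile is in depth order
  expect_equal(obs$ebf, rev(profile), tolerance = 1e-12)
  expect_equal(obs$t_mm, seq(0.5, 29.5, by = 1))
  expect_true(obs$interface[1] && !any(obs$interface[-1]))
  expect_equal(unique(obs$em_mev), 8 * (1 - 30 / 40))
})

test_that("noise-free synthetic pairs return the generating model values", {
  cfg <- synthetic_config("12", noise_relative_sd = 0)
  iface <- lead_interface(30)
  pair <- synth_pb_pair(cfg, iface)
  beam <- beam_preset("12")
  obs <- extract_backscatter(pair$pb, pair$ref, iface, beam)
  em <- mean_energy_at_depth(beam, 30)
  nonif <- !obs$interface
  expect_equal(obs$ebf[nonif],
               suppressWarnings(ebf_upstream(em, obs$t_mm[nonif])),
               tolerance = 1e-12)
  # the flagged observation carries the t = 0 interface EBF
  expect_equal(obs$ebf[obs$interface],
               suppressWarnings(ebf_at_interface(em)), tolerance = 1e-12)
})

test_that("grid handling: mismatch errors, resampling recovers, bounds checked", {
  cfg <- synthetic_config("9", noise_relative_sd = 0)
  iface <- lead_interface(20)
  pair <- synth_pb_pair(cfg, iface)
  beam <- beam_preset("9")
  shifted <- depth_dose(pair$ref$depth_mm + 0.25, pair$ref$dose)
  expect_error(extract_backscatter(pair$pb, shifted, iface, beam),
               regexp = "resample", class = "ebftools_validation_error")
  # resampling onto a coarser Pb grid hits shared nodes exactly
  pb_sub <- as_depth_dose(pair$pb[3:(nrow(pair$pb) - 3), ])
  obs_rs <- extract_backscatter(pb_sub, pair$ref, iface, beam, resample = TRUE)
  obs <- extract_backscatter(pair$pb, pair$ref, iface, beam)
  expect_equal(obs_rs$ebf, obs$ebf[obs$t_mm %in% obs_rs$t_mm],
               tolerance = 1e-12)
  expect_error(extract_backscatter(pair$pb, pair$ref, lead_interface(500), beam),
               class = "ebftools_validation_error")
})

test_that("zero reference-dose voxels are skipped with a warning", {
  ref <- depth_dose(seq(0.5, 9.5), c(0, rep(100, 9)))
  pb <- depth_dose(ref$depth_mm, c(0, rep(110, 8), 0))
  expect_warning(
    obs <- extract_backscatter(pb, ref, lead_interface(9),
                               beam_parameters(e0 = 6, rp = 30)),
    regexp = "zero reference")
  expect_equal(nrow(obs), 8)
})

test_that("perturbation applies the model upstream and zeroes the slab shadow", {
  cfg <- synthetic_config("9", noise_relative_sd = 0)
  ref <- synth_reference_pdd(cfg)
  beam <- beam_preset("9")
  iface <- lead_interface(beam$rp / 2)
  out <- predict_perturbed_pdd(ref, iface, beam)
  up <- ref$depth_mm < iface$depth
  # construction identity at geometric t for non-interface voxels
  t <- iface$depth - ref$depth_mm[up]
  em <- mean_energy_at_depth(beam, iface$depth)
  fac <- out$dose[up] / ref$dose[up]
  expect_equal(fac[-which.min(t)],
               suppressWarnings(ebf_upstream(em, t[-which.min(t)])),
               tolerance = 1e-12)
  # mid-range slab: interface voxel carries EBF(E0 / 2)
  expect_equal(fac[which.min(t)],
               suppressWarnings(ebf_at_interface(beam$e0 / 2)),
               tolerance = 1e-9)
  expect_true(all(out$dose[!up] == 0))
  # geometric mode drops the attribution convention
  out_g <- predict_perturbed_pdd(ref, iface, beam, interface_attribution = FALSE)
  facg <- out_g$dose[up] / ref$dose[up]
  expect_equal(facg, suppressWarnings(ebf_upstream(em, t)), tolerance = 1e-12)
})

test_that("slab beyond the practical range leaves upstream dose unchanged", {
  cfg <- synthetic_config("6", noise_relative_sd = 0)
  ref <- synth_reference_pdd(cfg)
  beam <- beam_preset("6")
  expect_warning(out <- predict_perturbed_pdd(ref, lead_interface(45), beam),
                 regexp = "practical range")
  up <- ref$depth_mm < 45
  expect_equal(out$dose[up], ref$dose[up])
  expect_true(all(out$dose[!up] == 0))
  expect_error(predict_perturbed_pdd(ref, lead_interface(1000), beam),
               class = "ebftools_validation_error")
})

test_that("extraction inverts prediction exactly (round trip)", {
  cfg <- synthetic_config("15", noise_relative_sd = 0)
  ref <- synth_reference_pdd(cfg)
  beam <- beam_preset("15")
  iface <- lead_interface(40)
  pred <- predict_perturbed_pdd(ref, iface, beam)
  obs <- extract_backscatter(pred, ref, iface, beam)
  em <- mean_energy_at_depth(beam, iface$depth)
  expect_equal(obs$ebf[!obs$interface],
               suppressWarnings(ebf_upstream(em, obs$t_mm[!obs$interface])),
               tolerance = 1e-12)
  expect_equal(obs$ebf[obs$interface],
               suppressWarnings(ebf_at_interface(em)), tolerance = 1e-12)
})
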