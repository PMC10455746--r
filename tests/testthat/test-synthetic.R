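test_that("gen_spectrum realizes the band-sum model", {
  # empty sum: no bands, no baseline, no noise
  m0 <- spectrum_model(bands = NULL, noise_sd = 0)
  expect_true(all(gen_spectrum(m0)$intensity == 0))

  # one Gaussian band peaks at its center with its amplitude
  m1 <- single_ha_model(amplitude = 100, sigma = 8)
  s1 <- gen_spectrum(m1)
  expect_equal(max(s1$intensity), 100)
  expect_equal(s1$wavenumber[which.max(s1$intensity)], 960)

  # amplitudes are linear: doubling a band doubles its peak (noiseless)
  m2 <- single_ha_model(amplitude = 200, sigma = 8)
  expect_equal(max(gen_spectrum(m2)$intensity), 200)

  # polynomial baseline is added pointwise
  mb <- spectrum_model(bands = NULL, baseline_coeffs = c(10, 0.5))
  sb <- gen_spectrum(mb)
  expect_equal(sb$intensity, 10 + 0.5 * sb$wavenumber)
})

test_that("generators are pure functions of their model (seed determinism)", {
  m <- spectrum_model(noise_sd = 2, seed = 11)
  expect_identical(gen_spectrum(m)$intensity, gen_spectrum(m)$intensity)

  set_a <- gen_spectrum_set(m, 5, jitter = 0.05)
  set_b <- gen_spectrum_set(m, 5, jitter = 0.05)
  expect_identical(lapply(set_a$spectra, `[[`, "intensity"),
                   lapply(set_b$spectra, `[[`, "intensity"))

  fm <- flexure_model(noise_sd = 0.2, seed = 3)
  expect_identical(gen_flexure_curve(fm)$curve, gen_flexure_curve(fm)$curve)

  dm <- degradation_model(noise_sd = 0.05, seed = 5)
  expect_identical(gen_degradation_series(dm)$ph,
                   gen_degradation_series(dm)$ph)

  expect_identical(gen_mass_table(0.145, 20, noise_sd = 0.02, seed = 9),
                   gen_mass_table(0.145, 20, noise_sd = 0.02, seed = 9))

  # the caller's RNG stream is not consumed by a seeded generator
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(gen_spectrum(m)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("spectrum sets share an axis and scale with the model", {
  m <- spectrum_model(noise_sd = 0, seed = 1)
  set1 <- gen_spectrum_set(m, 1, jitter = 0)
  expect_equal(mean_spectrum(set1)$intensity, gen_spectrum(m)$intensity)

  set148 <- gen_spectrum_set(spectrum_model(noise_sd = 1, seed = 2),
                             148, jitter = 0.05)
  expect_length(set148$spectra, 148)

  # doubling the 960 amplitude doubles the mean peak height (noiseless)
  base <- gen_spectrum_set(single_ha_model(100, 8), 4, jitter = 0)
  dbl <- gen_spectrum_set(single_ha_model(200, 8), 4, jitter = 0)
  expect_equal(peak_intensity(mean_spectrum(dbl), 960),
               2 * peak_intensity(mean_spectrum(base), 960))

  expect_error(gen_spectrum_set(m, 0), "n_spectra")
})

test_that("flexure curves follow beam theory and invert exactly", {
  # hand value: m = 4 E w b^3 / L^3 = 4*800*6*216/40^3 = 64.8 N/mm
  mod <- flexure_model(E_true = 800, span = 40, width = 6, thickness = 6,
                       break_load = 18, noise_sd = 0)
  sp <- gen_flexure_curve(mod)
  slope <- diff(sp$curve$load_N[1:2]) / diff(sp$curve$deflection_mm[1:2])
  expect_equal(slope, 64.8, tolerance = 1e-12)

  # noiseless round-trip recovers E_true to < 0.1 %
  em <- elastic_modulus(sp)
  expect_equal(em$modulus, 800, tolerance = 1e-3)
  expect_equal(em$slope, 64.8, tolerance = 1e-9)

  expect_error(flexure_model(break_load = 0), "break_load")
  expect_error(flexure_model(thickness = -1), "thickness")
})

test_that("mass tables carry the true coating fraction", {
  noiseless <- gen_mass_table(0.145, 5, noise_sd = 0)
  ce <- coating_efficiency(noiseless$weight_before_g,
                           noiseless$weight_after_g)
  expect_equal(ce, rep(14.5, 5))

  zero <- gen_mass_table(0, 3)
  expect_equal(zero$weight_after_g, zero$weight_before_g)

  # Monte-Carlo: mean recovered CE within 0.5 pp of truth at n = 1000
  big <- gen_mass_table(0.145, 1000, noise_sd = 0.02, seed = 42)
  expect_lt(abs(mean(coating_efficiency(big$weight_before_g,
                                        big$weight_after_g)) - 14.5), 0.5)

  expect_error(gen_mass_table(1, 5), "true_ce")
  expect_error(gen_mass_table(-0.1, 5), "true_ce")
})

test_that("degradation series realize the stated kinetics", {
  const <- gen_degradation_series(degradation_model(ph0 = 7, ph_inf = 7,
                                                    rate = 0, noise_sd = 0))
  expect_true(all(const$ph == 7))

  dec <- gen_degradation_series(degradation_model(ph0 = 7, ph_inf = 2,
                                                  rate = 0.1, noise_sd = 0))
  expect_equal(dec$ph[1L], 7)
  expect_true(all(diff(dec$ph) <= 0))

  expect_error(degradation_model(ph0 = 5, ph_inf = 6), "ph_inf")
  expect_error(degradation_model(duration = 0), "duration")
})

test_that("generators retain ground truth on their outputs", {
  m <- spectrum_model(noise_sd = 1, seed = 4)
  expect_identical(gen_spectrum(m)$meta$ground_truth, m)
  fm <- flexure_model(seed = 4)
  expect_identical(gen_flexure_curve(fm)$meta$ground_truth, fm)
  expect_equal(attr(gen_mass_table(0.1, 3, seed = 4),
                    "ground_truth")$true_ce, 0.1)
  dm <- degradation_model(seed = 4)
  expect_identical(attr(gen_degradation_series(dm), "ground_truth"), dm)
})

test_that("invalid spectrum models are rejected with the field named", {
  expect_error(spectrum_model(axis = c(3, 2, 1)), "axis")
  expect_error(band_spec("x", 960, -1, 5), "amplitude")
  expect_error(band_spec("x", 960, 10, 0), "sigma")
  expect_error(spectrum_model(bands = band_spec("x", 100, 10, 5)), "center")
  expect_error(spectrum_model(noise_sd = -1), "noise_sd")
})
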