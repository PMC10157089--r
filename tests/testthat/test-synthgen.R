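# Generators: determinism, analytic truth, and limiting behavior.

test_that("every generator is a pure function of its seed", {
  a <- gen_emission_spectrum(noise_sd = 0.02, seed = 5)
  b <- gen_emission_spectrum(noise_sd = 0.02, seed = 5)
  expect_identical(a$spectrum$intensities, b$spectrum$intensities)

  d1 <- gen_decay_trace(tau = 650, noise_sd = 0.02, seed = 5)
  d2 <- gen_decay_trace(tau = 650, noise_sd = 0.02, seed = 5)
  expect_identical(d1$signal, d2$signal)
  d3 <- gen_decay_trace(tau = 650, noise_sd = 0.02, seed = 6)
  expect_false(identical(d1$signal, d3$signal))

  s1 <- gen_strip_image(noise_sd = 0.02, debris_count = 3, seed = 5)
  s2 <- gen_strip_image(noise_sd = 0.02, debris_count = 3, seed = 5)
  expect_identical(s1$image$pixels, s2$image$pixels)
  expect_identical(s1$truth$debris, s2$truth$debris)

  t1 <- gen_titration_series(noise_sd = 0.05, seed = 5)
  t2 <- gen_titration_series(noise_sd = 0.05, seed = 5)
  expect_identical(t1$series$signals, t2$series$signals)

  # seeded generation does not disturb the caller's RNG stream
  set.seed(123); x1 <- runif(1)
  set.seed(123); invisible(gen_decay_trace(650, noise_sd = 0.01, seed = 99))
  x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("generated spectra carry their analytic band areas", {
  # narrow, well-separated bands: each window integral matches the
  # requested area to 1e-4 relative (0.2 nm grid, no noise)
  areas <- c(F0 = 0.2, F1 = 1.0, F2 = 24.0, F3 = 0.5, F4 = 1.76)
  g <- gen_emission_spectrum(areas = areas, widths = 1)
  centers <- c(F0 = 579, F1 = 593, F2 = 614, F3 = 654, F4 = 701)
  for (tr in names(areas)) {
    got <- integrate_band(g$spectrum,
                          band_window(tr, centers[[tr]] - 4, centers[[tr]] + 4))
    expect_equal(got, areas[[tr]], tolerance = 1e-4)
  }

  # default widths: the pipeline ratio matches the truth within 1e-3
  gd <- gen_emission_spectrum(areas = areas)
  expect_equal(band_areas(gd$spectrum)$ratio_tot_md, g$truth$ratio_tot_md,
               tolerance = 1e-3)
  expect_equal(g$truth$ratio_tot_md, 27.46)

  # MD-only emission
  g1 <- gen_emission_spectrum(areas = c(F1 = 2))
  expect_equal(band_areas(g1$spectrum)$ratio_tot_md, 1, tolerance = 1e-3)

  expect_error(gen_emission_spectrum(grid = c(580, 700, 0.2)),
               "4 sigma")
  expect_error(gen_emission_spectrum(areas = c(F0 = 1)), "F1")
})

test_that("decay generator matches its closed form", {
  tr <- gen_decay_trace(tau = 500, amplitude = 1000, baseline = 20,
                        window = c(0, 2000), step = 100)
  i <- which(tr$times == 500)
  expect_equal(tr$signal[i], 1000 / exp(1) + 20, tolerance = 1e-12)
  expect_equal(attr(tr, "truth")$tau, 500)
})

test_that("dilution series shows inner-filter compression then linearity", {
  d <- gen_dilution_series(2.0)
  ratios <- attr(d, "step_ratios")
  # closed-form oracle: (1 - 10^-A1)/(1 - 10^-A2) for A = 2, 0.2, 0.02
  oracle <- c((1 - 10^-2) / (1 - 10^-0.2),
              (1 - 10^-0.2) / (1 - 10^-0.02))
  expect_equal(ratios, oracle, tolerance = 1e-12)
  expect_equal(ratios, c(2.68, 8.20), tolerance = 1e-2)
  # first step strongly compressed, second nearly proportional
  expect_lt(ratios[1], ratios[2])
  expect_lt(ratios[2], 10)

  # dilute limit: step ratio tends to the dilution factor 10
  d0 <- gen_dilution_series(1e-6)
  expect_equal(attr(d0, "step_ratios"), c(10, 10), tolerance = 1e-3)

  # zero emission scale
  dz <- gen_dilution_series(2, emission_scale = 0)
  expect_true(all(dz$intensity == 0))

  expect_error(gen_dilution_series(2, concentrations = c(0.01, 0.1)),
               "decreasing")
})

test_that("strip generator produces uniform, lined, and flagged images", {
  u <- gen_strip_image(line_positions_mm = numeric(0),
                       line_heights = numeric(0), noise_sd = 0)
  expect_equal(unique(as.vector(u$image$pixels)), 0.1)

  g <- gen_strip_image(line_positions_mm = 20, line_heights = 0.3,
                       noise_sd = 0)
  pk <- detect_lines(lightness_profile(g$image))
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$position, 20, tolerance = 1e-2)
  expect_equal(pk$height, 0.3, tolerance = 0.05)

  expect_warning(
    o <- gen_strip_image(line_positions_mm = c(20, 20.8),
                         line_heights = c(0.3, 0.2)),
    "3 sigma")
  expect_true(o$truth$lines_overlap)
  expect_error(gen_strip_image(line_positions_mm = 45, line_heights = 0.3),
               "inside the strip")
})

test_that("titration generator encodes the 4-site blocking model", {
  g <- gen_titration_series(sites_per_bead = 1000, sites_per_protein = 4,
                            signal0 = 0.5, plateau = 0.02, noise_sd = 0)
  expect_equal(g$truth$endpoint_dose, 4000)
  expect_equal(g$series$signals[g$series$doses == 0], 0.52)
  post <- g$series$signals[g$series$doses >= 4000]
  expect_true(all(post == 0.02))
})
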