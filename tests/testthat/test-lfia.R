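# Strip densitometry and the biotin-blocking titration endpoint.

test_that("lightness_profile averages across the strip width", {
  flat <- strip_image(matrix(0.4, 20, 100), pixel_size = 0.1)
  p <- lightness_profile(flat)
  expect_equal(unique(p$lightness), 0.4)
  expect_length(p$positions, 100)
  expect_equal(diff(p$positions)[1], 0.1)

  # synthetic line at 20 mm: profile argmax within one pixel
  g <- gen_strip_image(line_positions_mm = 20, line_heights = 0.3)
  p2 <- lightness_profile(g$image)
  expect_lt(abs(p2$positions[which.max(p2$lightness)] - 20),
            1.5 * g$image$pixel_size)

  # transposing the pixels and swapping flow_axis gives the same profile
  tr <- strip_image(t(g$image$pixels), g$image$pixel_size, flow_axis = "row")
  expect_equal(lightness_profile(tr), p2)

  # noiseless strips have identical rows, so widening the strip with its
  # own background rows leaves the width-averaged profile unchanged
  wide <- strip_image(rbind(g$image$pixels,
                            g$image$pixels[rep(1L, 40), ]),
                      g$image$pixel_size)
  expect_equal(lightness_profile(wide), p2)

  expect_error(strip_image(matrix(1.2, 3, 3), 0.1), "\\[0, 1\\]")
})

test_that("detect_lines finds test and control lines and honors min_snr", {
  # flat noiseless profile: nothing to report
  flat <- strip_profile(seq(0.05, 40, by = 0.05),
                        rep(0.2, length(seq(0.05, 40, by = 0.05))))
  expect_equal(nrow(detect_lines(flat)), 0L)

  g <- gen_strip_image(line_positions_mm = c(20, 30),
                       line_heights = c(0.3, 0.2),
                       noise_sd = 0.01, seed = 42)
  pk <- detect_lines(lightness_profile(g$image))
  expect_equal(nrow(pk), 2L)
  expect_equal(pk$position, c(20, 30), tolerance = 0.01)
  expect_equal(pk$height, c(0.3, 0.2), tolerance = 0.05)
  expect_true(all(pk$snr >= 3))

  # an implausibly high SNR demand excludes everything
  expect_equal(nrow(detect_lines(lightness_profile(g$image),
                                 min_snr = 1e6)), 0L)

  # heights are invariant to a constant offset on the whole image
  shifted <- strip_image(g$image$pixels * 0 + pmin(g$image$pixels + 0.15, 1),
                         g$image$pixel_size)
  pk2 <- detect_lines(lightness_profile(shifted))
  expect_equal(pk2$height, pk$height, tolerance = 1e-6)
})

test_that("detection copes with debris and reduced line contrast", {
  g <- gen_strip_image(line_positions_mm = c(20, 30),
                       line_heights = c(0.3, 0.2),
                       debris_count = 8, debris_height = 0.15,
                       noise_sd = 0.02, seed = 7)
  pk <- detect_lines(lightness_profile(g$image))
  # the two true lines are present among the detections, within 5%
  near_test <- pk[which.min(abs(pk$position - 20)), ]
  near_ctrl <- pk[which.min(abs(pk$position - 30)), ]
  expect_lt(abs(near_test$position - 20), 0.5)
  expect_lt(abs(near_ctrl$position - 30), 0.5)
  expect_equal(near_test$height, 0.3, tolerance = 0.05)
  expect_equal(near_ctrl$height, 0.2, tolerance = 0.05)
})

test_that("titration_endpoint finds the onset of signal permanence", {
  # noiseless decline to a plateau starting at 4000: exact changepoint
  g <- gen_titration_series(sites_per_bead = 1000, sites_per_protein = 4,
                            noise_sd = 0)
  expect_equal(titration_endpoint(g$series), 4000)
  expect_equal(g$truth$endpoint_dose, 4000)

  # seeded noisy series: endpoint within one dose-grid step
  gn <- gen_titration_series(sites_per_bead = 1000, noise_sd = 0.03,
                             seed = 12)
  expect_lte(abs(titration_endpoint(gn$series) - 4000), 500)

  # strictly declining series: no plateau to report
  doses <- seq(0, 8000, by = 1000)
  dec <- titration_series(doses, 1 - doses / 10000, noise_floor = 0)
  expect_error(titration_endpoint(dec), "no signal permanence")

  # flat series: nothing ever declined
  flat <- titration_series(doses, rep(0.4, length(doses)),
                           noise_floor = 0.01)
  expect_error(titration_endpoint(flat), "no signal permanence")

  expect_error(titration_series(c(0, 100), c(1, 0.5), -1), "non-negative")
})

test_that("titration_to_proteins divides the endpoint by the site count", {
  g <- gen_titration_series(sites_per_bead = 1000, noise_sd = 0)
  expect_equal(titration_to_proteins(g$series), 1000)
  expect_equal(titration_to_proteins(g$series, sites_per_protein = 2), 2000)
})

test_that("relative conjugate activity is recovered from paired titrations", {
  # covalent vs adsorptive coupling: the adsorptive series is the same
  # blocking curve scaled down; the ratio of fitted unblocked signals
  # recovers the scale factor
  f <- 0.4
  cov <- gen_titration_series(signal0 = 0.5, plateau = 0.02,
                              noise_sd = 0.03, seed = 31)
  ads <- gen_titration_series(signal0 = 0.5 * f, plateau = 0.02 * f,
                              noise_sd = 0.03 * f, seed = 32)
  s0 <- function(g) {
    ep <- titration_endpoint(g$series)
    sel <- g$series$doses <= ep
    unname(coef(lm(g$series$signals[sel] ~ g$series$doses[sel]))[1])
  }
  expect_equal(s0(ads) / s0(cov), f, tolerance = 0.1)
})
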