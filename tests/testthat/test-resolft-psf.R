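test_that("both RESOLFT schemes collapse to the confocal PSF without 405 nm light", {
  m <- test_model()
  cfg <- test_optics()
  g <- coarse_grid()
  conf <- effective_psf_confocal(m, cfg, 0.6, g)
  one <- effective_psf_onestep(m, cfg, p488 = 0.6, p405 = 0, g)
  expect_equal(one$fwhm, conf$fwhm, tolerance = 1e-6)
  # without the off doughnut the sequential scheme stays diffraction-limited:
  # no sharper than the unsaturated activation x readout x detection product
  seq0 <- effective_psf_sequential(
    m, cfg, sequential_scheme(off_uW = 1e-12), g)
  expect_gt(seq0$fwhm, 150)
  expect_lte(seq0$fwhm, conf$fwhm)
  expect_gt(conf$fwhm, 150)
})

test_that("effective PSFs peak at the origin, are normalized and sub-diffraction", {
  m <- test_model()
  cfg <- test_optics()
  g <- coarse_grid()
  ctr <- (length(g$x) + 1) / 2
  one <- effective_psf_onestep(m, cfg, 0.6, 1.19, g)
  sq <- effective_psf_sequential(m, cfg, grid = g)
  conf <- effective_psf_confocal(m, cfg, 0.6, g)
  for (psf in list(one, sq)) {
    expect_equal(max(psf$values), 1)
    expect_equal(psf$values[ctr, ctr], 1)
    expect_true(all(psf$values >= 0))
    expect_lt(psf$fwhm, conf$fwhm / 2)
  }
})

test_that("one-step FWHM decreases monotonically with 405 nm power", {
  m <- test_model()
  cfg <- test_optics()
  g <- coarse_grid()
  powers <- c(0, 0.3, 1.19, 5)
  fw <- vapply(powers, function(p) {
    effective_psf_onestep(m, cfg, 0.6, p, g)$fwhm
  }, 0)
  expect_true(all(diff(fw) < 0))
})

test_that("sequential FWHM is non-increasing in off-switching power", {
  m <- test_model()
  cfg <- test_optics()
  g <- coarse_grid()
  fw <- vapply(c(0.2, 1.16, 4), function(p) {
    effective_psf_sequential(m, cfg, sequential_scheme(off_uW = p), g)$fwhm
  }, 0)
  expect_true(all(diff(fw) <= 0))
})

test_that("at the doughnut crest the one-step on-fraction is strongly suppressed", {
  m <- test_model()
  cfg <- test_optics()
  g <- coarse_grid()
  d405 <- focal_intensity_map(cfg, 405, "doughnut", 1.19, g)
  e488 <- focal_intensity_map(cfg, 488, "gaussian", 0.6, g)
  crest <- which(d405$values == max(d405$values), arr.ind = TRUE)[1, ]
  r <- switching_rates(m, list(
    illumination(405, d405$values[crest[1], crest[2]]),
    illumination(488, e488$values[crest[1], crest[2]])))
  p <- steady_state_on_fraction(r)
  ratio <- r$k_off / r$k_on
  if (ratio >= 19) expect_lte(p, 0.05)
  expect_equal(p, 1 / (1 + ratio), tolerance = 1e-12)
})

test_that("scheme validation rejects missing steps", {
  m <- test_model()
  cfg <- test_optics()
  bad <- pulse_scheme(list(list(role = "activation", duration = 70,
                                beams = list(list(beam_kind = "gaussian",
                                                  wavelength = 488,
                                                  power = 7.6)))))
  expect_error(effective_psf_sequential(m, cfg, bad, coarse_grid()),
               "missing")
  expect_error(pulse_scheme(list(list(role = "nonsense", duration = 1,
                                      beams = list()))), "role")
  expect_error(effective_psf_onestep(m, cfg, 0, 0, coarse_grid()),
               "power")
})

test_that("frozen-mode scan is the phantom-PSF convolution and conserves signal", {
  m <- test_model()
  cfg <- test_optics()
  g <- focal_grid(25, 400)
  ph <- two_line_phantom(140, g)
  psf <- effective_psf_onestep(m, cfg, 0.6, 1.19, g)
  res <- simulate_scan(ph, "onestep", m, cfg,
                       scan_config(pixel_size = 25, dwell_time = 300),
                       psf = psf)
  dwell_s <- 300e-6
  raw <- psf$values * psf$peak_brightness
  manual <- resolftsim:::conv2_same(ph$density, raw) * g$spacing^2 * dwell_s
  expect_equal(res$image, manual, tolerance = 1e-12)
  expect_equal(sum(res$image), sum(manual))
  # empty phantom gives a blank image
  empty <- phantom(g, matrix(0, length(g$x), length(g$y)))
  res0 <- simulate_scan(empty, "onestep", m, cfg,
                        scan_config(25, 300), psf = psf)
  expect_true(all(res0$image == 0))
})

test_that("kinetic scanning converges to the frozen convolution at long dwell", {
  m <- test_model()
  cfg <- test_optics()
  g <- focal_grid(25, 350)
  ph <- two_line_phantom(140, g, density_peak = 0.01)
  frozen <- simulate_scan(ph, "onestep", m, cfg,
                          scan_config(pixel_size = 50, dwell_time = 300,
                                      mode = "frozen"))
  kinetic <- simulate_scan(ph, "onestep", m, cfg,
                           scan_config(pixel_size = 50, dwell_time = 2e5,
                                       mode = "kinetic"))
  nf <- frozen$image / max(frozen$image)
  nk <- kinetic$image / max(kinetic$image)
  expect_lt(max(abs(nf - nk)), 0.01)
})

test_that("Poisson sampling is seeded and reproducible", {
  m <- test_model()
  cfg <- test_optics()
  g <- focal_grid(25, 300)
  ph <- two_line_phantom(140, g, density_peak = 0.05)
  sc <- scan_config(25, 300, photon_noise = TRUE, rng_seed = 99)
  r1 <- simulate_scan(ph, "confocal", m, cfg, sc)
  r2 <- simulate_scan(ph, "confocal", m, cfg, sc)
  expect_identical(r1$image, r2$image)
  expect_true(all(r1$image == floor(r1$image)))
})

test_that("Lorentzian profile fitting recovers the generating width", {
  x <- seq(-400, 400, by = 10)
  y <- 5 * 30^2 / ((x - 12)^2 + 30^2) + 0.3
  fit <- lorentzian_profile_fit(x, y)
  expect_equal(fit$fwhm, 60, tolerance = 1e-6)
  expect_equal(fit$center, 12, tolerance = 1e-6)
  # noisy Monte-Carlo: mean recovered FWHM within 5% of truth
  set.seed(3)
  est <- replicate(100, {
    lorentzian_profile_fit(x, y + rnorm(length(x), 0, 0.05 * max(y)))$fwhm
  })
  expect_lt(abs(mean(est) - 60) / 60, 0.05)
  expect_error(lorentzian_profile_fit(x, rep(1, length(x))), "constant")
  expect_error(lorentzian_profile_fit(1:4, 1:4), "at least 5")
})
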