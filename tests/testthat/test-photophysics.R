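test_that("cross section and photon flux follow the conversion constants", {
  # sigma = 1000 ln10 / N_A * eps
  expect_equal(cross_section(48700), 3.8235e-21 * 48700, tolerance = 1e-4)
  expect_equal(cross_section(0), 0)
  # Phi = I lambda / (h c)
  expect_equal(photon_flux(1, 405), 2.04e21, tolerance = 1e-3)
  expect_equal(photon_flux(0, 488), 0)
  expect_error(photon_flux(-1, 488), "non-negative")
})

test_that("switching rates are linear in intensity and zero without light", {
  m <- test_model()
  r0 <- switching_rates(m, list())
  expect_equal(r0$k_on + r0$k_off + r0$k_emit + r0$k_bleach, 0)
  r0 <- switching_rates(m, list(illumination(405, 0), illumination(488, 0)))
  expect_equal(r0$k_off, 0)
  f1 <- list(illumination(405, 1.3), illumination(488, 2.6))
  f2 <- list(illumination(405, 2.6), illumination(488, 5.2))
  r1 <- switching_rates(m, f1)
  r2 <- switching_rates(m, f2)
  expect_identical(r2$k_on, 2 * r1$k_on)
  expect_identical(r2$k_off, 2 * r1$k_off)
  expect_identical(r2$k_emit, 2 * r1$k_emit)
  expect_error(switching_rates(m, list(list(wavelength = 488, intensity = -1))),
               ">= 0")
})

test_that("role flags route absorption into the correct rates", {
  m <- test_model()
  # 405 nm: off-switching through the neutral on-state, weak cross-activation
  # through the off-state tail, no emission below the emission cutoff
  r405 <- switching_rates(m, list(illumination(405, 1)))
  expect_gt(r405$k_off, 0)
  expect_gt(r405$k_on, 0)
  expect_lt(r405$k_on, r405$k_off / 100)
  expect_equal(r405$k_emit, 0)
  # 488 nm drives on-switching and emission; off-switching only through the
  # weak neutral-band tail (positive-switching phenotype)
  r488 <- switching_rates(m, list(illumination(488, 1)))
  expect_gt(r488$k_on, 0)
  expect_lt(r488$k_off, r488$k_on / 10)
  expect_gt(r488$k_emit, 0)
  # the optional anionic-driven channel adds to 488 nm off-switching
  rx <- switching_rates(m, list(illumination(488, 1)),
                        cross_activation_488_off = TRUE)
  expect_gt(rx$k_off, r488$k_off)
})

test_that("steady state is k_on/(k_on+k_off) and matches long-time evolution", {
  expect_equal(steady_state_on_fraction(rate_set(k_on = 5, k_off = 5)), 0.5)
  expect_equal(steady_state_on_fraction(rate_set(k_on = 2, k_off = 0)), 1)
  expect_equal(steady_state_on_fraction(rate_set(k_on = 1, k_off = 3)), 0.25)
  expect_error(steady_state_on_fraction(rate_set(0, 0)), "undefined")
  set.seed(42)
  for (i in 1:20) {
    r <- rate_set(k_on = runif(1, 0.1, 1e4), k_off = runif(1, 0.1, 1e4))
    t50 <- 50 / (r$k_on + r$k_off)
    expect_equal(evolve_on_fraction(runif(1), r, t50),
                 steady_state_on_fraction(r), tolerance = 1e-6)
  }
})

test_that("population relaxation matches the closed form and the ODE oracle", {
  r <- rate_set(k_on = 500, k_off = 500)
  expect_equal(evolve_on_fraction(0.3, r, 0), 0.3)
  # p0 = 0, k_on = k_off = 500/s, t = 1 ms: 0.5 (1 - exp(-1))
  expect_equal(evolve_on_fraction(0, r, 1e-3), 0.5 * (1 - exp(-1)),
               tolerance = 1e-12)
  expect_equal(evolve_on_fraction(0, r, 1e-3),
               ode_on_fraction(0, 500, 500, 1e-3), tolerance = 1e-7)
  set.seed(7)
  for (i in 1:25) {
    kon <- runif(1, 0, 1e4); koff <- runif(1, 0, 1e4)
    p0 <- runif(1); tt <- runif(1, 0, 0.1)
    p <- evolve_on_fraction(p0, rate_set(k_on = kon, k_off = koff), tt)
    expect_gte(p, 0); expect_lte(p, 1)
  }
  expect_error(evolve_on_fraction(0.5, r, -1), ">= 0")
})

test_that("emitted signal is p_on * k_emit", {
  r <- rate_set(k_emit = 1e4)
  expect_equal(emitted_signal_rate(0, r), 0)
  expect_equal(emitted_signal_rate(1, r), 1e4)
  expect_equal(emitted_signal_rate(0.5, rate_set(k_emit = 2e4)),
               2 * emitted_signal_rate(0.5, r))
  expect_error(emitted_signal_rate(1.5, r), "\\[0, 1\\]")
})

test_that("table-derived rates keep the periphery mostly off when k_off/k_on >= 19", {
  m <- test_model()
  co405 <- rate_coefficients(m, 405)
  co488 <- rate_coefficients(m, 488)
  set.seed(11)
  for (i in 1:10) {
    i405 <- runif(1, 0.5, 50)
    # choose a 488 intensity that keeps the rate ratio at or above 19
    i488_max <- co405$k_off * i405 / (19 * co488$k_on) * 0.999
    i488 <- runif(1, 0.01 * i488_max, i488_max)
    r <- switching_rates(m, list(illumination(405, i405),
                                 illumination(488, i488)))
    expect_gte(r$k_off / r$k_on, 19 * 0.99)
    expect_gte(1 - steady_state_on_fraction(r), 0.95 * 0.999)
  }
})

test_that("model constructor enforces the type invariants", {
  sp <- gen_state_spectra(list(on_neutral = c(384, 23500, 30),
                               on_anionic = c(495, 13250, 30),
                               off = c(498, 48700, 30)))
  expect_error(rsfp_model(sp, qy_off = 1.5, qy_on = 0.005, qy_fl = 0.49),
               "\\[0, 1\\]")
  expect_error(rsfp_model(sp, 0.1, 0.005, 0.49, f_anionic = 2), "f_anionic")
  sp_bad <- sp
  sp_bad$on_anionic$emits_fluorescence <- FALSE
  expect_error(rsfp_model(sp_bad, 0.1, 0.005, 0.49), "emit")
})

test_that("protein parameter files round-trip through YAML", {
  m <- test_model()
  f <- withr::local_tempfile(fileext = ".yml")
  write_protein_model(m, f)
  m2 <- read_protein_model(f)
  expect_equal(m2$qy_off, m$qy_off)
  expect_equal(m2$f_anionic, m$f_anionic)
  expect_equal(species_extinction(m2$species$off, 488),
               species_extinction(m$species$off, 488), tolerance = 1e-6)
})
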