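test_that("relative quantum yield follows the ratio formula", {
  wl <- 470:650
  em <- data.frame(wavelength = wl, value = exp(-(wl - 516)^2 / 900))
  # identical spectra and absorbances: sample QY equals the reference QY
  expect_equal(relative_quantum_yield(em, 0.05, em, 0.05, 0.64), 0.64)
  # twice the emission at the same absorbance doubles the estimate
  em2 <- transform(em, value = 2 * value)
  expect_equal(relative_quantum_yield(em2, 0.05, em, 0.05, 0.3), 0.6)
  # halving the sample absorbance also doubles it
  expect_equal(relative_quantum_yield(em, 0.025, em, 0.05, 0.3), 0.6)
  # scale invariance of the emission units
  expect_equal(relative_quantum_yield(transform(em, value = 1e6 * value),
                                      0.05,
                                      transform(em, value = 1e6 * value),
                                      0.08, 0.64),
               relative_quantum_yield(em, 0.05, em, 0.08, 0.64))
  expect_error(relative_quantum_yield(em, 0, em, 0.05, 0.64), "> 0")
  expect_error(relative_quantum_yield(em[c(2, 1, 3:10), ], 0.1, em, 0.1, 0.5),
               "increasing")
})

test_that("pH fits recover monophasic and biphasic generating parameters", {
  curve <- gen_titration_curve("monophasic", pka = 5.9,
                               spec = generator_spec(noise_model = "none"))
  fit <- fit_ph_response(curve, "monophasic")
  expect_equal(unname(fit$parameters["pKa"]), 5.9, tolerance = 1e-6)
  bi <- gen_titration_curve("biphasic", pka = c(6.6, 9.1),
                            spec = generator_spec(noise_model = "none"))
  bfit <- fit_ph_response(bi, "biphasic")
  expect_equal(unname(bfit$parameters["pKa1"]), 6.6, tolerance = 1e-6)
  expect_equal(unname(bfit$parameters["pKa2"]), 9.1, tolerance = 1e-6)
  expect_lt(bfit$parameters["pKa1"], bfit$parameters["pKa2"])
})

test_that("pH fits are robust to noise and flag constant curves", {
  set.seed(21)
  err <- replicate(25, {
    spec <- generator_spec(rng_seed = sample.int(1e6, 1),
                           noise_model = "gaussian", noise_sd = 0.02)
    curve <- gen_titration_curve("monophasic", pka = 6.6, spec = spec)
    unname(fit_ph_response(curve, "monophasic")$parameters["pKa"]) - 6.6
  })
  expect_lt(abs(mean(err)), 0.05)
  expect_lt(max(abs(err)), 0.3)
  flat <- data.frame(pH = seq(3, 10, 0.5), intensity = 1)
  ffit <- fit_ph_response(flat, "monophasic")
  expect_false(ffit$identifiable)
  expect_true(is.na(ffit$parameters["pKa"]))
  expect_error(fit_ph_response(data.frame(pH = 1:4, intensity = 1:4)),
               "at least")
})

test_that("alkaline denaturation anchors extinction to 44,000 at 447 nm", {
  wl <- seq(300, 650, by = 1)
  native <- data.frame(wavelength = wl,
                       absorbance = 0.487 * exp(-(wl - 498)^2 / (2 * 30^2)))
  denatured <- data.frame(wavelength = wl,
                          absorbance = 0.44 * exp(-(wl - 447)^2 / (2 * 35^2)))
  eps <- extinction_from_denaturation(native, denatured, state_peak = 498)
  expect_equal(eps, 44000 * 0.487 / 0.44, tolerance = 1e-9)
  # dilution-invariant: scaling both spectra equally changes nothing
  eps2 <- extinction_from_denaturation(
    transform(native, absorbance = absorbance / 3),
    transform(denatured, absorbance = absorbance / 3), 498)
  expect_equal(eps2, eps)
  expect_error(extinction_from_denaturation(native,
                                            transform(denatured,
                                                      absorbance = 0 * absorbance),
                                            498), "denatured")
})

test_that("photokinetic factor has the right limits and is monotone", {
  expect_equal(photokinetic_factor(0), 1)
  expect_equal(photokinetic_factor(1), (1 - 0.1) / log(10), tolerance = 1e-12)
  expect_equal(photokinetic_factor(2), (1 - 0.01) / (2 * log(10)),
               tolerance = 1e-12)
  a <- seq(0, 3, by = 0.01)
  f <- photokinetic_factor(a)
  expect_true(all(diff(f) < 0))
  expect_true(all(f > 0 & f <= 1))
  # optically thin limit: first-order expansion 1 - A ln(10)/2
  expect_equal(photokinetic_factor(1e-4), 1 - 1e-4 * log(10) / 2,
               tolerance = 1e-7)
  expect_error(photokinetic_factor(-0.1), ">= 0")
})

test_that("the cuvette forward model conserves populations and hits the thin limit", {
  m <- test_model()
  irr <- irradiation_record(405, 6.02)
  ser <- forward_cuvette_switching(m, irr, c(1, 2, 3, 4, 5, 10, 20, 30, 60))
  expect_equal(ser$times[1], 0)
  expect_equal(ser$p_on[1], 1)
  expect_true(all(ser$p_on >= 0 & ser$p_on <= 1))
  expect_true(all(diff(ser$p_on) < 0)) # off-switching drives p_on down
  # optically thin sample: kinetics match the closed-form two-state solution
  thin <- irradiation_record(405, 6.02, concentration = 0.01)
  tt <- c(0.5, 1, 2, 5, 10, 20, 30, 60)
  sthin <- forward_cuvette_switching(m, thin, tt,
                                     use_photokinetic_factor = FALSE)
  co <- rate_coefficients(m, 405)
  r <- rate_set(k_on = co$k_on * 6.02e-6, k_off = co$k_off * 6.02e-6)
  expect_equal(sthin$p_on[-1],
               vapply(tt, function(t) evolve_on_fraction(1, r, t), 0),
               tolerance = 1e-6)
  # photokinetic correction slows the observed switching at finite A
  sfull <- forward_cuvette_switching(m, irr, tt)
  snof <- forward_cuvette_switching(m, irr, tt,
                                    use_photokinetic_factor = FALSE)
  expect_true(all(sfull$p_on[-1] > snof$p_on[-1]))
})

test_that("unmixing inverts the forward spectra exactly", {
  m <- test_model()
  ser <- forward_cuvette_switching(m, irradiation_record(405, 6.02),
                                   c(1, 2, 5, 10, 30, 60))
  p_hat <- unmix_populations(ser, m)
  expect_equal(p_hat, ser$p_on, tolerance = 1e-8)
})

test_that("switching quantum yields are recovered across their range", {
  m <- test_model()
  with_qy <- function(base, qy_off = base$qy_off, qy_on = base$qy_on) {
    rsfp_model(base$species, qy_off, qy_on, base$qy_fl,
               qy_bleach = base$qy_bleach, f_anionic = base$f_anionic,
               name = base$name)
  }
  for (qy in c(0.005, 0.05, 0.115)) {
    m_true <- with_qy(m, qy_off = qy)
    ser <- forward_cuvette_switching(m_true, irradiation_record(405, 6.02),
                                     c(1, 2, 3, 4, 5, 10, 20, 30, 60))
    fit <- fit_switching_quantum_yield(ser, m, which = "qy_off")
    expect_equal(unname(fit$parameters["qy_off"]), qy, tolerance = 1e-3)
  }
  m_true <- with_qy(m, qy_on = 0.001)
  ser <- forward_cuvette_switching(m_true, irradiation_record(500, 12.61),
                                   c(5, 10, 20, 30, 60, 120, 180), p0 = 0)
  fit <- fit_switching_quantum_yield(ser, m, which = "qy_on")
  expect_equal(unname(fit$parameters["qy_on"]), 0.001, tolerance = 1e-5)
  expect_error(fit_switching_quantum_yield(
    forward_cuvette_switching(m, irradiation_record(405, 6.02), c(1, 2)),
    m), "at least 5")
})

test_that("ExpDec2 recovers biexponential parameters with the t1 <= t2 convention", {
  x <- seq(0, 50, by = 0.5)
  y <- 0.2 + 1.5 * exp(-x / 2) + 0.8 * exp(-x / 15)
  fit <- expdec2_fit(x, y)
  p <- fit$parameters
  expect_equal(unname(p["y0"]), 0.2, tolerance = 1e-6)
  expect_equal(unname(p["t1"]), 2, tolerance = 1e-5)
  expect_equal(unname(p["t2"]), 15, tolerance = 1e-5)
  expect_equal(unname(p["A1"]), 1.5, tolerance = 1e-5)
  expect_lte(p["t1"], p["t2"])
  # order of the input points must not matter
  sh <- sample(seq_along(x))
  fit2 <- expdec2_fit(x[sh], y[sh])
  expect_equal(fit2$parameters, fit$parameters, tolerance = 1e-6)
  # a single exponential is fitted consistently (both time constants usable)
  y1 <- 3 * exp(-x / 5)
  f1 <- expdec2_fit(x, y1)
  pred <- f1$parameters["y0"] +
    f1$parameters["A1"] * exp(-x / f1$parameters["t1"]) +
    f1$parameters["A2"] * exp(-x / f1$parameters["t2"])
  expect_lt(max(abs(pred - y1)), 1e-6)
  expect_error(expdec2_fit(1:5, 1:5), "at least 6")
})
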