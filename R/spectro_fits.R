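#' Fit-result container
#'
#' @param parameters Named numeric vector of estimates.
#' @param residual_norm Residual sum of squares of the fit.
#' @param converged Logical convergence flag.
#' @param covariance Optional covariance matrix of the estimates.
#' @param identifiable Logical; `FALSE` when the data carry no information
#'   on the parameters (e.g. a constant titration curve).
#' @return An object of class `fit_result`.
#' @export
fit_result <- function(parameters, residual_norm, converged = TRUE,
                       covariance = NULL, identifiable = TRUE) {
  structure(list(parameters = parameters, residual_norm = residual_norm,
                 converged = converged, covariance = covariance,
                 identifiable = identifiable),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result>", if (!x$identifiable) "(unidentifiable)" else "", "\n")
  print(x$parameters)
  cat(sprintf("  residual norm %.4g, converged: %s\n",
              x$residual_norm, x$converged))
  invisible(x)
}

check_spectrum <- function(s, what = "spectrum") {
  stopifnot(is.data.frame(s), ncol(s) >= 2)
  wl <- s[[1]]
  if (any(diff(wl) <= 0)) stop(what, ": wavelengths must be strictly increasing")
  s
}

#' Relative fluorescence quantum yield
#'
#' Quantum yield of a sample relative to a reference of known quantum
#' yield, from integrated emission spectra and absorbances at the common
#' excitation wavelength:
#' `QY_s = QY_ref * (int F_s / A_s) / (int F_r / A_r)`
#' (trapezoidal integration). The ratio is scale-invariant in the emission
#' units.
#'
#' @param sample_emission,reference_emission Two-column data frames
#'   (`wavelength`, `value`) of emission spectra.
#' @param sample_absorbance,reference_absorbance Absorbances at the
#'   excitation wavelength, `> 0`.
#' @param reference_qy Known quantum yield of the reference.
#' @return Estimated quantum yield (unitless).
#' @examples
#' em <- data.frame(wavelength = 500:600,
#'                  value = exp(-((500:600) - 516)^2 / 800))
#' relative_quantum_yield(em, 0.05, em, 0.10, reference_qy = 0.64) # 1.28
#' @export
relative_quantum_yield <- function(sample_emission, sample_absorbance,
                                   reference_emission, reference_absorbance,
                                   reference_qy) {
  if (sample_absorbance <= 0 || reference_absorbance <= 0) {
    stop("absorbances at the excitation wavelength must be > 0")
  }
  s <- check_spectrum(sample_emission, "sample emission")
  r <- check_spectrum(reference_emission, "reference emission")
  int_s <- pracma::trapz(s[[1]], s[[2]])
  int_r <- pracma::trapz(r[[1]], r[[2]])
  reference_qy * (int_s / sample_absorbance) / (int_r / reference_absorbance)
}

ph_response <- function(pH, mode, pars) {
  if (mode == "monophasic") {
    pars[["A0"]] + pars[["A1"]] / (1 + 10^(pars[["pKa"]] - pH))
  } else {
    pars[["A0"]] + pars[["A1"]] / (1 + 10^(pars[["pKa1"]] - pH)) +
      pars[["A2"]] / (1 + 10^(pars[["pKa2"]] - pH))
  }
}

#' Fit a pH dose-response (pKa) curve
#'
#' Fits the fluorescence-versus-pH titration of a protein to a mono- or
#' biphasic dose-response function with unit Hill slope:
#' monophasic `F(pH) = A0 + A1 / (1 + 10^(pKa - pH))`; biphasic adds a
#' second transition `+ A2 / (1 + 10^(pKa2 - pH))` with `pKa1 < pKa2`
#' enforced by sorting. Amplitudes are unconstrained in sign. The fit is
#' restarted from a grid of transition-point guesses and the best
#' least-squares solution is returned.
#'
#' @param curve Data frame with columns `pH` and `intensity`.
#' @param mode `"monophasic"` or `"biphasic"`.
#' @return A [fit_result()] with `pKa` (and amplitudes); for a constant
#'   curve the amplitudes are 0 and the result is flagged unidentifiable.
#' @export
fit_ph_response <- function(curve, mode = c("monophasic", "biphasic")) {
  mode <- match.arg(mode)
  stopifnot(all(c("pH", "intensity") %in% names(curve)))
  pH <- curve$pH
  y <- curve$intensity
  need <- if (mode == "monophasic") 6L else 8L
  if (length(pH) < need) stop("need at least ", need, " titration points")
  if (diff(range(y)) < 1e-12 * max(abs(y), 1)) {
    pars <- if (mode == "monophasic") {
      c(A0 = mean(y), A1 = 0, pKa = NA_real_)
    } else {
      c(A0 = mean(y), A1 = 0, A2 = 0, pKa1 = NA_real_, pKa2 = NA_real_)
    }
    return(fit_result(pars, 0, converged = TRUE, identifiable = FALSE))
  }
  rng <- range(pH)
  grid <- seq(rng[1] + 0.5, rng[2] - 0.5, length.out = 6)
  amp <- diff(range(y))
  best <- NULL
  starts <- if (mode == "monophasic") {
    lapply(grid, function(p) list(A0 = min(y), A1 = amp, pKa = p))
  } else {
    pairs <- utils::combn(grid, 2, simplify = FALSE)
    lapply(pairs, function(p) list(A0 = min(y), A1 = amp / 2, A2 = amp / 2,
                                   pKa1 = p[1], pKa2 = p[2]))
  }
  fml <- if (mode == "monophasic") {
    y ~ A0 + A1 / (1 + 10^(pKa - pH))
  } else {
    y ~ A0 + A1 / (1 + 10^(pKa1 - pH)) + A2 / (1 + 10^(pKa2 - pH))
  }
  dat <- data.frame(pH = pH, y = y)
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(fml, data = dat, start = st,
                        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) stop("pH response fit failed to converge from all starts")
  cf <- stats::coef(best$fit)
  if (mode == "biphasic" && cf["pKa1"] > cf["pKa2"]) {
    cf[c("pKa1", "pKa2")] <- cf[c("pKa2", "pKa1")]
    cf[c("A1", "A2")] <- cf[c("A2", "A1")]
  }
  cov <- tryCatch(stats::vcov(best$fit), error = function(e) NULL)
  fit_result(cf, best$rss, converged = TRUE, covariance = cov)
}

#' Extinction coefficient by alkaline denaturation
#'
#' The native-state extinction coefficient from paired absorption spectra
#' of the intact and NaOH-denatured protein (equal dilution), anchored to
#' the denatured GFP chromophore (`eps = 44,000 M^-1 cm^-1 at 447 nm`):
#' `eps = 44000 * A_native(state_peak) / A_denatured(447)`.
#'
#' @param native,denatured Two-column absorption spectra
#'   (`wavelength`, `absorbance`).
#' @param state_peak Wavelength (nm) of the native state's absorption peak.
#' @param noise_floor Denatured absorbance at 447 nm at or below this value
#'   is rejected.
#' @return Extinction coefficient in M^-1 cm^-1.
#' @export
extinction_from_denaturation <- function(native, denatured, state_peak,
                                         noise_floor = 0) {
  native <- check_spectrum(native, "native")
  denatured <- check_spectrum(denatured, "denatured")
  a_nat <- stats::approx(native[[1]], native[[2]], xout = state_peak)$y
  a_den <- stats::approx(denatured[[1]], denatured[[2]], xout = 447)$y
  if (is.na(a_den) || a_den <= noise_floor) {
    stop("denatured absorbance at 447 nm is at or below the noise floor")
  }
  44000 * a_nat / a_den
}

#' Photokinetic factor
#'
#' Absorbance-dependent correction relating the incident photon flux to
#' the volume-averaged absorbed flux in a cuvette:
#' `F(A) = (1 - 10^-A) / (A ln 10)`, with the continuous extension
#' `F(0) = 1`. Monotonically decreasing in `A`.
#'
#' @param A Total absorbance at the irradiation wavelength, `>= 0`
#'   (vectorized).
#' @return Unitless factor in `(0, 1]`.
#' @examples
#' photokinetic_factor(c(0, 1)) # 1, 0.3909
#' @export
photokinetic_factor <- function(A) {
  if (any(A < 0)) stop("absorbance must be >= 0")
  out <- ifelse(A < 1e-12, 1, (1 - 10^(-A)) / (A * log(10)))
  as.numeric(out)
}

#' Irradiation record for cuvette switching
#'
#' @param wavelength Irradiation wavelength in nm.
#' @param intensity Incident intensity in mW/cm^2.
#' @param path_length Optical path length in cm.
#' @param concentration Chromophore concentration in micromolar.
#' @return A list of class `irradiation_record`.
#' @export
irradiation_record <- function(wavelength, intensity, path_length = 0.15,
                               concentration = 10) {
  if (path_length <= 0 || concentration <= 0) {
    stop("path length and concentration must be > 0")
  }
  if (intensity < 0) stop("intensity must be >= 0")
  structure(list(wavelength = wavelength, intensity = intensity,
                 path_length = path_length, concentration = concentration),
            class = "irradiation_record")
}

model_state_eps <- function(model, wavelengths) {
  on_eps <- species_extinction(model$species$on_neutral, wavelengths) +
    species_extinction(model$species$on_anionic, wavelengths)
  off_eps <- species_extinction(model$species$off, wavelengths)
  list(on = on_eps, off = off_eps)
}

cuvette_rates <- function(model, irr, use_photokinetic_factor = TRUE) {
  phi0 <- photon_flux(irr$intensity * 1e-6, irr$wavelength)
  cl <- irr$concentration * 1e-6 * irr$path_length
  eps <- model_state_eps(model, irr$wavelength)
  sig_off_switch <- cross_section(
    species_extinction(model$species$on_neutral, irr$wavelength))
  sig_on_switch <- cross_section(
    species_extinction(model$species$off, irr$wavelength))
  function(p, qy_off = model$qy_off, qy_on = model$qy_on) {
    a_tot <- cl * (p * eps$on + (1 - p) * eps$off)
    f <- if (use_photokinetic_factor) photokinetic_factor(a_tot) else 1
    list(k_off = qy_off * sig_off_switch * phi0 * f,
         k_on = qy_on * sig_on_switch * phi0 * f,
         a_tot = a_tot)
  }
}

#' Forward model of ensemble cuvette switching
#'
#' Integrates the on-state population of a protein solution under
#' continuous monochromatic irradiation, including the self-screening
#' (inner-filter) correction through the [photokinetic_factor()] evaluated
#' at the evolving total absorbance, and emits the composite absorption
#' spectrum at each requested cumulative exposure time:
#' `dp/dt = -qy_off sigma_neutral Phi0 F(A_tot) p
#'          + qy_on sigma_off Phi0 F(A_tot) (1 - p)`.
#'
#' @param model An [rsfp_model()].
#' @param irradiation An [irradiation_record()].
#' @param durations Cumulative exposure times in seconds (non-decreasing);
#'   a 0 time point is prepended if absent.
#' @param p0 Initial on-fraction (default 1 for an off-switching ladder).
#' @param use_photokinetic_factor Set `FALSE` for the optically-thin limit.
#' @param wavelengths Wavelength grid of the emitted spectra.
#' @return An object of class `spectrum_series`: list with `times`,
#'   `p_on`, `spectra` (list of two-column data frames) and `irradiation`.
#' @export
forward_cuvette_switching <- function(model, irradiation, durations,
                                      p0 = 1, use_photokinetic_factor = TRUE,
                                      wavelengths = spectral_grid()) {
  stopifnot(inherits(irradiation, "irradiation_record"))
  if (any(diff(durations) < 0)) stop("durations must be non-decreasing")
  times <- unique(c(0, durations))
  rates <- cuvette_rates(model, irradiation, use_photokinetic_factor)
  deriv <- function(t, y, parms) {
    k <- rates(y[1])
    if (!is.finite(k$a_tot)) stop("total absorbance became non-finite")
    list(-k$k_off * y[1] + k$k_on * (1 - y[1]))
  }
  sol <- deSolve::lsoda(c(p = p0), times, deriv, parms = NULL,
                        rtol = 1e-10, atol = 1e-12)
  p_on <- sol[, "p"]
  cl <- irradiation$concentration * 1e-6 * irradiation$path_length
  eps <- model_state_eps(model, wavelengths)
  spectra <- lapply(p_on, function(p) {
    data.frame(wavelength = wavelengths,
               absorbance = cl * (p * eps$on + (1 - p) * eps$off))
  })
  structure(list(times = times, p_on = as.numeric(p_on), spectra = spectra,
                 irradiation = irradiation),
            class = "spectrum_series")
}

#' Unmix a spectrum series into state populations
#'
#' Non-negative least-squares decomposition of each absorption spectrum
#' into on- and off-state reference spectra (populations cannot be
#' negative), normalized to the conserved total.
#'
#' @param series A `spectrum_series`.
#' @param model An [rsfp_model()] providing the state reference spectra.
#' @return Numeric vector of on-fractions, one per time point.
#' @export
unmix_populations <- function(series, model) {
  wl <- series$spectra[[1]]$wavelength
  cl <- series$irradiation$concentration * 1e-6 *
    series$irradiation$path_length
  eps <- model_state_eps(model, wl)
  M <- cbind(on = cl * eps$on, off = cl * eps$off)
  cosang <- sum(M[, 1] * M[, 2]) /
    sqrt(sum(M[, 1]^2) * sum(M[, 2]^2))
  if (cosang > 1 - 1e-6) {
    stop("state reference spectra are nearly collinear: unmixing is ill-conditioned")
  }
  vapply(series$spectra, function(s) {
    x <- pracma::lsqnonneg(M, s$absorbance)$x
    if (sum(x) <= 0) return(NA_real_)
    x[1] / sum(x)
  }, 0)
}

#' Estimate a switching quantum yield from timed absorption spectra
#'
#' The photokinetic estimation procedure: each spectrum of the series is
#' unmixed into state populations ([unmix_populations()]), and the single
#' free switching quantum yield of the forward cuvette model is fitted by
#' least squares on the population trajectory. The other quantum yield is
#' held at its value in `model`.
#'
#' @param series A `spectrum_series` (>= 5 time points).
#' @param model An [rsfp_model()]; the quantum yield named by `which` is
#'   treated as unknown.
#' @param which `"qy_off"` or `"qy_on"`.
#' @param interval Search interval for the quantum yield.
#' @return A [fit_result()] with the estimated quantum yield.
#' @export
fit_switching_quantum_yield <- function(series, model,
                                        which = c("qy_off", "qy_on"),
                                        interval = c(1e-5, 1)) {
  which <- match.arg(which)
  if (length(series$times) < 5) stop("need at least 5 time points")
  p_obs <- unmix_populations(series, model)
  p0 <- p_obs[1]
  times <- series$times
  rates <- cuvette_rates(model, series$irradiation)
  trajectory <- function(qy) {
    deriv <- function(t, y, parms) {
      k <- if (which == "qy_off") rates(y[1], qy_off = qy) else
        rates(y[1], qy_on = qy)
      list(-k$k_off * y[1] + k$k_on * (1 - y[1]))
    }
    sol <- deSolve::lsoda(c(p = p0), times, deriv, parms = NULL,
                          rtol = 1e-10, atol = 1e-12)
    sol[, "p"]
  }
  sse <- function(lq) sum((trajectory(exp(lq)) - p_obs)^2)
  opt <- stats::optimize(sse, log(interval), tol = 1e-9)
  est <- exp(opt$minimum)
  fit_result(stats::setNames(est, which), opt$objective, converged = TRUE)
}

#' Biexponential decay fit (ExpDec2)
#'
#' Fits `y = y0 + A1 exp(-x/t1) + A2 exp(-x/t2)` with `t1 <= t2` by
#' convention; used for residual off-state decays and similar traces. Data
#' are sorted by `x` internally.
#'
#' @param x Ordered abscissa values (>= 6 points).
#' @param y Response values.
#' @return A [fit_result()] with `y0`, `A1`, `t1`, `A2`, `t2`.
#' @export
expdec2_fit <- function(x, y) {
  if (length(x) < 6) stop("need at least 6 points")
  ord <- order(x)
  x <- x[ord]
  y <- y[ord]
  span <- diff(range(x))
  amp <- y[1] - y[length(y)]
  dat <- data.frame(x = x, y = y)
  best <- NULL
  for (f1 in c(0.05, 0.15, 0.5)) {
    for (f2 in c(1, 3)) {
      st <- list(y0 = y[length(y)], A1 = amp / 2, t1 = f1 * span,
                 A2 = amp / 2, t2 = f2 * span)
      fit <- tryCatch(
        minpack.lm::nlsLM(y ~ y0 + A1 * exp(-x / t1) + A2 * exp(-x / t2),
                          data = dat, start = st,
                          lower = c(-Inf, -Inf, 1e-12 * span, -Inf, 1e-12 * span),
                          control = minpack.lm::nls.lm.control(maxiter = 400)),
        error = function(e) NULL)
      if (!is.null(fit)) {
        rss <- sum(stats::resid(fit)^2)
        if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
      }
    }
  }
  if (is.null(best)) stop("ExpDec2 fit failed to converge")
  cf <- stats::coef(best$fit)
  if (cf["t1"] > cf["t2"]) {
    cf[c("t1", "t2")] <- cf[c("t2", "t1")]
    cf[c("A1", "A2")] <- cf[c("A2", "A1")]
  }
  fit_result(cf, best$rss, converged = TRUE,
             covariance = tryCatch(stats::vcov(best$fit),
                                   error = function(e) NULL))
}
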