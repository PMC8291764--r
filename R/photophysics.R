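#' Spectral wavelength grid
#'
#' The common 1 nm wavelength grid (240-700 nm) on which all state spectra
#' and spectral integrals in the package are evaluated.
#'
#' @return Integer vector of wavelengths in nm.
#' @export
spectral_grid <- function() 240:700

#' Chromophore species
#'
#' One of the three chromophore forms of a positive-switching RSFP:
#' the neutral (protonated) on-state, the anionic (deprotonated) on-state,
#' and the off-state. Each species carries an extinction spectrum and role
#' flags stating which photoprocess absorption by that species drives.
#'
#' @param name One of `"on_neutral"`, `"on_anionic"`, `"off"`.
#' @param wavelengths Wavelengths (nm) at which `extinction` is sampled;
#'   must be strictly increasing. Values between samples are obtained by
#'   linear interpolation; outside the sampled range the extinction is 0.
#' @param extinction Extinction coefficients in M^-1 cm^-1, all `>= 0`.
#' @param emits_fluorescence Does excitation of this species produce
#'   fluorescence? (Only the anionic on-state.)
#' @param drives_off_switching Does absorption by this species drive the
#'   on-to-off transition? (The neutral on-state.)
#' @param drives_on_switching Does absorption by this species drive the
#'   off-to-on transition? (The off-state.)
#' @return An object of class `chromophore_species`.
#' @seealso [rsfp_model()], [gen_state_spectra()]
#' @export
chromophore_species <- function(name, wavelengths, extinction,
                                emits_fluorescence = identical(name, "on_anionic"),
                                drives_off_switching = identical(name, "on_neutral"),
                                drives_on_switching = identical(name, "off")) {
  name <- match.arg(name, c("on_neutral", "on_anionic", "off"))
  stopifnot(length(wavelengths) == length(extinction),
            length(wavelengths) >= 2,
            all(diff(wavelengths) > 0))
  if (any(extinction < 0)) stop("extinction coefficients must be >= 0")
  structure(
    list(name = name,
         wavelengths = as.numeric(wavelengths),
         extinction = as.numeric(extinction),
         emits_fluorescence = isTRUE(emits_fluorescence),
         drives_off_switching = isTRUE(drives_off_switching),
         drives_on_switching = isTRUE(drives_on_switching)),
    class = "chromophore_species"
  )
}

#' Evaluate a species' extinction coefficient
#'
#' @param species A [chromophore_species()].
#' @param wavelength Wavelength(s) in nm.
#' @return Extinction in M^-1 cm^-1 (0 outside the sampled range).
#' @export
species_extinction <- function(species, wavelength) {
  stats::approx(species$wavelengths, species$extinction, xout = wavelength,
                rule = 1)$y -> y
  y[is.na(y)] <- 0
  y
}

#' Two-state RSFP photoswitching model
#'
#' Bundles the three chromophore species with the quantum yields governing
#' switching, fluorescence and (optionally) photobleaching. The on-state is
#' treated as an instantaneous protonation equilibrium: the supplied state
#' spectra are the apparent (equilibrium-weighted) on-state band spectra as
#' measured on the ensemble, so no additional anionic-fraction weighting is
#' applied when rates are formed. `f_anionic` records the equilibrium
#' fraction for reference.
#'
#' @param species List of three [chromophore_species()] (one per name).
#' @param qy_off Off-switching quantum yield (per photon absorbed by the
#'   neutral on-state), in `[0, 1]`.
#' @param qy_on On-switching quantum yield (per photon absorbed by the
#'   off-state), in `[0, 1]`.
#' @param qy_fl Fluorescence quantum yield of the anionic on-state.
#' @param qy_bleach Photobleaching quantum yield per absorbed photon
#'   (lumped over species); default 0.
#' @param f_anionic Fraction of on-state chromophores in the anionic form at
#'   working pH (default 0.222).
#' @param name Protein label.
#' @param emission_min_wavelength Illumination below this wavelength (nm) is
#'   not counted as fluorescence excitation (default 450 nm): positive
#'   switchers show very little emission under 405 nm light.
#' @return An object of class `rsfp_model`.
#' @seealso [padron2_model()], [switching_rates()]
#' @export
rsfp_model <- function(species, qy_off, qy_on, qy_fl, qy_bleach = 0,
                       f_anionic = 0.222, name = "rsfp",
                       emission_min_wavelength = 450) {
  stopifnot(is.list(species), length(species) == 3)
  nms <- vapply(species, `[[`, "", "name")
  if (!setequal(nms, c("on_neutral", "on_anionic", "off"))) {
    stop("species must contain exactly on_neutral, on_anionic and off")
  }
  names(species) <- nms
  n_emit <- sum(vapply(species, `[[`, TRUE, "emits_fluorescence"))
  if (n_emit != 1L || !species$on_anionic$emits_fluorescence) {
    stop("exactly one species (on_anionic) must emit fluorescence")
  }
  for (qy in list(qy_off, qy_on, qy_fl, qy_bleach)) {
    if (!is.na(qy) && (qy < 0 || qy > 1)) stop("quantum yields must lie in [0, 1]")
  }
  if (f_anionic < 0 || f_anionic > 1) stop("f_anionic must lie in [0, 1]")
  structure(
    list(name = name, species = species,
         qy_off = qy_off, qy_on = qy_on, qy_fl = qy_fl,
         qy_bleach = qy_bleach, f_anionic = f_anionic,
         emission_min_wavelength = emission_min_wavelength),
    class = "rsfp_model"
  )
}

#' @export
print.rsfp_model <- function(x, ...) {
  cat("<rsfp_model>", x$name, "\n")
  cat(sprintf("  qy_off %.4g  qy_on %.4g  qy_fl %.4g  qy_bleach %.4g\n",
              x$qy_off, x$qy_on, x$qy_fl, x$qy_bleach))
  cat(sprintf("  anionic on-state fraction %.3f\n", x$f_anionic))
  invisible(x)
}

#' Illumination field
#'
#' A single monochromatic illumination component at a point.
#'
#' @param wavelength Wavelength in nm.
#' @param intensity Irradiance in kW/cm^2, `>= 0`.
#' @return An object of class `illumination`.
#' @export
illumination <- function(wavelength, intensity) {
  if (intensity < 0) stop("intensity must be >= 0")
  structure(list(wavelength = wavelength, intensity = intensity),
            class = "illumination")
}

#' Rate set of the two-state model
#'
#' @param k_on Off-to-on switching rate, 1/s.
#' @param k_off On-to-off switching rate, 1/s.
#' @param k_bleach Photobleaching rate, 1/s.
#' @param k_emit Fluorescence emission rate per on-state molecule,
#'   photons/s.
#' @return An object of class `rate_set`.
#' @export
rate_set <- function(k_on = 0, k_off = 0, k_bleach = 0, k_emit = 0) {
  if (any(c(k_on, k_off, k_bleach, k_emit) < 0)) stop("rates must be >= 0")
  structure(list(k_on = k_on, k_off = k_off,
                 k_bleach = k_bleach, k_emit = k_emit),
            class = "rate_set")
}

#' Per-unit-intensity rate coefficients at a wavelength
#'
#' Rates of the two-state model per 1 kW/cm^2 of illumination at a given
#' wavelength. Multiplying these coefficients by an intensity map gives the
#' spatially resolved rates; [switching_rates()] uses them for scalar fields.
#'
#' @param model An [rsfp_model()].
#' @param wavelength Wavelength in nm.
#' @param cross_activation_488_off If `TRUE`, absorption by the anionic
#'   on-state also contributes to off-switching (disabled by default; the
#'   on-to-off transition proceeds through the protonated chromophore).
#' @return A list with `k_on`, `k_off`, `k_bleach`, `k_emit`, each in 1/s
#'   per kW/cm^2.
#' @export
rate_coefficients <- function(model, wavelength,
                              cross_activation_488_off = FALSE) {
  phi <- photon_flux(1, wavelength)
  sp <- model$species
  sig <- function(s) cross_section(species_extinction(s, wavelength))
  k_off <- 0
  if (sp$on_neutral$drives_off_switching) {
    k_off <- k_off + sig(sp$on_neutral) * phi * model$qy_off
  }
  if (cross_activation_488_off) {
    k_off <- k_off + sig(sp$on_anionic) * phi * model$qy_off
  }
  k_on <- if (sp$off$drives_on_switching) sig(sp$off) * phi * model$qy_on else 0
  k_emit <- if (wavelength >= model$emission_min_wavelength) {
    sig(sp$on_anionic) * phi * model$qy_fl
  } else 0
  k_bleach <- model$qy_bleach * phi *
    (sig(sp$on_neutral) + sig(sp$on_anionic) + sig(sp$off))
  list(k_on = k_on, k_off = k_off, k_bleach = k_bleach, k_emit = k_emit)
}

#' Switching rates under a set of illumination fields
#'
#' Forms the rates of the two-state model under one or more simultaneous
#' monochromatic illumination components. Each rate is the product of the
#' relevant species' absorption cross section `sigma(lambda)`, the photon
#' flux `Phi = I lambda / (h c)` and the corresponding quantum yield, summed
#' over fields; rates are exactly linear in intensity.
#'
#' @param model An [rsfp_model()].
#' @param fields A list of [illumination()] objects (possibly empty).
#' @param cross_activation_488_off Passed to [rate_coefficients()].
#' @return A [rate_set()].
#' @examples
#' m <- padron2_model()
#' switching_rates(m, list(illumination(405, 1), illumination(488, 1)))
#' @export
switching_rates <- function(model, fields,
                            cross_activation_488_off = FALSE) {
  stopifnot(inherits(model, "rsfp_model"), is.list(fields))
  k <- c(k_on = 0, k_off = 0, k_bleach = 0, k_emit = 0)
  for (f in fields) {
    if (f$intensity < 0) stop("intensity must be >= 0")
    co <- rate_coefficients(model, f$wavelength,
                            cross_activation_488_off = cross_activation_488_off)
    k <- k + f$intensity * unlist(co)[names(k)]
  }
  rate_set(k_on = k[["k_on"]], k_off = k[["k_off"]],
           k_bleach = k[["k_bleach"]], k_emit = k[["k_emit"]])
}

#' Steady-state on-fraction
#'
#' The stationary on-state population of the two-state model,
#' `k_on / (k_on + k_off)`. Bleaching is excluded from the steady state.
#'
#' @param rates A [rate_set()] or a list with `k_on` and `k_off`.
#' @return Fraction in `[0, 1]`.
#' @examples
#' steady_state_on_fraction(rate_set(k_on = 1, k_off = 19)) # 0.05
#' @export
steady_state_on_fraction <- function(rates) {
  if (rates$k_on + rates$k_off <= 0) {
    stop("steady state undefined: k_on + k_off must be > 0")
  }
  rates$k_on / (rates$k_on + rates$k_off)
}

#' Relax the on-fraction for a time interval
#'
#' Closed-form solution of `dp/dt = k_on (1 - p) - k_off p`:
#' `p(t) = p_ss + (p0 - p_ss) exp(-(k_on + k_off) t)`.
#'
#' @param p0 Initial on-fraction in `[0, 1]`.
#' @param rates A [rate_set()].
#' @param t Time in seconds, `>= 0` (vectorized).
#' @return On-fraction(s) in `[0, 1]`.
#' @export
evolve_on_fraction <- function(p0, rates, t) {
  if (any(t < 0)) stop("t must be >= 0")
  if (p0 < 0 || p0 > 1) stop("p0 must lie in [0, 1]")
  ktot <- rates$k_on + rates$k_off
  if (ktot == 0) return(rep(p0, length.out = length(t)))
  p_ss <- rates$k_on / ktot
  p_ss + (p0 - p_ss) * exp(-ktot * t)
}

#' Expected emission rate
#'
#' @param p_on On-fraction in `[0, 1]`.
#' @param rates A [rate_set()].
#' @return Expected photons/s per molecule, `p_on * k_emit`.
#' @export
emitted_signal_rate <- function(p_on, rates) {
  if (any(p_on < 0 | p_on > 1)) stop("p_on must lie in [0, 1]")
  p_on * rates$k_emit
}
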